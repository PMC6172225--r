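#' Row-wise relative abundance
#'
#' Standardises a samples x taxa count matrix to equal unit total: each row
#' is divided by its sum.
#'
#' @param m Non-negative matrix with positive row sums.
#' @return Matrix of proportions; rows sum to 1.
#' @export
relative_abundance <- function(m) {
  m <- as.matrix(m)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("zero-sum sample(s): ",
         paste(rownames(m)[tot <= 0] %||% which(tot <= 0), collapse = ", "))
  m / tot
}

#' Euclidean distance matrix between sample profiles
#'
#' @param m Samples x variables matrix (rows are samples).
#' @return A \code{dist} object.
#' @export
euclidean_distance <- function(m) stats::dist(as.matrix(m), method = "euclidean")

#' Sorensen dissimilarity between presence-absence profiles
#'
#' \eqn{D = 1 - 2a / (2a + b + c)} with \eqn{a} shared presences and
#' \eqn{b}, \eqn{c} the exclusive presences of either sample. Counts are
#' binarised first. Two empty samples are defined to be at distance 0
#' (with a warning).
#'
#' @param m Samples x taxa matrix (any non-negative counts; converted to
#'   presence/absence).
#' @return A \code{dist} object.
#' @export
sorensen_distance <- function(m) {
  b <- (as.matrix(m) > 0) * 1
  n <- nrow(b)
  out <- matrix(0, n, n, dimnames = list(rownames(b), rownames(b)))
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sum(b[i, ] & b[j, ])
    bc <- sum(b[i, ] != b[j, ])
    if (2 * a + bc == 0) {
      if (!warned) {
        warning("empty sample pair(s): Sorensen distance defined as 0")
        warned <- TRUE
      }
      d <- 0
    } else d <- 1 - 2 * a / (2 * a + bc)
    out[i, j] <- out[j, i] <- d
  }
  stats::as.dist(out)
}

.as_dist_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-10) ||
      any(abs(diag(m)) > 1e-10))
    stop("not a valid distance matrix (symmetric, zero diagonal)")
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries; significance by
#' jointly permuting the rows and columns of the second matrix. Two-sided:
#' the p-value counts permutations with \eqn{|r^*| \ge |r|}, with the
#' observed statistic included, \eqn{p = (1 + m)/(1 + n_{perm})}.
#'
#' With \code{exact = TRUE} all \eqn{n!} label permutations are enumerated
#' instead (identity included) and \eqn{p = m / n!}.
#'
#' @param d1,d2 Distance matrices (\code{dist} or square matrix) over the
#'   same samples in the same order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed RNG seed for reproducibility.
#' @param exact Enumerate all permutations (feasible for n <= 8).
#' @return List of class \code{mantel_result}: \code{r}, \code{p},
#'   \code{n_perm}.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL, exact = FALSE) {
  m1 <- .as_dist_matrix(d1)
  m2 <- .as_dist_matrix(d2)
  if (nrow(m1) != nrow(m2)) stop("distance matrices differ in size")
  n <- nrow(m1)
  ut <- upper.tri(m1)
  x <- m1[ut]
  if (stats::sd(x) == 0 || stats::sd(m2[ut]) == 0) {
    warning("constant distance matrix: Mantel r undefined")
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm),
                     class = "mantel_result"))
  }
  r_obs <- cor(x, m2[ut])
  if (exact) {
    if (n > 8) stop("exact enumeration infeasible for n > 8")
    perms <- .permutations(n)
    rs <- apply(perms, 1, function(p) cor(x, m2[p, p][ut]))
    return(structure(list(r = r_obs,
                          p = mean(abs(rs) >= abs(r_obs) - 1e-12),
                          n_perm = nrow(perms)),
                     class = "mantel_result"))
  }
  with_seed(seed, {
    exceed <- 0L
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      r_perm <- cor(x, m2[p, p][ut])
      if (abs(r_perm) >= abs(r_obs) - 1e-12) exceed <- exceed + 1L
    }
    structure(list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
                   n_perm = n_perm),
              class = "mantel_result")
  })
}

# All permutations of 1..n as rows (row 1 = identity).
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

# Pseudo-F from squared distances: SS_total = sum_{i<j} d^2 / n,
# SS_within = sum over groups of within-group pair d^2 / n_g.
.permanova_F <- function(d2mat, groups) {
  n <- nrow(d2mat)
  g <- length(unique(groups))
  ss_tot <- sum(d2mat[upper.tri(d2mat)]) / n
  ss_w <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    sub <- d2mat[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_b <- ss_tot - ss_w
  (ss_b / (g - 1)) / (ss_w / (n - g))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: pseudo-F from within/between
#' sums of squared distances, significance by free permutation of group
#' labels, \eqn{p = (1 + m)/(1 + n_{perm})}. Pairwise group contrasts use
#' the same statistic on the sub-matrix of each pair.
#'
#' @param d Distance matrix (\code{dist} or square matrix).
#' @param groups Factor-like group labels, one per sample.
#' @param n_perm Number of permutations (default 9999, the study's
#'   setting).
#' @param seed RNG seed.
#' @param pairwise Also run all pairwise contrasts (default TRUE).
#' @return List of class \code{permanova_result}: \code{pseudo_F},
#'   \code{p}, \code{n_perm}, \code{pairwise} (data.frame or NULL).
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL, pairwise = TRUE) {
  m <- .as_dist_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("group(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- m^2
  f_obs <- .permanova_F(d2, groups)
  one_p <- function(d2, groups, f_obs, n_perm) {
    exceed <- 0L
    n <- nrow(d2)
    for (k in seq_len(n_perm))
      if (.permanova_F(d2, groups[sample.int(n)]) >= f_obs - 1e-12)
        exceed <- exceed + 1L
    (1 + exceed) / (1 + n_perm)
  }
  with_seed(seed, {
    p <- one_p(d2, groups, f_obs, n_perm)
    pw <- NULL
    if (pairwise && length(sizes) > 2) {
      combos <- combn(names(sizes), 2)
      pw <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
        lev <- combos[, k]
        idx <- groups %in% lev
        sub <- d2[idx, idx, drop = FALSE]
        f <- .permanova_F(sub, groups[idx])
        data.frame(group1 = lev[1], group2 = lev[2], pseudo_F = f,
                   p = one_p(sub, groups[idx], f, n_perm))
      }))
    }
    structure(list(pseudo_F = f_obs, p = p, n_perm = n_perm, pairwise = pw),
              class = "permanova_result")
  })
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p, x$n_perm))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

# Principal-coordinate embedding retaining real and imaginary axes.
.pcoa_axes <- function(m) {
  n <- nrow(m)
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (m^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  list(real = e$vectors[, pos, drop = FALSE] %*%
         diag(sqrt(e$values[pos]), sum(pos)),
       imag = e$vectors[, neg, drop = FALSE] %*%
         diag(sqrt(-e$values[neg]), sum(neg)))
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates (negative
#' eigenvalues kept as imaginary axes whose squared contributions are
#' subtracted), computes each sample's distance to its group centroid, and
#' tests equality of mean dispersion with a one-way F statistic whose null
#' distribution is obtained by permuting the distances-to-centroid across
#' groups.
#'
#' @inheritParams permanova
#' @return List of class \code{permdisp_result}: \code{F}, \code{p},
#'   \code{group_means} (mean distance to centroid per group),
#'   \code{distances}.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = NULL) {
  m <- .as_dist_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least two groups with at least two samples each")
  ax <- .pcoa_axes(m)
  z <- numeric(nrow(m))
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    cr <- colMeans(ax$real[idx, , drop = FALSE])
    ci <- if (ncol(ax$imag)) colMeans(ax$imag[idx, , drop = FALSE]) else numeric(0)
    d2 <- rowSums(sweep(ax$real[idx, , drop = FALSE], 2, cr)^2)
    if (length(ci))
      d2 <- d2 - rowSums(sweep(ax$imag[idx, , drop = FALSE], 2, ci)^2)
    z[idx] <- sqrt(pmax(d2, 0))
  }
  f_stat <- function(z, groups) {
    n <- length(z); g <- length(unique(groups))
    gm <- tapply(z, groups, mean)
    ssb <- sum(tapply(z, groups, length) * (gm - mean(z))^2)
    ssw <- sum((z - gm[groups])^2)
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_stat(z, groups)
  with_seed(seed, {
    exceed <- 0L
    for (k in seq_len(n_perm))
      if (f_stat(z[sample.int(length(z))], groups) >= f_obs - 1e-12)
        exceed <- exceed + 1L
    structure(list(F = f_obs, p = (1 + exceed) / (1 + n_perm),
                   group_means = tapply(z, groups, mean), distances = z,
                   n_perm = n_perm),
              class = "permdisp_result")
  })
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.4f, p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_perm))
  print(round(x$group_means, 4))
  invisible(x)
}

# Non-metric stress-1 via monotone (isotonic) regression of configuration
# distances on the rank order of the dissimilarities.
.nmds_stress <- function(dvec, conf_d) {
  ord <- order(dvec)
  fit <- isoreg(conf_d[ord])$yf
  dhat <- numeric(length(dvec))
  dhat[ord] <- fit
  list(stress = sqrt(sum((conf_d - dhat)^2) / sum(conf_d^2)), dhat = dhat)
}

#' Non-metric multidimensional scaling (nMDS)
#'
#' Kruskal-style nMDS: configuration distances are fitted to the
#' dissimilarity ranks by isotonic regression and the configuration is
#' updated by the Guttman transform (SMACOF majorisation), which makes the
#' tracked stress-1 non-increasing. The best of \code{n_starts} runs
#' (principal-coordinate start plus random starts) is returned.
#'
#' @param d Distance matrix (\code{dist} or square matrix).
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of starts (default 4).
#' @param seed RNG seed.
#' @param max_iter,tol Iteration cap and stress-decrease tolerance.
#' @return List of class \code{nmds_result}: \code{points} (n x k),
#'   \code{stress}, \code{stress_trace}, \code{converged}.
#' @export
nmds <- function(d, k = 2, n_starts = 4, seed = NULL, max_iter = 200,
                 tol = 1e-7) {
  m <- .as_dist_matrix(d)
  n <- nrow(m)
  if (n < k + 1) stop("need at least k + 1 samples")
  dvec <- m[upper.tri(m)]
  if (stats::sd(dvec) == 0)
    warning("degenerate (all-equal) dissimilarities: embedding arbitrary")
  run_once <- function(X) {
    trace <- numeric(0)
    last <- Inf
    for (it in seq_len(max_iter)) {
      cd <- as.matrix(stats::dist(X))
      conf_d <- cd[upper.tri(cd)]
      if (all(conf_d == 0)) break
      st <- .nmds_stress(dvec, conf_d)
      trace <- c(trace, st$stress)
      if (last - st$stress < tol) break
      last <- st$stress
      # Guttman transform toward dhat
      dhat <- matrix(0, n, n)
      dhat[upper.tri(dhat)] <- st$dhat
      dhat <- dhat + t(dhat)
      ratio <- ifelse(cd > 0, dhat / cd, 0)
      B <- -ratio
      diag(B) <- rowSums(ratio)
      X <- B %*% X / n
      X <- scale(X, center = TRUE, scale = FALSE)
    }
    list(points = X, stress = if (length(trace)) min(trace) else NA_real_,
         stress_trace = trace, converged = length(trace) < max_iter)
  }
  with_seed(seed, {
    starts <- vector("list", n_starts)
    pc <- suppressWarnings(cmdscale(stats::as.dist(m), k = k))
    if (ncol(pc) < k) pc <- cbind(pc, matrix(0, n, k - ncol(pc)))
    starts[[1]] <- pc
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- matrix(rnorm(n * k), n, k)
    fits <- lapply(starts, run_once)
    best <- fits[[which.min(vapply(fits, `[[`, 0, "stress"))]]
    rownames(best$points) <- rownames(m)
    structure(best, class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("nMDS: %d points in %d dimensions, stress = %.4f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' @export
plot.nmds_result <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$points[, 1], x$points[, 2], col = col, pch = 19,
                 xlab = "nMDS1", ylab = "nMDS2",
                 main = sprintf("nMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}

#' Analytic rarefaction curve
#'
#' Expected taxon richness in a hypergeometric subsample of \code{d} reads:
#' \eqn{E[S_d] = \sum_i (1 - C(N - N_i, d) / C(N, d))}. Monotone
#' non-decreasing in depth and equal to observed richness at \eqn{d = N}.
#'
#' @param counts Non-negative integer vector of reads per taxon for one
#'   sample.
#' @param depths Subsample depths (each at most \code{sum(counts)}).
#' @return data.frame with \code{depth} and \code{expected_richness}.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds sample total (", N, ")")
  if (any(depths < 0)) stop("depths must be non-negative")
  er <- vapply(depths, function(d) {
    sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  }, 0)
  data.frame(depth = depths, expected_richness = er)
}
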