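#' Denoising parameters
#'
#' @param ratio_threshold Maximum child/parent per-sample count ratio for a
#'   variant edge (default 0.05, the study's \code{r}); must be in (0, 1)
#'   so the variant graph stays acyclic.
#' @param max_edit_distance Maximum Levenshtein distance
#'   (substitutions + indels) between parent and variant (default 1).
#' @return List of class \code{denoise_params}.
#' @export
denoise_params <- function(ratio_threshold = 0.05, max_edit_distance = 1) {
  if (ratio_threshold <= 0 || ratio_threshold >= 1)
    stop("ratio_threshold must be in (0, 1): edges must strictly decrease counts")
  stopifnot(max_edit_distance >= 1)
  structure(list(ratio_threshold = ratio_threshold,
                 max_edit_distance = as.integer(max_edit_distance)),
            class = "denoise_params")
}

#' Dereplicate inserts into an OTU table
#'
#' Collapses identical sequences (exact string identity; sequences of
#' different length are distinct OTUs) and tallies counts per sample.
#' Per-sample read totals are conserved.
#'
#' @param samples Named list sample -> character vector of inserts.
#' @return Object of class \code{otu_table}: list with \code{otu_id},
#'   \code{sequence} (named by otu id), \code{counts} (integer matrix, OTUs
#'   x samples) and optionally \code{status} after [denoise()].
#' @export
dereplicate <- function(samples) {
  if (is.null(names(samples)) && length(samples))
    names(samples) <- paste0("sample", seq_along(samples))
  all_seq <- unlist(samples, use.names = FALSE)
  uniq <- unique(all_seq)
  # deterministic order: most abundant first, ties lexicographic
  tot <- tabulate(match(all_seq, uniq), nbins = length(uniq))
  ord <- order(-tot, uniq)
  uniq <- uniq[ord]
  counts <- if (length(uniq)) {
    vapply(samples, function(x) tabulate(match(x, uniq), nbins = length(uniq)),
           integer(length(uniq)))
  } else integer(0)
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   ncol = length(samples),
                   dimnames = list(NULL, names(samples)))
  otu_id <- sprintf("OTU_%05d", seq_along(uniq))
  rownames(counts) <- otu_id
  structure(list(otu_id = otu_id, sequence = setNames(uniq, otu_id),
                 counts = counts, status = NULL),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d sample(s), %d reads\n",
              length(x$otu_id), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

.subset_otus <- function(tab, keep) {
  structure(list(otu_id = tab$otu_id[keep],
                 sequence = tab$sequence[keep],
                 counts = tab$counts[keep, , drop = FALSE],
                 status = if (!is.null(tab$status))
                   tab$status[keep, , drop = FALSE] else NULL),
            class = "otu_table")
}

#' Drop rare OTUs
#'
#' Removes OTUs whose total count across samples is below \code{min_reads}
#' (inclusive threshold: an OTU with exactly \code{min_reads} reads stays).
#'
#' @param tab An [otu_table][dereplicate()].
#' @param min_reads Minimum total reads (default 3).
#' @return Filtered \code{otu_table}.
#' @export
min_count_filter <- function(tab, min_reads = 3) {
  .subset_otus(tab, rowSums(tab$counts) >= min_reads)
}

# All unordered pairs of sequences at Levenshtein distance exactly 1
# (substitution or single indel), found by key hashing: two equal-length
# sequences differing at one position share a (length, position, remainder)
# key; an insertion/deletion pair shares a deletion-variant key. Returns a
# 2-column index matrix into `seqs`. O(total sequence length), so it scales
# to tables where an all-pairs edit-distance matrix would not.
.neighbour_pairs_d1 <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(matrix(integer(), 0, 2))
  L <- nchar(seqs)
  keys <- vector("list", max(L) + 2L)
  # substitution keys
  for (i in seq_len(max(L))) {
    has <- which(L >= i)
    if (!length(has)) next
    keys[[i]] <- setNames(
      paste0("S", L[has], ":", i, ":", substr(seqs[has], 1, i - 1),
             substr(seqs[has], i + 1, L[has])),
      has)
  }
  # deletion keys: each sequence itself plus all single-deletion variants
  del <- vector("list", max(L) + 1L)
  del[[1]] <- setNames(paste0("D:", seqs), seq_len(n))
  for (i in seq_len(max(L))) {
    has <- which(L >= i)
    if (!length(has)) next
    del[[i + 1L]] <- setNames(
      paste0("D:", substr(seqs[has], 1, i - 1),
             substr(seqs[has], i + 1, L[has])),
      has)
  }
  collide <- function(key) {
    idx <- as.integer(names(key))
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    key <- key[dup]; idx <- idx[dup]
    if (!length(key)) return(matrix(integer(), 0, 2))
    pairs <- do.call(cbind, lapply(split(idx, key), function(g) {
      g <- unique(g)
      if (length(g) < 2) return(NULL)
      combn(sort(g), 2)
    }))
    if (is.null(pairs)) return(matrix(integer(), 0, 2))
    unique(t(pairs))
  }
  sub_pairs <- collide(unlist(keys))   # equal length, Hamming distance 1
  del_pairs <- collide(unlist(del))
  if (nrow(del_pairs)) {
    # a deletion-key collision is edit distance 1 only when the lengths
    # differ by exactly 1 (equal-length collisions can be distance 2)
    ok <- abs(L[del_pairs[, 1]] - L[del_pairs[, 2]]) == 1
    del_pairs <- del_pairs[ok, , drop = FALSE]
  }
  unique(rbind(sub_pairs, del_pairs))
}

# Neighbour pairs at Levenshtein distance <= d (generic path via adist).
.neighbour_pairs <- function(seqs, d) {
  if (d == 1) return(.neighbour_pairs_d1(seqs))
  n <- length(seqs)
  if (n < 2) return(matrix(integer(), 0, 2))
  if (n > 4000)
    stop("all-pairs edit distance over ", n,
         " OTUs is infeasible; use max_edit_distance = 1")
  dm <- adist(seqs)
  idx <- which(dm <= d & upper.tri(dm), arr.ind = TRUE)
  unname(idx[, c(1, 2), drop = FALSE])
}

#' Build per-sample variant graphs
#'
#' Within each sample, draws a directed edge from OTU \code{u} to OTU
#' \code{v} when their sequences are within \code{max_edit_distance} and
#' \code{count(v)/count(u) <= ratio_threshold}; \code{v} is then a likely
#' amplification/sequencing variant of \code{u}. With
#' \code{ratio_threshold < 1} every edge strictly decreases the count, so
#' each per-sample graph is a DAG.
#'
#' @param tab An [otu_table][dereplicate()].
#' @param params A [denoise_params()].
#' @return Named list sample -> data.frame of edges (\code{from},
#'   \code{to}, otu ids).
#' @export
build_clean_graph <- function(tab, params = denoise_params()) {
  pairs <- .neighbour_pairs(unname(tab$sequence), params$max_edit_distance)
  r <- params$ratio_threshold
  out <- lapply(colnames(tab$counts), function(s) {
    cnt <- tab$counts[, s]
    if (nrow(pairs) == 0)
      return(data.frame(from = character(), to = character()))
    a <- pairs[, 1]; b <- pairs[, 2]
    present <- cnt[a] > 0 & cnt[b] > 0
    a <- a[present]; b <- b[present]
    # orient: edge high -> low where ratio <= r (both directions checked)
    ab <- cnt[b] / cnt[a] <= r
    ba <- cnt[a] / cnt[b] <= r
    data.frame(from = tab$otu_id[c(a[ab], b[ba])],
               to = tab$otu_id[c(b[ab], a[ba])])
  })
  names(out) <- colnames(tab$counts)
  out
}

#' Classify OTUs as head, internal or singleton per sample
#'
#' In each sample's variant graph: \code{singleton} = no incident edges
#' (a sequence lacking a variant), \code{internal} = at least one incoming
#' edge (it is someone's variant; incoming beats outgoing), \code{head} =
#' outgoing edges only (a frequent sequence with variants).
#'
#' @param tab An [otu_table][dereplicate()].
#' @param graph Result of [build_clean_graph()].
#' @return The table with a \code{status} character matrix (OTUs x samples;
#'   \code{NA} where the OTU has no reads).
#' @export
classify_status <- function(tab, graph) {
  status <- matrix(NA_character_, nrow = length(tab$otu_id),
                   ncol = ncol(tab$counts),
                   dimnames = dimnames(tab$counts))
  for (s in colnames(tab$counts)) {
    present <- tab$counts[, s] > 0
    status[present, s] <- "singleton"
    e <- graph[[s]]
    if (nrow(e)) {
      status[unique(e$from), s] <- "head"
      status[unique(e$to), s] <- "internal"  # incoming beats outgoing
    }
  }
  tab$status <- status
  tab
}

#' Discard internal OTUs
#'
#' Removes an OTU when its status is \code{internal} in every sample where
#' it occurs; an OTU heading (or isolated in) any sample is retained. This
#' is the conservative cross-sample reading of "discard all internal OTUs".
#'
#' @param tab An [otu_table][dereplicate()] with computed \code{status}.
#' @return Filtered \code{otu_table}.
#' @export
discard_internal <- function(tab) {
  if (is.null(tab$status)) stop("statuses not computed; run classify_status()")
  all_internal <- apply(tab$status, 1, function(st) {
    st <- st[!is.na(st)]
    length(st) > 0 && all(st == "internal")
  })
  .subset_otus(tab, !all_internal)
}

#' Abundance-ratio graph denoising
#'
#' Convenience wrapper: [build_clean_graph()], [classify_status()],
#' [discard_internal()].
#'
#' @param tab An [otu_table][dereplicate()].
#' @param params A [denoise_params()].
#' @return Denoised \code{otu_table} (statuses attached).
#' @export
denoise <- function(tab, params = denoise_params()) {
  graph <- build_clean_graph(tab, params)
  tab <- classify_status(tab, graph)
  discard_internal(tab)
}

#' Export an OTU table as a data.frame / TSV
#'
#' @param tab An [otu_table][dereplicate()].
#' @param path Optional TSV output path.
#' @return data.frame with otu id, sequence, per-sample counts and (when
#'   available) per-sample statuses.
#' @export
otu_table_frame <- function(tab, path = NULL) {
  df <- data.frame(otu_id = tab$otu_id, sequence = unname(tab$sequence),
                   total = rowSums(tab$counts))
  cnt <- as.data.frame(tab$counts)
  names(cnt) <- paste0("count_", names(cnt))
  df <- cbind(df, cnt)
  if (!is.null(tab$status)) {
    st <- as.data.frame(tab$status)
    names(st) <- paste0("status_", names(st))
    df <- cbind(df, st)
  }
  rownames(df) <- NULL
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
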