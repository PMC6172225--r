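#' Simulation parameters
#'
#' Study-condition defaults: a 30-species community (the artificial
#' sample's size), 124-bp minibarcode inserts read as 125-bp paired ends,
#' a 0.5\% per-base substitution error rate, a small chimera fraction, and
#' equimolar abundances.
#'
#' @param n_species Number of species in the reference library (default 30).
#' @param specimens_per_species Specimens per species (default 1; the first
#'   specimen carries the unmutated species sequence).
#' @param interspecific_divergence Guaranteed minimum pairwise p-distance
#'   between species inserts (default 0.05).
#' @param intraspecific_divergence Maximum within-species divergence
#'   (default 0.01); must be below \code{interspecific_divergence}.
#' @param insert_length Minibarcode insert length (default 124).
#' @param read_length Read length (default 125, paired-end).
#' @param substitution_error_rate Per-base substitution error rate applied
#'   to each read (default 0.005).
#' @param chimera_rate Fraction of reads that are single-breakpoint
#'   two-parent chimeras (default 0.01).
#' @param quality_mean,quality_decay,quality_sd Phred quality model: mean
#'   at the first cycle, linear per-cycle decay, and per-base Gaussian
#'   spread (defaults 37, 0.02, 3; clamped to [2, 40]).
#' @param abundance_model \code{"equimolar"} or \code{"lognormal"}.
#' @param lognormal_sdlog sdlog of the log-normal abundance model.
#' @param seed Master seed for the generator.
#' @return List of class \code{sim_params}.
#' @export
sim_params <- function(n_species = 30, specimens_per_species = 1,
                       interspecific_divergence = 0.05,
                       intraspecific_divergence = 0.01,
                       insert_length = 124, read_length = 125,
                       substitution_error_rate = 0.005, chimera_rate = 0.01,
                       quality_mean = 37, quality_decay = 0.02,
                       quality_sd = 3,
                       abundance_model = c("equimolar", "lognormal"),
                       lognormal_sdlog = 1, seed = 1) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_species >= 1, specimens_per_species >= 1,
            interspecific_divergence >= 0, interspecific_divergence < 1,
            intraspecific_divergence >= 0,
            substitution_error_rate >= 0, substitution_error_rate < 1,
            chimera_rate >= 0, chimera_rate < 1)
  if (interspecific_divergence <= intraspecific_divergence)
    stop("interspecific divergence must exceed intraspecific divergence")
  structure(as.list(environment()), class = "sim_params")
}

.bases <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.bases, n, replace = TRUE), collapse = "")

# Substitute the given positions of a sequence with different random bases.
.mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(.bases, ch[p]), 1)
  paste(ch, collapse = "")
}

.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# One concrete plain-DNA expansion of a degenerate primer.
.expand_primer <- function(primer) {
  codes <- iupac_codes()
  sym <- strsplit(.primer_seq(primer), "", fixed = TRUE)[[1]]
  paste(vapply(sym, function(s) {
    b <- codes[[s]]
    if (length(b) == 1) b else sample(b, 1)
  }, ""), collapse = "")
}

#' Simulate a barcode reference library with planted primer sites
#'
#' Species inserts derive from one random scaffold, each mutated so that
#' every species pair differs at no fewer than
#' \code{ceiling(interspecific_divergence * insert_length)} positions
#' (enforced by bounded re-drawing; an error is raised when unsatisfiable).
#' Specimens within a species are mutated at up to
#' \code{intraspecific_divergence}. Every template embeds one concrete
#' expansion of the forward primer and (reverse-complemented) of the
#' reverse primer flanking the insert, plus random padding, so every
#' species is amplifiable with zero mismatches.
#'
#' @param params A [sim_params()].
#' @param fwd,rev Primers to embed (default the COI minibarcode pair).
#' @param pad Padding length on each side of the amplicon (default 30).
#' @return List of class \code{sim_library}: \code{library} (a
#'   [reference_library()]), \code{species} (data.frame with the planted
#'   \code{insert}, \code{fwd_site}, \code{rev_site} per species) and
#'   \code{params}.
#' @export
simulate_reference_library <- function(params = sim_params(),
                                       fwd = coi_minibarcode_primers()$fwd,
                                       rev = coi_minibarcode_primers()$rev,
                                       pad = 30) {
  L <- params$insert_length
  m <- ceiling(params$interspecific_divergence * L)
  if (m >= L) stop("interspecific divergence unsatisfiable at insert length ", L)
  n <- params$n_species
  with_seed(params$seed, {
    scaffold <- .random_dna(L)
    inserts <- vapply(seq_len(n), function(i)
      .mutate_at(scaffold, sample.int(L, m)), "")
    # enforce the pairwise floor by re-drawing offenders (bounded)
    for (round in seq_len(200)) {
      ok <- TRUE
      if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (.hamming(inserts[i], inserts[j]) < m) {
          inserts[j] <- .mutate_at(scaffold, sample.int(L, m))
          ok <- FALSE
        }
      }
      if (ok) break
      if (round == 200)
        stop("could not satisfy the interspecific divergence floor; ",
             "reduce n_species or divergence")
    }
    genus <- sprintf("Genus%03d", seq_len(n))
    species <- sprintf("Genus%03d species%03d", seq_len(n), seq_len(n))
    groups <- rep_len(c("Annelida", "Arthropoda", "Cnidaria", "Mollusca",
                        "Echinodermata", "Craniata"), n)
    fwd_site <- vapply(seq_len(n), function(i) .expand_primer(fwd), "")
    rev_site <- vapply(seq_len(n), function(i) .expand_primer(rev), "")
    k_intra <- floor(params$intraspecific_divergence * L)
    recs <- do.call(rbind, lapply(seq_len(n), function(i) {
      ns <- params$specimens_per_species
      spec_ins <- c(inserts[i], vapply(seq_len(max(0, ns - 1)), function(s)
        .mutate_at(inserts[i], sample.int(L, k_intra)), ""))[seq_len(ns)]
      data.frame(
        specimen_id = sprintf("SP%03d_%02d", i, seq_len(ns)),
        phylum = groups[i], genus = genus[i], species = species[i],
        sequence = paste0(.random_dna(pad), fwd_site[i], spec_ins,
                          revcomp(rev_site[i]), .random_dna(pad)))
    }))
    structure(list(
      library = reference_library(recs),
      species = data.frame(species = species, phylum = groups,
                           insert = inserts, fwd_site = fwd_site,
                           rev_site = rev_site),
      params = params),
      class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %d species x %d specimen(s), insert %d nt\n",
              x$params$n_species, x$params$specimens_per_species,
              x$params$insert_length))
  invisible(x)
}

#' Simulate a mock community
#'
#' Equimolar composition gives every selected species the same expected
#' read share; the log-normal model draws shares and normalises them to 1.
#'
#' @param sim_lib A [simulate_reference_library()] result.
#' @param n_species_subset Number of species to include (default all).
#' @param params A [sim_params()] (abundance model and seed).
#' @param seed RNG seed (default \code{params$seed + 1}).
#' @return data.frame of class \code{mock_community}: \code{species},
#'   \code{share} (sums to 1).
#' @export
simulate_mock_community <- function(sim_lib, n_species_subset = NULL,
                                    params = sim_lib$params, seed = NULL) {
  pool <- sim_lib$species$species
  k <- n_species_subset %||% length(pool)
  if (k > length(pool)) stop("subset exceeds library species count")
  with_seed(seed %||% (params$seed + 1), {
    chosen <- if (k == length(pool)) pool else sample(pool, k)
    share <- if (params$abundance_model == "equimolar") rep(1 / k, k)
    else {
      w <- stats::rlnorm(k, meanlog = 0, sdlog = params$lognormal_sdlog)
      w / sum(w)
    }
    out <- data.frame(species = chosen, share = share)
    class(out) <- c("mock_community", "data.frame")
    out
  })
}

# Apply substitution errors to reads at a per-base rate (vectorised for the
# common single-error case).
.apply_errors <- function(x, rate) {
  if (rate <= 0) return(x)
  L <- nchar(x)
  nmut <- rbinom(length(x), L, rate)
  one <- which(nmut == 1)
  if (length(one)) {
    pos <- ceiling(runif(length(one)) * L[one])
    old <- substr(x[one], pos, pos)
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    new <- alt[cbind(match(old, rownames(alt)),
                     sample.int(3, length(one), replace = TRUE))]
    substr(x[one], pos, pos) <- new
  }
  multi <- which(nmut > 1)
  for (i in multi)
    x[i] <- .mutate_at(x[i], sample.int(L[i], nmut[i]))
  x
}

# n Phred+33 quality strings of length L under the linear-decay model.
.quality_strings <- function(n, L, mean, decay, sd) {
  mu <- rep(mean - decay * (seq_len(L) - 1), each = n)
  q <- as.integer(pmin(40, pmax(2, round(rnorm(n * L, mu, sd)))))
  long <- rawToChar(as.raw(as.vector(t(matrix(q, n, L))) + 33L))
  substring(long, seq(1, n * L, by = L), seq(L, n * L, by = L))
}

#' Simulate tagged, error-prone paired-end reads
#'
#' Each read pair derives from the construct
#' \code{tag_F + forward site + insert + revcomp(reverse site) +
#' revcomp(tag_R)} of a species drawn multinomially from the community
#' shares. A \code{chimera_rate} fraction of reads instead carries a
#' two-parent insert spliced at a uniform breakpoint. Substitution errors
#' and Phred qualities follow the parameters' error and quality models.
#'
#' @param sim_lib A [simulate_reference_library()] result.
#' @param community A [simulate_mock_community()] result.
#' @param scheme A [tag_scheme()]; the tag pair of \code{sample} is used.
#' @param params A [sim_params()].
#' @param depth Number of read pairs.
#' @param sample Sample id (must appear in the scheme's sample map).
#' @param seed RNG seed (default \code{params$seed + 2}).
#' @param min_overlap Required read overlap; an error is raised when the
#'   construct is too long to merge at the given read length (the in-silico
#'   analogue of fragments undetectable at 125-bp paired-end reading).
#' @return List of class \code{sim_reads}: \code{pairs} (a
#'   \code{read_pairs} data.frame), \code{truth} (species read counts and
#'   chimera tally), \code{sample}.
#' @export
simulate_reads <- function(sim_lib, community, scheme = study_tag_scheme("COI"),
                           params = sim_lib$params, depth = 1e5,
                           sample = scheme$sample_map$sample[1],
                           seed = NULL, min_overlap = 10) {
  sp <- sim_lib$species
  m <- match(community$species, sp$species)
  if (anyNA(m)) stop("community species missing from library")
  row <- scheme$sample_map[scheme$sample_map$sample == sample, ]
  if (nrow(row) != 1) stop("sample not in scheme sample_map: ", sample)
  tagF <- toupper(row$forward_tag)
  tagR <- toupper(row$reverse_tag)
  constructs <- paste0(tagF, sp$fwd_site[m], sp$insert[m],
                       revcomp(sp$rev_site[m]), revcomp(tagR))
  cl <- unique(nchar(constructs))
  rl <- params$read_length
  if (any(cl > 2 * rl - min_overlap))
    stop("construct length ", max(cl), " exceeds mergeable length ",
         2 * rl - min_overlap, " at read length ", rl)
  with_seed(seed %||% (params$seed + 2), {
    n_chim <- rbinom(1, depth, params$chimera_rate)
    n_real <- depth - n_chim
    counts <- as.integer(rmultinom(1, n_real, community$share))
    templates <- rep(constructs, counts)
    truth <- data.frame(species = community$species,
                        expected_share = community$share, reads = counts)
    if (n_chim > 0) {
      p1 <- base::sample.int(nrow(community), n_chim, replace = TRUE,
                             prob = community$share)
      p2 <- base::sample.int(nrow(community), n_chim, replace = TRUE,
                             prob = community$share)
      L <- params$insert_length
      bp <- base::sample.int(L - 1, n_chim, replace = TRUE)
      chim_ins <- paste0(substr(sp$insert[m][p1], 1, bp),
                         substr(sp$insert[m][p2], bp + 1, L))
      templates <- c(templates,
                     paste0(tagF, sp$fwd_site[m][p1], chim_ins,
                            revcomp(sp$rev_site[m][p2]), revcomp(tagR)))
    }
    templates <- templates[base::sample.int(length(templates))]
    n <- length(templates)
    tl <- nchar(templates)
    fwd_seq <- .apply_errors(substr(templates, 1, rl),
                             params$substitution_error_rate)
    rev_raw <- substr(templates, tl - rl + 1, tl)
    rev_seq <- .apply_errors(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(rev_raw))),
      params$substitution_error_rate)
    pairs <- data.frame(
      read_id = sprintf("read_%06d", seq_len(n)),
      fwd_seq = fwd_seq, rev_seq = rev_seq,
      fwd_qual = .quality_strings(n, rl, params$quality_mean,
                                  params$quality_decay, params$quality_sd),
      rev_qual = .quality_strings(n, rl, params$quality_mean,
                                  params$quality_decay, params$quality_sd))
    class(pairs) <- c("read_pairs", "data.frame")
    structure(list(pairs = pairs,
                   truth = list(species = truth, n_chimeras = n_chim,
                                depth = depth),
                   sample = sample),
              class = "sim_reads")
  })
}

#' Simulate abiotic sample metadata
#'
#' Pressure follows a depth gradient; temperature, salinity and water
#' density track pressure at a configurable correlation strength, the rest
#' being independent noise. Mirrors CTD casts accompanying water sampling.
#'
#' @param n_samples Number of samples (>= 2).
#' @param depth_range Pressure range in dbar (default 5-50).
#' @param correlation Correlation strength with pressure in [0, 1]
#'   (default 0.8).
#' @param seed RNG seed.
#' @return data.frame: \code{sample}, \code{pressure} (dbar),
#'   \code{temperature} (degC), \code{salinity} (PSU),
#'   \code{water_density} (kg/m^3).
#' @export
simulate_abiotic_metadata <- function(n_samples, depth_range = c(5, 50),
                                      correlation = 0.8, seed = NULL) {
  if (n_samples < 2) stop("need at least two samples")
  stopifnot(correlation >= 0, correlation <= 1)
  with_seed(seed, {
    pressure <- seq(depth_range[1], depth_range[2], length.out = n_samples)
    z <- as.numeric(scale(pressure))
    mix <- function(z) correlation * z +
      sqrt(1 - correlation^2) * rnorm(length(z))
    data.frame(sample = paste0("sample", seq_len(n_samples)),
               pressure = pressure,
               temperature = 15 - 2.5 * mix(z),
               salinity = 31 + 1.5 * mix(z),
               water_density = 1022 + 1.2 * mix(z))
  })
}

#' Standardise variables to equal unit total
#'
#' Divides each column by its total, the standardisation applied to both
#' sequence counts and abiotic variables before distance construction.
#'
#' @param m Numeric matrix or data.frame of non-negative variables
#'   (columns).
#' @return Matrix with unit column sums.
#' @export
standardize_unit_total <- function(m) {
  m <- as.matrix(m)
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero-total column(s)")
  sweep(m, 2, tot, "/")
}
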