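#' Construct a barcode reference library
#'
#' A reference library is a data.frame of specimen barcode records with, at
#' minimum, columns \code{specimen_id}, \code{species} and \code{sequence}.
#' Additional columns are treated as taxonomic ranks (conventionally
#' \code{phylum}, \code{class}, \code{order}, \code{family}, \code{genus});
#' together with \code{species} they form each record's lineage.
#'
#' @param records data.frame with the columns above.
#' @return Object of class \code{reference_library} (a data.frame).
#' @export
reference_library <- function(records) {
  need <- c("specimen_id", "species", "sequence")
  if (!all(need %in% names(records)))
    stop("reference library needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(records$specimen_id))
    stop("specimen_id values must be unique")
  if (any(!nzchar(records$sequence)))
    stop("sequences must be non-empty")
  records$sequence <- toupper(records$sequence)
  class(records) <- c("reference_library", "data.frame")
  records
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d records, %d species\n",
              nrow(x), length(unique(x$species))))
  invisible(x)
}

# Taxonomic ranks recognised in library columns, shallow to deep.
.lineage_ranks <- function(lib) {
  intersect(c("phylum", "class", "order", "family", "genus", "species"),
            names(lib))
}

#' Read a reference library from FASTA plus taxonomy TSV
#'
#' FASTA record names are specimen ids; the taxonomy TSV must contain a
#' \code{specimen_id} column, a \code{species} column and any further rank
#' columns. Sequences are expected unaligned (or pre-aligned per species when
#' species consensus is to be computed; see [species_consensus()]).
#'
#' @param fasta Path to the FASTA file.
#' @param taxonomy Path to the taxonomy TSV.
#' @return A [reference_library()].
#' @export
read_reference_library <- function(fasta, taxonomy) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tax <- read.delim(taxonomy, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(tax))
    stop("taxonomy table needs a specimen_id column")
  ids <- sub("\\s.*$", "", names(seqs))
  m <- match(ids, tax$specimen_id)
  if (anyNA(m))
    stop("specimens missing from taxonomy: ",
         paste(head(ids[is.na(m)]), collapse = ", "))
  rec <- tax[m, , drop = FALSE]
  rec$sequence <- as.character(seqs)
  rownames(rec) <- NULL
  reference_library(rec)
}

#' Write a reference library to FASTA plus taxonomy TSV
#'
#' @param lib A [reference_library()].
#' @param fasta,taxonomy Output paths.
#' @return Invisibly, the library.
#' @export
write_reference_library <- function(lib, fasta, taxonomy) {
  seqs <- Biostrings::DNAStringSet(lib$sequence)
  names(seqs) <- lib$specimen_id
  Biostrings::writeXStringSet(seqs, fasta)
  tax <- lib[, setdiff(names(lib), "sequence"), drop = FALSE]
  write.table(tax, taxonomy, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}

#' Species consensus of aligned sequences
#'
#' For each alignment column, emits the smallest IUPAC code covering every
#' non-gap base observed (ambiguity codes in the input contribute their full
#' base set). All-gap columns are dropped. Input sequences must be equal
#' length (pre-aligned, gaps as \code{-}).
#'
#' @param sequences Character vector of aligned sequences of one species.
#' @return Consensus IUPAC string.
#' @examples
#' species_consensus(c("ACGT", "GCGT"))  # "RCGT"
#' @export
species_consensus <- function(sequences) {
  if (length(sequences) == 0) stop("no sequences supplied")
  sequences <- toupper(sequences)
  if (length(unique(nchar(sequences))) != 1)
    stop("sequences must be aligned to equal length")
  if (length(sequences) == 1) return(gsub("-", "", sequences, fixed = TRUE))
  m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  codes <- iupac_codes()
  cons <- apply(m, 2, function(col) {
    obs <- setdiff(unique(col), "-")
    if (length(obs) == 0) return(NA_character_)
    bad <- setdiff(obs, names(codes))
    if (length(bad)) stop("non-IUPAC symbol in alignment: ", bad[1])
    .iupac_code_for(unique(unlist(codes[obs])))
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Evaluate primer-pair amplifiability over a reference library
#'
#' A specimen is amplifiable when [in_silico_pcr()] on its raw sequence
#' yields at least one amplicon with both primers within the mismatch
#' budget. A species is judged on its species consensus (all its records
#' collapsed with [species_consensus()]), mirroring evaluation on a
#' species-consensus alignment. Forward-only failures (no forward site
#' within budget) are tallied separately.
#'
#' @param lib A [reference_library()].
#' @param fwd,rev Primers, 5'->3'.
#' @param max_mm Mismatch budget per primer (default 4).
#' @param max_insert Maximum insert length (default 1000).
#' @return List of class \code{amplifiability_report}: \code{specimens} and
#'   \code{species} data.frames plus a \code{summary} list with failure
#'   counts and fractions.
#' @export
evaluate_amplifiability <- function(lib, fwd, rev, max_mm = 4,
                                    max_insert = 1000) {
  if (nrow(lib) == 0) stop("empty reference library")
  eval_one <- function(seq) {
    amp <- in_silico_pcr(fwd, rev, seq, max_mm, max_insert)
    f <- scan_binding_sites(fwd, seq, max_mm, "plus")
    data.frame(amplifiable = nrow(amp) > 0,
               fwd_site = nrow(f) > 0,
               min_fwd_mm = if (nrow(amp)) min(amp$fwd_mismatches) else NA,
               min_rev_mm = if (nrow(amp)) min(amp$rev_mismatches) else NA)
  }
  specimens <- do.call(rbind, lapply(lib$sequence, eval_one))
  specimens <- cbind(data.frame(specimen_id = lib$specimen_id,
                           species = lib$species), specimens)
  cons <- vapply(split(lib$sequence, lib$species), species_consensus, "")
  sp <- do.call(rbind, lapply(cons, eval_one))
  sp <- cbind(data.frame(species = names(cons), consensus = unname(cons)), sp)
  rownames(sp) <- NULL
  summary <- list(
    n_specimens = nrow(specimens),
    n_species = nrow(sp),
    failed_specimens = sum(!specimens$amplifiable),
    failed_species = sum(!sp$amplifiable),
    specimen_failure_fraction = mean(!specimens$amplifiable),
    species_failure_fraction = mean(!sp$amplifiable),
    fwd_failed_species = sum(!sp$fwd_site))
  structure(list(specimens = specimens, species = sp, summary = summary),
            class = "amplifiability_report")
}

#' @export
print.amplifiability_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<amplifiability_report> %d species (%d failed, %.1f%%); %d specimens (%d failed, %.1f%%)\n",
    s$n_species, s$failed_species, 100 * s$species_failure_fraction,
    s$n_specimens, s$failed_specimens, 100 * s$specimen_failure_fraction))
  invisible(x)
}

#' Extract per-species minibarcode inserts
#'
#' For each amplifiable species, the insert of the best amplicon of its
#' species consensus: fewest total mismatches, ties broken by the leftmost
#' forward site. Non-amplifiable species are listed in the \code{failed}
#' attribute.
#'
#' @inheritParams evaluate_amplifiability
#' @return Named character vector species -> insert, with attribute
#'   \code{failed} naming species without an in-budget amplicon.
#' @export
extract_minibarcodes <- function(lib, fwd, rev, max_mm = 4, max_insert = 1000) {
  cons <- vapply(split(lib$sequence, lib$species), species_consensus, "")
  res <- lapply(cons, function(seq) {
    amp <- in_silico_pcr(fwd, rev, seq, max_mm, max_insert)
    if (nrow(amp) == 0) return(NA_character_)
    total <- amp$fwd_mismatches + amp$rev_mismatches
    best <- amp[order(total, amp$insert_start), , drop = FALSE][1, ]
    best$insert_sequence
  })
  out <- unlist(res)
  failed <- names(out)[is.na(out)]
  out <- out[!is.na(out)]
  attr(out, "failed") <- failed
  out
}

#' Build an assignment reference database of minibarcode fragments
#'
#' Reference databases for fragment-level assignment hold the potential
#' amplicons of the primers used, not full-length barcodes. This extracts
#' each species' minibarcode insert with [extract_minibarcodes()] and
#' returns a species-level [reference_library()] carrying those inserts
#' (one record per species, lineage columns retained); species without an
#' in-budget amplicon are dropped with a message.
#'
#' @inheritParams evaluate_amplifiability
#' @return A [reference_library()] of minibarcode fragments.
#' @export
minibarcode_refdb <- function(lib, fwd, rev, max_mm = 4, max_insert = 1000) {
  mb <- extract_minibarcodes(lib, fwd, rev, max_mm, max_insert)
  failed <- attr(mb, "failed")
  if (length(failed))
    message(length(failed), " species without an in-budget amplicon dropped: ",
            paste(head(failed, 5), collapse = ", "),
            if (length(failed) > 5) ", ..." else "")
  keep <- lib[!duplicated(lib$species) & lib$species %in% names(mb), ,
              drop = FALSE]
  keep$sequence <- unname(mb[keep$species])
  keep$specimen_id <- keep$species
  rownames(keep) <- NULL
  reference_library(keep)
}

# Uncorrected p-distance between two IUPAC sequences. Equal lengths are
# compared column-wise with set-intersection matching (overlapping ambiguity
# sets count as a match); unequal lengths go through global alignment, where
# gapped positions are excluded from the denominator.
p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    keep <- av != "-" & bv != "-"
    if (!any(keep)) return(0)
    codes <- iupac_codes()
    overlap <- mapply(function(x, y) length(intersect(codes[[x]], codes[[y]])) > 0,
                      av[keep], bv[keep])
    return(mean(!overlap))
  }
  nw <- cpp_nw_identity(a, b)
  compared <- nchar(a) + nchar(b) - nw[1, "columns"]  # aligned, gap-free cols
  if (compared <= 0) return(0)
  unname((compared - nw[1, "matches"]) / compared)
}

#' Species-discrimination power of minibarcode inserts
#'
#' Computes pairwise uncorrected p-distances between species minibarcodes.
#' A pair is confounded when its p-distance is below
#' \code{min_dissimilarity}; a species is distinguishable when it appears in
#' no confounded pair.
#'
#' @param minibarcodes Named character vector species -> insert, as returned
#'   by [extract_minibarcodes()].
#' @param min_dissimilarity Minimum between-species dissimilarity required
#'   to call a pair distinct (default 0.02, i.e. 2\%).
#' @return List of class \code{discrimination_report}: \code{n_species},
#'   \code{distinguishable_fraction}, and \code{confounded_pairs}
#'   data.frame (\code{species1}, \code{species2}, \code{p_distance}).
#' @export
discrimination_power <- function(minibarcodes, min_dissimilarity = 0.02) {
  n <- length(minibarcodes)
  if (n == 0) stop("no minibarcodes supplied")
  pairs <- if (n >= 2) combn(n, 2) else matrix(integer(), 2, 0)
  confounded <- data.frame(species1 = character(), species2 = character(),
                           p_distance = numeric())
  if (ncol(pairs)) {
    pd <- apply(pairs, 2, function(ij)
      p_distance(minibarcodes[[ij[1]]], minibarcodes[[ij[2]]]))
    bad <- pd < min_dissimilarity
    confounded <- data.frame(
      species1 = names(minibarcodes)[pairs[1, bad]],
      species2 = names(minibarcodes)[pairs[2, bad]],
      p_distance = pd[bad])
  }
  involved <- unique(c(confounded$species1, confounded$species2))
  structure(list(
    n_species = n,
    distinguishable_fraction = (n - length(involved)) / n,
    confounded_pairs = confounded,
    min_dissimilarity = min_dissimilarity),
    class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf(
    "<discrimination_report> %d species, %.1f%% distinguishable at %.0f%% dissimilarity; %d confounded pair(s)\n",
    x$n_species, 100 * x$distinguishable_fraction,
    100 * x$min_dissimilarity, nrow(x$confounded_pairs)))
  invisible(x)
}
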