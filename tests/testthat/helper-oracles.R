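# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles (brute-force enumeration, exhaustive DP
# via Biostrings, Monte-Carlo resampling) rather than reusing package code.

# IUPAC base sets, written out independently of the package's table.
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# All plain-DNA expansions of a degenerate sequence (brute force).
oracle_expand <- function(seq) {
  sets <- ORACLE_IUPAC[strsplit(toupper(seq), "")[[1]]]
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1,
        paste, collapse = "")
}

# Min Hamming distance between a window and any expansion of the primer.
oracle_mismatch <- function(primer, window) {
  wv <- strsplit(toupper(window), "")[[1]]
  min(vapply(strsplit(oracle_expand(primer), ""), function(e)
    sum(e != wv), 0L))
}

# Exhaustive sliding-window site enumeration on the plus strand.
oracle_scan <- function(primer, template, max_mm) {
  pl <- nchar(primer); tl <- nchar(template)
  if (tl < pl) return(integer(0))
  starts <- 0:(tl - pl)
  mm <- vapply(starts, function(s)
    oracle_mismatch(primer, substr(template, s + 1, s + pl)), 0L)
  starts[mm <= max_mm]
}

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# plain reverse complement, independent of package internals
rc <- function(x) vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), ""),
                         function(s) paste(rev(s), collapse = ""), "")

# merged_reads row(s) built directly from full construct sequences
as_merged <- function(seqs, qual = NULL) {
  out <- data.frame(read_id = sprintf("r%03d", seq_along(seqs)),
                    sequence = seqs,
                    quality = qual %||% strrep("I", nchar(seqs)),
                    overlap_length = 30L, aligned = TRUE)
  class(out) <- c("merged_reads", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rand_degenerate <- function(len, p_degen = 0.3) {
  syms <- names(ORACLE_IUPAC)
  paste(ifelse(runif(len) < p_degen,
               sample(syms, len, replace = TRUE),
               sample(c("A", "C", "G", "T"), len, replace = TRUE)),
        collapse = "")
}

# Optimal global-alignment score by exhaustive dynamic programming
# (match +1, mismatch -1, gap -1), via Biostrings.
oracle_nw_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 1,
                                scoreOnly = TRUE)
}

# A small reference library with known species inserts flanked by exact
# primer binding sites, for assignment and primer-evaluation tests.
toy_library <- function(inserts, fwd_site = "ACGTACGTAA",
                        rev_site_rc = "TTGGCCAATT",
                        genus = sprintf("Genus%02d", seq_along(inserts)),
                        phylum = "Annelida") {
  species <- paste(genus, sprintf("species%02d", seq_along(inserts)))
  reference_library(data.frame(
    specimen_id = sprintf("SP%02d", seq_along(inserts)),
    phylum = rep_len(phylum, length(inserts)),
    genus = genus, species = species,
    sequence = paste0("GGGGG", fwd_site, inserts, rev_site_rc, "CCCCC")))
}
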