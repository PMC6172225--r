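#' IUPAC nucleotide ambiguity codes
#'
#' Named list mapping each one-letter IUPAC nucleotide code to the set of
#' plain bases it denotes. Degenerate primers are written in this alphabet.
#'
#' @examples
#' iupac_codes()[["R"]]  # A, G
#' @export
iupac_codes <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

.iupac_alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N")

# Smallest IUPAC code covering a set of plain bases.
.iupac_code_for <- local({
  map <- NULL
  function(bases) {
    if (is.null(map)) {
      codes <- iupac_codes()
      map <<- setNames(names(codes),
                       vapply(codes, function(b) paste(sort(b), collapse = ""),
                              ""))
    }
    key <- paste(sort(unique(bases)), collapse = "")
    code <- map[[key]]
    if (is.null(code)) stop("no IUPAC code for base set: ", key)
    code
  }
})

# Reverse complement of IUPAC text (vectorised over character strings).
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), "")
}

#' Does a degenerate primer symbol accept a template base?
#'
#' A primer symbol is compatible with a template symbol when the template's
#' base set is contained in the primer symbol's set. For a plain A/C/G/T
#' template base this is simple set membership; an ambiguous template symbol
#' (e.g. \code{N} in a reference sequence) is only accepted by a primer
#' symbol covering all its possibilities, so \code{N} in a template matches
#' only \code{N} in the primer.
#'
#' @param primer_symbol Single IUPAC code.
#' @param template_base Single template symbol.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' iupac_compatible("R", "A")  # TRUE
#' iupac_compatible("R", "C")  # FALSE
#' @export
iupac_compatible <- function(primer_symbol, template_base) {
  primer_symbol <- toupper(primer_symbol)
  template_base <- toupper(template_base)
  codes <- iupac_codes()
  if (!primer_symbol %in% names(codes))
    stop("unknown IUPAC symbol in primer: ", primer_symbol)
  if (!template_base %in% names(codes))
    stop("unknown template symbol: ", template_base)
  all(codes[[template_base]] %in% codes[[primer_symbol]])
}

#' Construct a degenerate primer
#'
#' @param name Primer name (e.g. \code{"nsCOIFo"}).
#' @param sequence Primer sequence 5'->3' over the IUPAC alphabet.
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @return An object of class \code{degenerate_primer}.
#' @examples
#' degenerate_primer("toy", "ACGRN", "forward")
#' @export
degenerate_primer <- function(name, sequence, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("primer sequence must be non-empty")
  sym <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(sym, .iupac_alphabet)
  if (length(bad))
    stop("primer '", name, "' contains non-IUPAC symbols: ",
         paste(unique(bad), collapse = ", "))
  structure(list(name = name, sequence = sequence, direction = direction),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s) %s [%d nt, degeneracy %d]\n",
              x$name, x$direction, x$sequence, nchar(x$sequence),
              degeneracy(x)))
  invisible(x)
}

.primer_seq <- function(primer) {
  if (inherits(primer, "degenerate_primer")) primer$sequence
  else toupper(as.character(primer))
}

#' Count primer/template mismatches in a window
#'
#' Number of positions at which the degenerate primer does not accept the
#' template symbol (see [iupac_compatible()]). Equals the minimum Hamming
#' distance between the window and any plain-DNA expansion of the primer.
#'
#' @param primer A [degenerate_primer()] or IUPAC string.
#' @param window Template window of the same length (may be a character
#'   vector; one count per window).
#' @return Integer mismatch count(s).
#' @examples
#' mismatch_count("RG", "AG")  # 0
#' mismatch_count("RG", "CG")  # 1
#' @export
mismatch_count <- function(primer, window) {
  pseq <- .primer_seq(primer)
  window <- toupper(window)
  if (any(nchar(window) != nchar(pseq)))
    stop("window length (", paste(unique(nchar(window)), collapse = ","),
         ") does not match primer length (", nchar(pseq), ")")
  cpp_iupac_mismatch(pseq, window)
}

#' Number of plain-DNA expansions of a degenerate primer
#'
#' Product over positions of the size of each symbol's base set.
#'
#' @inheritParams mismatch_count
#' @return Integer degeneracy.
#' @examples
#' degeneracy("RY")  # 4
#' @export
degeneracy <- function(primer) {
  sym <- strsplit(.primer_seq(primer), "", fixed = TRUE)[[1]]
  codes <- iupac_codes()
  bad <- setdiff(sym, names(codes))
  if (length(bad)) stop("non-IUPAC symbols: ", paste(bad, collapse = ", "))
  prod(lengths(codes[sym]))
}

#' Scan a template for primer binding sites
#'
#' Slides the primer over the template and reports every window whose
#' mismatch count is within the budget. For the minus strand the primer's
#' reverse complement is matched against the plus strand and sites are
#' reported in plus-strand coordinates. Coordinates are 0-based.
#'
#' @param primer A [degenerate_primer()] or IUPAC string.
#' @param template Template sequence (plain DNA; ambiguous symbols count as
#'   mismatches unless covered by the primer symbol).
#' @param max_mm Maximum number of mismatches (default 4, the study's budget).
#' @param strand \code{"plus"} or \code{"minus"}.
#' @return data.frame with columns \code{start}, \code{strand},
#'   \code{mismatches}, ascending by \code{start}. A template shorter than
#'   the primer yields zero rows.
#' @export
scan_binding_sites <- function(primer, template, max_mm = 4,
                               strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  if (max_mm < 0) stop("max_mm must be >= 0")
  pseq <- .primer_seq(primer)
  if (strand == "minus") pseq <- revcomp(pseq)
  template <- toupper(template)
  if (nchar(template) < nchar(pseq))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  mm <- cpp_scan_template(pseq, template)
  hit <- which(mm <= max_mm)
  data.frame(start = hit - 1L, strand = rep(strand, length(hit)),
             mismatches = mm[hit])
}

#' In silico PCR
#'
#' Pairs every forward binding site on the plus strand with every reverse
#' site on the minus strand lying strictly downstream, and extracts the
#' insert between the two primer footprints. Both primers are given 5'->3'
#' as printed in primer tables; the reverse primer is internally
#' reverse-complemented for plus-strand scanning.
#'
#' @param fwd,rev Forward and reverse [degenerate_primer()]s (or strings).
#' @param template Template sequence.
#' @param max_mm Mismatch budget per primer (default 4).
#' @param max_insert Maximum insert length reported (default 1000).
#' @return data.frame of amplicons: \code{insert_sequence},
#'   \code{insert_start}, \code{insert_end} (0-based, half-open, excluding
#'   both primer footprints), \code{fwd_mismatches}, \code{rev_mismatches}.
#' @examples
#' tpl <- paste0("AAAA", "ACGTAC", strrep("T", 10), "CCGGTT", "AAAA")
#' in_silico_pcr("ACGTAC", "AACCGG", tpl, max_mm = 0)
#' @export
in_silico_pcr <- function(fwd, rev, template, max_mm = 4, max_insert = 1000) {
  if (max_insert <= 0) stop("max_insert must be positive")
  template <- toupper(template)
  fseq <- .primer_seq(fwd)
  rseq <- .primer_seq(rev)
  fsites <- scan_binding_sites(fseq, template, max_mm, "plus")
  if (nrow(fsites) == 0)
    return(.empty_amplicons())
  rsites <- scan_binding_sites(rseq, template, max_mm, "minus")
  if (nrow(rsites) == 0)
    return(.empty_amplicons())
  lf <- nchar(fseq)
  lr <- nchar(rseq)
  combos <- expand.grid(fi = seq_len(nrow(fsites)), ri = seq_len(nrow(rsites)))
  ins_start <- fsites$start[combos$fi] + lf
  ins_end <- rsites$start[combos$ri]
  keep <- ins_end >= ins_start & (ins_end - ins_start) <= max_insert
  if (!any(keep)) return(.empty_amplicons())
  ins_start <- ins_start[keep]
  ins_end <- ins_end[keep]
  out <- data.frame(
    insert_sequence = substr(rep(template, length(ins_start)),
                             ins_start + 1L, ins_end),
    insert_start = ins_start,
    insert_end = ins_end,
    fwd_mismatches = fsites$mismatches[combos$fi[keep]],
    rev_mismatches = rsites$mismatches[combos$ri[keep]])
  out[order(out$insert_start, out$insert_end), , drop = FALSE]
}

.empty_amplicons <- function() {
  data.frame(insert_sequence = character(), insert_start = integer(),
             insert_end = integer(), fwd_mismatches = integer(),
             rev_mismatches = integer())
}
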