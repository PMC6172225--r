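#' Read a primer table
#'
#' Reads a TSV with columns \code{name}, \code{marker}, \code{direction},
#' \code{sequence} and returns a named list of [degenerate_primer()] objects.
#'
#' @param path Path to the TSV file.
#' @return Named list of \code{degenerate_primer}s; the \code{marker} column
#'   is kept as an attribute on each entry.
#' @export
read_primer_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "direction", "sequence")
  if (!all(need %in% names(tab)))
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  dirmap <- c(F = "forward", R = "reverse",
              forward = "forward", reverse = "reverse")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    p <- degenerate_primer(tab$name[i], tab$sequence[i],
                           dirmap[[tab$direction[i]]])
    attr(p, "marker") <- if ("marker" %in% names(tab)) tab$marker[i] else NA
    p
  })
  names(out) <- tab$name
  out
}

#' Primers used by the study design
#'
#' The packaged primer table: the COI minibarcode pair (forward
#' \code{nsCOIFo}, reverse \code{mlCOIintK}, plus the published variant
#' \code{mlCOIintR}) and the 18S V8 pair (\code{18S#4}, \code{18S#5_RC}).
#'
#' @param marker Optional marker filter, \code{"COI"} or \code{"18S"}.
#' @return Named list of [degenerate_primer()]s.
#' @examples
#' study_primers("COI")[["nsCOIFo"]]
#' @export
study_primers <- function(marker = NULL) {
  primers <- read_primer_table(
    system.file("extdata", "primers.tsv", package = "ednabar"))
  if (!is.null(marker))
    primers <- primers[vapply(primers, function(p) attr(p, "marker"), "") ==
                         marker]
  primers
}

#' Default COI minibarcode primer pair
#'
#' Convenience accessor for the pair used throughout the pipeline defaults:
#' forward \code{nsCOIFo} and reverse \code{mlCOIintK}.
#'
#' @return List with elements \code{fwd} and \code{rev}.
#' @export
coi_minibarcode_primers <- function() {
  p <- study_primers("COI")
  list(fwd = p[["nsCOIFo"]], rev = p[["mlCOIintK"]])
}
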