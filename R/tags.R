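#' Tag design rules
#'
#' Design constraints for MID (multiplex identifier) tags: a per-base
#' multiplicity cap ("no more than two identical bases"), no directly
#' repeated bases, and optionally balanced purine/pyrimidine content. Note
#' that one printed COI tag of the original design (\code{agagac}) violates
#' the strict multiplicity cap; the packaged tag scheme is shipped verbatim
#' and not re-validated.
#'
#' @param max_count_per_base Maximum occurrences of any single base
#'   (default 2).
#' @param forbid_adjacent_repeats Disallow identical adjacent bases
#'   (default TRUE).
#' @param require_purine_pyrimidine_balance Require
#'   \eqn{|\#\{A,G\} - \#\{C,T\}| \le 1} (default FALSE; the printed tags do
#'   not all satisfy strict balance, so this is off by default).
#' @param min_pairwise_hamming Minimum Hamming distance between generated
#'   tags (used by [generate_tag_set()]; default 0).
#' @return List of class \code{tag_rules}.
#' @export
tag_rules <- function(max_count_per_base = 2, forbid_adjacent_repeats = TRUE,
                      require_purine_pyrimidine_balance = FALSE,
                      min_pairwise_hamming = 0) {
  stopifnot(max_count_per_base >= 0, min_pairwise_hamming >= 0)
  structure(list(max_count_per_base = max_count_per_base,
                 forbid_adjacent_repeats = forbid_adjacent_repeats,
                 require_purine_pyrimidine_balance =
                   require_purine_pyrimidine_balance,
                 min_pairwise_hamming = min_pairwise_hamming),
            class = "tag_rules")
}

#' Validate a MID tag against design rules
#'
#' @param tag A/C/G/T string (case-insensitive).
#' @param rules A [tag_rules()] object.
#' @return Character vector of violated rule labels (empty when valid):
#'   \code{"base_count"}, \code{"adjacent_repeat"},
#'   \code{"purine_pyrimidine_balance"}.
#' @examples
#' validate_tag("actgac")  # character(0)
#' validate_tag("aaacgt")  # "base_count"
#' @export
validate_tag <- function(tag, rules = tag_rules()) {
  tag <- toupper(tag)
  bases <- strsplit(tag, "", fixed = TRUE)[[1]]
  if (length(bases) == 0) stop("tag must be non-empty")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("tag contains non-ACGT symbols: ", tag)
  bad <- character()
  if (any(table(bases) > rules$max_count_per_base))
    bad <- c(bad, "base_count")
  if (rules$forbid_adjacent_repeats && length(bases) > 1 &&
      any(bases[-1] == bases[-length(bases)]))
    bad <- c(bad, "adjacent_repeat")
  if (rules$require_purine_pyrimidine_balance) {
    pur <- sum(bases %in% c("A", "G"))
    if (abs(pur - (length(bases) - pur)) > 1)
      bad <- c(bad, "purine_pyrimidine_balance")
  }
  bad
}

#' Generate a set of MID tags
#'
#' Random bounded search for \code{n} tags of the given length that all pass
#' [validate_tag()] and are pairwise at Hamming distance at least
#' \code{rules$min_pairwise_hamming}. Deterministic for a fixed seed.
#'
#' @param length Tag length.
#' @param n Number of tags.
#' @param rules A [tag_rules()] object.
#' @param seed RNG seed.
#' @param max_tries Search budget (candidate draws; default \code{5000 * n}).
#' @return Character vector of \code{n} tags (lower case, as printed tag
#'   tables are conventionally written).
#' @export
generate_tag_set <- function(length, n, rules = tag_rules(), seed = 1,
                             max_tries = 5000 * n) {
  stopifnot(n >= 1, length >= 1)
  with_seed(seed, {
    tags <- character(0)
    tries <- 0
    while (base::length(tags) < n && tries < max_tries) {
      tries <- tries + 1
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (base::length(validate_tag(cand, rules))) next
      if (cand %in% tags) next
      if (base::length(tags) && rules$min_pairwise_hamming > 0) {
        dmin <- min(vapply(tags, function(t)
          sum(strsplit(t, "")[[1]] != strsplit(cand, "")[[1]]), 0L))
        if (dmin < rules$min_pairwise_hamming) next
      }
      tags <- c(tags, cand)
    }
    if (base::length(tags) < n)
      stop("tag search exhausted after ", max_tries,
           " tries: rules unsatisfiable for length ", length, ", n ", n)
    tolower(tags)
  })
}

#' Construct a tag scheme
#'
#' A tag scheme holds the per-marker forward and reverse MID tags and the
#' sample map linking each sample to its (forward tag, reverse tag) pair.
#' Tag matching at demultiplexing is exact.
#'
#' @param marker Marker name (\code{"COI"} or \code{"18S"}).
#' @param forward_tags,reverse_tags Character vectors of equal-length tags,
#'   unique within each direction.
#' @param sample_map data.frame with columns \code{sample},
#'   \code{forward_tag}, \code{reverse_tag}; every entry must reference a
#'   listed tag. Defaults to rank-matched pairs (F1+R1, F2+R2, ...).
#' @return Object of class \code{tag_scheme}.
#' @export
tag_scheme <- function(marker, forward_tags, reverse_tags, sample_map = NULL) {
  forward_tags <- tolower(forward_tags)
  reverse_tags <- tolower(reverse_tags)
  len <- unique(nchar(c(forward_tags, reverse_tags)))
  if (length(len) != 1)
    stop("all tags of a scheme must share one length, got: ",
         paste(len, collapse = ", "))
  if (anyDuplicated(forward_tags) || anyDuplicated(reverse_tags))
    stop("tags must be unique within a direction")
  if (is.null(sample_map)) {
    k <- min(length(forward_tags), length(reverse_tags))
    sample_map <- data.frame(sample = paste0("sample", seq_len(k)),
                             forward_tag = forward_tags[seq_len(k)],
                             reverse_tag = reverse_tags[seq_len(k)])
  }
  if (!all(sample_map$forward_tag %in% forward_tags) ||
      !all(sample_map$reverse_tag %in% reverse_tags))
    stop("sample_map references unlisted tags")
  structure(list(marker = marker, tag_length = len,
                 forward_tags = forward_tags, reverse_tags = reverse_tags,
                 sample_map = sample_map),
            class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat(sprintf("<tag_scheme> %s: %d-bp tags, %d forward, %d reverse, %d sample(s)\n",
              x$marker, x$tag_length, length(x$forward_tags),
              length(x$reverse_tags), nrow(x$sample_map)))
  invisible(x)
}

#' Tag scheme of the study design
#'
#' Loads the packaged tag table: five 6-bp tags per direction for COI and
#' five 4-bp tags per direction for 18S, shipped verbatim. The default
#' sample map pairs tags by rank.
#'
#' @param marker \code{"COI"} or \code{"18S"}.
#' @param sample_map Optional sample map (see [tag_scheme()]).
#' @return A [tag_scheme()].
#' @examples
#' study_tag_scheme("COI")
#' @export
study_tag_scheme <- function(marker = c("COI", "18S"), sample_map = NULL) {
  marker <- match.arg(marker)
  tab <- read.delim(system.file("extdata", "tags.tsv", package = "ednabar"),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$marker == marker, ]
  tag_scheme(marker,
             forward_tags = tab$tag[tab$direction == "forward"],
             reverse_tags = tab$tag[tab$direction == "reverse"],
             sample_map = sample_map)
}

#' Read/write tag schemes
#'
#' Tag schemes are stored as a TSV (\code{marker}, \code{direction},
#' \code{tag}) plus an optional sample-map CSV (\code{sample},
#' \code{forward_tag}, \code{reverse_tag}).
#'
#' @param path Tag TSV path.
#' @param marker Marker to select.
#' @param sample_map_csv Optional path to a sample-map CSV.
#' @return A [tag_scheme()].
#' @export
read_tag_scheme <- function(path, marker, sample_map_csv = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$marker == marker, ]
  if (nrow(tab) == 0) stop("no tags for marker ", marker)
  sm <- if (!is.null(sample_map_csv))
    utils::read.csv(sample_map_csv, stringsAsFactors = FALSE) else NULL
  tag_scheme(marker,
             forward_tags = tab$tag[tab$direction == "forward"],
             reverse_tags = tab$tag[tab$direction == "reverse"],
             sample_map = sm)
}
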