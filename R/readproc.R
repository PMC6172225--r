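#' Demultiplexing and filtering parameters
#'
#' Defaults are the study's processing thresholds: exact tags, up to four
#' mismatches per primer, mean Phred quality of at least 30, minimum insert
#' length 100 bp for COI and 140 bp for 18S, and a minimum of three reads
#' per OTU.
#'
#' @param tag_mismatches Allowed tag mismatches; only 0 (exact matching) is
#'   supported.
#' @param primer_mismatches Allowed mismatches per primer (default 4).
#' @param min_quality Minimum mean Phred score of a merged read (default 30).
#' @param min_length Named integer vector marker -> minimum insert length.
#' @param min_reads Minimum total reads per OTU (default 3).
#' @return List of class \code{demux_params}.
#' @export
demux_params <- function(tag_mismatches = 0, primer_mismatches = 4,
                         min_quality = 30,
                         min_length = c(COI = 100, "18S" = 140),
                         min_reads = 3) {
  if (tag_mismatches != 0)
    stop("tag matching is exact; tag_mismatches must be 0")
  stopifnot(primer_mismatches >= 0, min_quality >= 0, min_reads >= 0,
            all(min_length >= 0))
  structure(list(tag_mismatches = tag_mismatches,
                 primer_mismatches = primer_mismatches,
                 min_quality = min_quality, min_length = min_length,
                 min_reads = min_reads),
            class = "demux_params")
}

#' Read paired FASTQ files
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ files.
#' @return Object of class \code{read_pairs}: data.frame with
#'   \code{read_id}, \code{fwd_seq}, \code{rev_seq}, \code{fwd_qual},
#'   \code{rev_qual} (Phred+33 strings).
#' @export
read_paired_fastq <- function(r1, r2) {
  rd <- function(path) withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # harmless notice when FASTQ carries no extra metadata columns
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  f <- rd(r1)
  r <- rd(r2)
  if (length(f) != length(r))
    stop("R1 and R2 differ in read count")
  out <- data.frame(read_id = sub("\\s.*$", "", names(f)),
                    fwd_seq = as.character(f),
                    rev_seq = as.character(r),
                    fwd_qual = as.character(Biostrings::quality(f)),
                    rev_qual = as.character(Biostrings::quality(r)))
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Write paired FASTQ files
#'
#' @param pairs A \code{read_pairs} data.frame (see [read_paired_fastq()]).
#' @param r1,r2 Output paths.
#' @return Invisibly, \code{pairs}.
#' @export
write_paired_fastq <- function(pairs, r1, r2) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(pairs$fwd_seq, pairs$fwd_qual, pairs$read_id, r1)
  wr(pairs$rev_seq, pairs$rev_qual, pairs$read_id, r2)
  invisible(pairs)
}

# Mean Phred score of each Phred+33 quality string.
phred_means <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)
}

#' Merge read pairs by best ungapped overlap
#'
#' Aligns each forward read against the reverse complement of its mate at
#' every overlap of at least \code{min_overlap} bases and keeps the
#' quality-weighted best: agreements score \code{+min(qf, qr)}, conflicts
#' \code{-min(qf, qr)}. The consensus keeps the base with the higher Phred
#' at conflicts (quality = absolute Phred difference) and the shared base at
#' agreements (quality = max Phred). A pair is flagged unaligned when no
#' overlap reaches \code{min_overlap}, the best score is below
#' \code{min_score}, or fewer than \code{min_match_frac} of overlap
#' positions agree.
#'
#' @param pairs A \code{read_pairs} data.frame.
#' @param min_overlap Minimum overlap length in nt (default 10).
#' @param min_score Minimum quality-weighted score (default 0).
#' @param min_match_frac Minimum fraction of agreeing overlap positions
#'   (default 0.75).
#' @return Object of class \code{merged_reads}: data.frame with
#'   \code{read_id}, \code{sequence}, \code{quality},
#'   \code{overlap_length}, \code{aligned}.
#' @export
merge_pairs <- function(pairs, min_overlap = 10, min_score = 0,
                        min_match_frac = 0.75) {
  if (nrow(pairs) == 0) {
    out <- data.frame(read_id = character(), sequence = character(),
                      quality = character(), overlap_length = integer(),
                      aligned = logical())
    class(out) <- c("merged_reads", "data.frame")
    return(out)
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(pairs$rev_seq)))
  rq <- vapply(strsplit(pairs$rev_qual, "", fixed = TRUE),
               function(s) paste(rev(s), collapse = ""), "")
  res <- cpp_merge_pairs(pairs$fwd_seq, rc, pairs$fwd_qual, rq,
                         as.integer(min_overlap), min_score, min_match_frac)
  out <- data.frame(read_id = pairs$read_id, sequence = res$sequence,
                    quality = res$quality,
                    overlap_length = res$overlap_length,
                    aligned = res$aligned)
  class(out) <- c("merged_reads", "data.frame")
  out
}

#' Mean-quality filter for merged reads
#'
#' TRUE when the mean Phred score over the merged sequence is at least
#' \code{min_quality} (boundary inclusive).
#'
#' @param merged A \code{merged_reads} data.frame; all rows must be aligned.
#' @param min_quality Minimum mean Phred (default 30).
#' @return Logical vector, one value per read.
#' @export
quality_filter <- function(merged, min_quality = 30) {
  if (any(!merged$aligned))
    stop("quality_filter expects aligned merged reads; filter on `aligned` first")
  phred_means(merged$quality) >= min_quality
}

#' Demultiplex merged reads into samples
#'
#' A read is assigned when it carries the layout
#' \code{tag_F + forward primer + insert + revcomp(reverse primer) +
#' revcomp(tag_R)} (or the reverse complement of the whole construct) with
#' exact tags and at most \code{primer_mismatches} mismatches per primer,
#' and the tag pair maps to a sample. Tags and primers are trimmed from the
#' returned inserts. Unassigned reads carry a reason code:
#' \code{"unmerged"}, \code{"too_short"}, \code{"tag_mismatch"} (a flank is
#' not a listed tag), \code{"unknown_tag_pair"} (both flanks are listed
#' tags but the pair is unmapped), or \code{"primer_mismatch"}.
#'
#' @param merged A \code{merged_reads} data.frame (unaligned rows are
#'   binned as \code{"unmerged"}).
#' @param scheme A [tag_scheme()].
#' @param fwd,rev The marker's primers, 5'->3'.
#' @param params A [demux_params()].
#' @return Object of class \code{demux_result}: list with \code{samples}
#'   (named list sample -> character vector of inserts),
#'   \code{assignments} (read_id, sample, insert), \code{unassigned}
#'   (read_id, reason), and \code{counts}.
#' @export
demultiplex <- function(merged, scheme, fwd, rev, params = demux_params()) {
  fseq <- .primer_seq(fwd)
  rseq <- .primer_seq(rev)
  lf <- nchar(fseq); lr <- nchar(rseq); tl <- scheme$tag_length
  minlen <- 2L * tl + lf + lr
  rc_rev <- revcomp(rseq)
  sm <- scheme$sample_map
  keys <- paste(toupper(sm$forward_tag), revcomp(toupper(sm$reverse_tag)))
  ftags <- toupper(scheme$forward_tags)
  rtags_rc <- revcomp(toupper(scheme$reverse_tags))

  n <- nrow(merged)
  orient <- function(s) {
    len <- nchar(s)
    usable <- !is.na(s) & len >= minlen
    tagF <- substr(s, 1, tl)
    tagRrc <- substr(s, len - tl + 1, len)
    smp <- sm$sample[match(paste(tagF, tagRrc), keys)]
    fmm <- rmm <- rep(NA_integer_, length(s))
    idx <- which(usable)
    if (length(idx)) {
      fmm[idx] <- cpp_iupac_mismatch(fseq, substr(s, tl + 1, tl + lf)[idx])
      rmm[idx] <- cpp_iupac_mismatch(rc_rev,
                                     substr(s, len - tl - lr + 1, len - tl)[idx])
    }
    ok <- usable & !is.na(smp) & !is.na(fmm) & !is.na(rmm) &
      fmm <= params$primer_mismatches & rmm <= params$primer_mismatches
    list(ok = ok, sample = smp, usable = usable,
         insert = substr(s, tl + lf + 1, len - tl - lr),
         tags_listed = usable & tagF %in% ftags & tagRrc %in% rtags_rc,
         pair_known = usable & !is.na(smp),
         primer_ok = usable & !is.na(fmm) & !is.na(rmm) &
           fmm <= params$primer_mismatches & rmm <= params$primer_mismatches)
  }
  s1 <- merged$sequence
  s1[!merged$aligned] <- NA
  o1 <- orient(s1)
  s2 <- s1
  has <- which(!is.na(s1))
  if (length(has))
    s2[has] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(s1[has])))
  o2 <- orient(s2)

  sample <- ifelse(o1$ok, o1$sample, ifelse(o2$ok, o2$sample, NA))
  insert <- ifelse(o1$ok, o1$insert, ifelse(o2$ok, o2$insert, NA))
  assigned <- !is.na(sample)

  reason <- rep("tag_mismatch", n)
  reason[!merged$aligned] <- "unmerged"
  short <- merged$aligned & !(o1$usable | o2$usable)
  reason[short] <- "too_short"
  listed <- (o1$usable | o2$usable) & (o1$tags_listed | o2$tags_listed)
  reason[listed] <- "unknown_tag_pair"
  known <- o1$pair_known | o2$pair_known
  reason[known] <- "primer_mismatch"
  reason[assigned] <- NA

  assignments <- data.frame(read_id = merged$read_id[assigned],
                            sample = sample[assigned],
                            insert = insert[assigned])
  unassigned <- data.frame(read_id = merged$read_id[!assigned],
                           reason = reason[!assigned])
  samples <- split(assignments$insert, assignments$sample)
  # keep every mapped sample present, even when empty
  empty <- setdiff(sm$sample, names(samples))
  samples[empty] <- list(character(0))
  samples <- samples[sm$sample]
  structure(list(samples = samples, assignments = assignments,
                 unassigned = unassigned,
                 counts = list(input = n, assigned = sum(assigned),
                               unassigned = n - sum(assigned),
                               reasons = table(reason[!assigned]))),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("<demux_result> %d reads: %d assigned to %d sample(s), %d unassigned\n",
              x$counts$input, x$counts$assigned, length(x$samples),
              x$counts$unassigned))
  if (length(x$counts$reasons)) {
    r <- x$counts$reasons
    cat("  reasons:", paste(names(r), r, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Marker-specific insert length filter
#'
#' Keeps inserts of length at least \code{min_length[marker]} (inclusive:
#' a 100-nt COI insert passes).
#'
#' @param samples Named list sample -> character vector of inserts (e.g.
#'   the \code{samples} element of a [demultiplex()] result).
#' @param marker Marker name used to look up the threshold.
#' @param params A [demux_params()].
#' @return Named list of retained inserts per sample.
#' @export
length_filter <- function(samples, marker = "COI", params = demux_params()) {
  if (!marker %in% names(params$min_length))
    stop("no length threshold for marker ", marker)
  thr <- params$min_length[[marker]]
  lapply(samples, function(x) x[nchar(x) >= thr])
}
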