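#' Pipeline configuration
#'
#' Bundles all stage parameters with the study defaults: mean Phred >= 30,
#' 4 primer / 0 tag mismatches, insert length >= 100 (COI) or 140 (18S),
#' >= 3 reads per OTU, abundance-ratio threshold r = 0.05, 98\% assignment
#' identity and the 2\% 18S group filter. The stage order (merge, quality
#' filter, demultiplex, length filter, dereplicate, count filter, denoise,
#' assign, roll-up) is normative and validated; a reordered \code{stages}
#' vector is rejected.
#'
#' @param marker \code{"COI"} or \code{"18S"}.
#' @param scheme A [tag_scheme()] (default the study scheme for the
#'   marker).
#' @param fwd,rev Primers (default the marker's study primers).
#' @param demux A [demux_params()].
#' @param denoise A [denoise_params()].
#' @param assign An [assign_params()].
#' @param min_overlap Merge overlap floor in nt (default 10).
#' @param seed Seed governing any stochastic stage.
#' @param stages Stage order; must equal the canonical order.
#' @param output_dir Optional directory for intermediate TSV tables.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(marker = c("COI", "18S"), scheme = NULL,
                            fwd = NULL, rev = NULL,
                            demux = demux_params(),
                            denoise = denoise_params(),
                            assign = assign_params(),
                            min_overlap = 10, seed = 1,
                            stages = pipeline_stages(),
                            output_dir = NULL) {
  marker <- match.arg(marker)
  if (!identical(stages, pipeline_stages()))
    stop("stage order is fixed; got: ", paste(stages, collapse = " -> "))
  if (is.null(scheme)) scheme <- study_tag_scheme(marker)
  if (is.null(fwd) || is.null(rev)) {
    p <- study_primers(marker)
    dirs <- vapply(p, `[[`, "", "direction")
    if (is.null(fwd)) fwd <- if (marker == "COI")
      p[["nsCOIFo"]] else p[[which(dirs == "forward")[1]]]
    if (is.null(rev)) rev <- if (marker == "COI")
      p[["mlCOIintK"]] else p[[which(dirs == "reverse")[1]]]
  }
  stopifnot(inherits(demux, "demux_params"), inherits(denoise, "denoise_params"),
            inherits(assign, "assign_params"), inherits(scheme, "tag_scheme"))
  if (!marker %in% names(demux$min_length))
    stop("no length threshold configured for marker ", marker)
  structure(list(marker = marker, scheme = scheme, fwd = fwd, rev = rev,
                 demux = demux, denoise = denoise, assign = assign,
                 min_overlap = min_overlap, seed = seed, stages = stages,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Canonical pipeline stage order
#'
#' @return Character vector of stage names in execution order.
#' @export
pipeline_stages <- function() {
  c("merge", "quality_filter", "demultiplex", "length_filter",
    "dereplicate", "count_filter", "denoise", "assign", "rollup")
}

#' Run the full amplicon pipeline
#'
#' Executes merge, quality filter, demultiplex, length filter,
#' dereplicate, minimum-count filter, abundance-ratio denoising,
#' taxonomic assignment (with blocklist removal) and phylum roll-up, with
#' per-stage read/OTU accounting. Deterministic for a fixed config.
#'
#' @param pairs A \code{read_pairs} data.frame, or \code{NULL} when
#'   \code{r1}/\code{r2} FASTQ paths are given.
#' @param refdb A [reference_library()] used for assignment.
#' @param config A [pipeline_config()].
#' @param r1,r2 Optional paired FASTQ paths (read when \code{pairs} is
#'   NULL).
#' @return List of class \code{pipeline_run}: \code{merged},
#'   \code{demux}, \code{samples} (post length filter), \code{otu_table}
#'   (denoised), \code{assignments}, \code{rollup}, \code{species}
#'   (species-rank detections), \code{accounting}, \code{config}.
#' @export
run_pipeline <- function(pairs = NULL, refdb, config = pipeline_config(),
                         r1 = NULL, r2 = NULL) {
  if (is.null(pairs)) {
    if (is.null(r1) || is.null(r2))
      stop("supply either `pairs` or both `r1` and `r2`")
    pairs <- tryCatch(read_paired_fastq(r1, r2),
                      error = function(e) stop("merge stage: failed to read FASTQ input: ",
                                               conditionMessage(e), call. = FALSE))
  }
  acc <- list()
  note <- function(stage, n_in, n_out)
    acc[[length(acc) + 1]] <<- data.frame(stage = stage, input = n_in,
                                          retained = n_out)

  merged <- merge_pairs(pairs, min_overlap = config$min_overlap)
  ok <- merged$aligned
  note("merge", nrow(pairs), sum(ok))
  merged <- merged[ok, , drop = FALSE]

  qok <- quality_filter(merged, config$demux$min_quality)
  note("quality_filter", length(qok), sum(qok))
  merged <- merged[qok, , drop = FALSE]

  dm <- demultiplex(merged, config$scheme, config$fwd, config$rev,
                    config$demux)
  note("demultiplex", dm$counts$input, dm$counts$assigned)

  samples <- length_filter(dm$samples, config$marker, config$demux)
  note("length_filter", sum(lengths(dm$samples)), sum(lengths(samples)))

  tab <- dereplicate(samples)
  note("dereplicate", sum(lengths(samples)), sum(tab$counts))

  pre <- sum(tab$counts)
  tab <- min_count_filter(tab, config$demux$min_reads)
  note("count_filter", pre, sum(tab$counts))

  pre <- sum(tab$counts)
  tab <- denoise(tab, config$denoise)
  note("denoise", pre, sum(tab$counts))

  assignments <- assign_otus(tab, refdb, config$assign)
  assignments <- suppressMessages(
    remove_taxon(assignments, config$assign$blocklist))
  assigned_reads <- sum(tab$counts[match(
    assignments$otu_id[assignments$rank != "unassigned"], tab$otu_id), ])
  note("assign", sum(tab$counts), assigned_reads)

  roll <- phylum_rollup(assignments, tab, config$assign)
  if (config$marker == "18S")
    roll <- abundance_filter_18s(roll, config$assign$min_fraction_18s)
  note("rollup", assigned_reads, sum(roll))

  sp <- assignments[assignments$rank == "species", , drop = FALSE]
  species <- data.frame(
    species = sort(unique(sp$taxon)),
    n_otus = as.integer(table(sp$taxon)[sort(unique(sp$taxon))]),
    reads = vapply(sort(unique(sp$taxon)), function(t)
      sum(tab$counts[match(sp$otu_id[sp$taxon == t], tab$otu_id), ]), 0))
  rownames(species) <- NULL

  accounting <- do.call(rbind, acc)
  run <- structure(list(merged_reads = nrow(merged), demux = dm,
                        samples = samples, otu_table = tab,
                        assignments = assignments, rollup = roll,
                        species = species, accounting = accounting,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(config$output_dir)) .write_run(run, config$output_dir)
  run
}

.write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(run$accounting, file.path(dir, "accounting.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  otu_table_frame(run$otu_table, file.path(dir, "otu_table.tsv"))
  write.table(run$assignments, file.path(dir, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$species, file.path(dir, "species.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(run$rollup), file.path(dir, "rollup.csv"))
  jsonlite::write_json(
    list(species_detected = nrow(run$species),
         otus = length(run$otu_table$otu_id),
         accounting = run$accounting),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s: %d species at species rank, %d OTUs\n",
              x$config$marker, nrow(x$species), length(x$otu_table$otu_id)))
  print(x$accounting, row.names = FALSE)
  invisible(x)
}

#' Per-stage retention accounting
#'
#' @param run A [run_pipeline()] result.
#' @return data.frame with \code{stage}, \code{input}, \code{retained}
#'   read counts, in execution order; retained counts are non-increasing
#'   across the filtering stages.
#' @export
accounting_report <- function(run) run$accounting
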