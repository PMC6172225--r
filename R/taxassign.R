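#' The higher metazoan groups used for roll-up
#'
#' The 19 higher taxonomic groups to which assigned OTUs are aggregated;
#' OTUs outside these groups are dropped from community analyses.
#'
#' @return Character vector of 19 group names.
#' @export
metazoan_groups <- function() {
  c("Annelida", "Arthropoda", "Bryozoa", "Chaetognatha", "Cnidaria",
    "Craniata", "Ctenophora", "Echinodermata", "Entoprocta", "Gastrotricha",
    "Hemichordata", "Mollusca", "Nematoda", "Nemertea", "Platyhelminthes",
    "Porifera", "Rotifera", "Tunicata", "Xenacoelomorpha")
}

#' Taxonomic assignment parameters
#'
#' @param min_identity Minimum global-alignment identity for an assignment
#'   (default 0.98, the study's 98\% similarity rate).
#' @param allowed_groups Higher groups retained at roll-up (default the 19
#'   of [metazoan_groups()]).
#' @param min_fraction_18s Per-sample relative-abundance floor for the 18S
#'   group filter (default 0.02; strictly-less-than removal).
#' @param blocklist Taxa always removed from assignments (default
#'   \code{"Homo sapiens"}; terrestrial contaminants can be appended).
#' @return List of class \code{assign_params}.
#' @export
assign_params <- function(min_identity = 0.98,
                          allowed_groups = metazoan_groups(),
                          min_fraction_18s = 0.02,
                          blocklist = "Homo sapiens") {
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  structure(list(min_identity = min_identity,
                 allowed_groups = allowed_groups,
                 min_fraction_18s = min_fraction_18s,
                 blocklist = blocklist),
            class = "assign_params")
}

#' Global-alignment identity between two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' gap -1; identity is matched columns divided by alignment length.
#' Symmetric and in [0, 1].
#'
#' @param a,b DNA strings.
#' @return Identity fraction.
#' @examples
#' global_identity("ACGT", "ACGA")  # 0.75
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  unname(cpp_nw_identity(toupper(a), toupper(b))[1, "identity"])
}

# Lowest common ancestor of lineages (rows of rank columns, shallow->deep).
# Returns list(taxon, rank); rank "unassigned" when even the shallowest
# rank disagrees.
.lineage_lca <- function(lin) {
  for (rank in rev(names(lin))) {
    vals <- unique(lin[[rank]])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 1) return(list(taxon = vals, rank = rank))
  }
  list(taxon = NA_character_, rank = "unassigned")
}

#' Assign OTUs against a reference library
#'
#' For each query sequence the best global-alignment identity over the
#' reference library is found. Below \code{min_identity} the OTU is
#' unassigned. Otherwise all references tying at the best identity vote:
#' the OTU is assigned the lowest common ancestor of their lineages
#' (species when unanimous; e.g. two species with identical references
#' collapse to their genus). Tie resolution is order-invariant.
#'
#' @param query Named character vector of OTU sequences (names = otu ids),
#'   or an [otu_table][dereplicate()].
#' @param refdb A [reference_library()] with lineage columns.
#' @param params An [assign_params()].
#' @return data.frame of class \code{otu_assignments}: \code{otu_id},
#'   \code{best_identity}, \code{taxon}, \code{rank}, \code{phylum},
#'   \code{n_best}, \code{ref_ids} (comma-separated supporting specimens).
#' @export
assign_otus <- function(query, refdb, params = assign_params()) {
  if (inherits(query, "otu_table")) query <- query$sequence
  if (is.null(names(query))) names(query) <- sprintf("OTU_%05d", seq_along(query))
  if (nrow(refdb) == 0) stop("empty reference library")
  ranks <- .lineage_ranks(refdb)
  if (!"species" %in% ranks) stop("reference library must carry species lineage")
  if (anyNA(refdb$species)) stop("reference record without lineage")
  refseq <- toupper(refdb$sequence)
  rows <- lapply(seq_along(query), function(i) {
    nw <- cpp_nw_identity(toupper(query[[i]]), refseq)
    ident <- nw[, "identity"]
    best <- max(ident)
    if (best < params$min_identity) {
      return(data.frame(otu_id = names(query)[i], best_identity = best,
                        taxon = NA_character_, rank = "unassigned",
                        phylum = NA_character_, n_best = 0L,
                        ref_ids = NA_character_))
    }
    hits <- which(ident >= best - 1e-12)
    lca <- .lineage_lca(refdb[hits, ranks, drop = FALSE])
    phyl <- unique(refdb$phylum[hits])
    data.frame(otu_id = names(query)[i], best_identity = best,
               taxon = lca$taxon, rank = lca$rank,
               phylum = if (length(phyl) == 1) phyl else NA_character_,
               n_best = length(hits),
               ref_ids = paste(sort(refdb$specimen_id[hits]), collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("otu_assignments", "data.frame")
  out
}

#' Remove assignments to a blocklisted taxon
#'
#' Drops all assignments to the named taxa (by default \emph{Homo
#' sapiens}, the study's standing contaminant rule; terrestrial bycatch
#' species can be passed the same way). The number removed is reported as
#' an attribute and a message.
#'
#' @param assignments An \code{otu_assignments} data.frame.
#' @param taxon Character vector of taxa to remove.
#' @return Filtered assignments with attribute \code{removed}.
#' @export
remove_taxon <- function(assignments, taxon = "Homo sapiens") {
  drop <- !is.na(assignments$taxon) & assignments$taxon %in% taxon
  out <- assignments[!drop, , drop = FALSE]
  attr(out, "removed") <- sum(drop)
  if (sum(drop))
    message("removed ", sum(drop), " assignment(s) to ",
            paste(taxon, collapse = ", "))
  out
}

#' Roll read counts up to higher taxonomic groups
#'
#' Sums reads per sample per allowed higher group over the assigned OTUs.
#' OTUs whose phylum is missing or outside \code{allowed_groups} are
#' dropped and tallied in the \code{dropped} attribute.
#'
#' @param assignments An \code{otu_assignments} data.frame (with
#'   \code{phylum}).
#' @param tab The matching [otu_table][dereplicate()].
#' @param params An [assign_params()].
#' @return Numeric matrix samples x groups with attribute \code{dropped}
#'   (OTU count excluded).
#' @export
phylum_rollup <- function(assignments, tab, params = assign_params()) {
  m <- match(assignments$otu_id, tab$otu_id)
  if (anyNA(m)) stop("assignments reference OTUs absent from the table")
  keep <- !is.na(assignments$phylum) &
    assignments$phylum %in% params$allowed_groups
  groups <- sort(unique(assignments$phylum[keep]))
  out <- matrix(0, nrow = ncol(tab$counts), ncol = length(groups),
                dimnames = list(colnames(tab$counts), groups))
  for (i in which(keep)) {
    g <- assignments$phylum[i]
    out[, g] <- out[, g] + tab$counts[m[i], ]
  }
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Relative-abundance group filter (18S rule)
#'
#' Within each sample, zeroes groups holding strictly less than
#' \code{min_fraction} of the sample's reads (a group at exactly the
#' threshold is retained). Samples with zero total are left unchanged with
#' a warning.
#'
#' @param mat Samples x groups count matrix (e.g. from [phylum_rollup()]).
#' @param min_fraction Threshold (default 0.02).
#' @return Filtered matrix.
#' @export
abundance_filter_18s <- function(mat, min_fraction = 0.02) {
  tot <- rowSums(mat)
  if (any(tot == 0))
    warning("sample(s) with zero reads left unchanged: ",
            paste(rownames(mat)[tot == 0], collapse = ", "))
  nz <- tot > 0
  frac <- mat[nz, , drop = FALSE] / tot[nz]
  mat[nz, ][frac < min_fraction] <- 0
  mat
}
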