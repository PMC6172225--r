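---
title: "Methods: minibarcode metabarcoding from primer to permutation test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minibarcode metabarcoding from primer to permutation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednabar)
```

`ednabar` implements the computational chain of a COI-minibarcode /
18S-V8 eDNA metabarcoding workflow: in silico primer evaluation, tagged
paired-end read processing, abundance-graph denoising, identity-threshold
taxonomic assignment with LCA tie resolution, and permutation community
statistics, exercised end to end on synthetic mock communities. This
vignette records the models, the parameters that matter, and the design
choices made where the underlying procedure is conventionally
under-specified.

## Degenerate primer matching

Degenerate primers are strings over the IUPAC alphabet; each symbol
denotes a set of bases (`R` = {A,G}, `N` = {A,C,G,T}, ...). A primer
symbol *accepts* a template symbol when the template's base set is
contained in the primer symbol's set. For plain A/C/G/T templates this is
ordinary set membership and the mismatch count of a window equals the
minimum Hamming distance over all plain-DNA expansions of the primer
(verified in the tests against brute-force enumeration; the most
degenerate shipped primer, nsCOIFo, has 9216 expansions). The containment
rule makes ambiguity in *references* conservative: an `N` in a reference
sequence is only accepted by an `N` in the primer, so uncertain template
positions count against a binding site rather than for it.

In silico PCR pairs every forward site on the plus strand with every
reverse site on the minus strand strictly downstream, under a per-primer
mismatch budget (default 4, the budget used throughout). Coordinates are
0-based and half-open, the insert excludes both primer footprints, and
reverse primers are always supplied 5'→3' as printed in primer tables and
reverse-complemented internally. `max_insert` defaults to 1000 nt purely
to suppress pathological pairings on concatemer-like templates.

Species-level evaluation runs on the *species consensus*: per alignment
column, the smallest IUPAC code covering every non-gap base observed.
Consensus requires pre-aligned (equal-length) input; multiple sequence
alignment itself is out of scope for the package. Minibarcode
discrimination uses the uncorrected p-distance with a 2% floor; because
consensus sequences can carry ambiguity codes, equal-length comparisons
treat overlapping base sets as a match (disjoint sets as a difference),
and gapped positions are excluded from the denominator.

## Tags and demultiplexing

Sample (MID) tags are fixed-length 5' extensions: 6 bp for COI, 4 bp for
18S, five per direction, shipped verbatim as a packaged fixture. The
validator interprets "no more than two identical bases" as a per-base
multiplicity cap (a run-length reading is redundant with the separate
no-adjacent-repeat rule). One printed COI reverse tag, `agagac`, violates
that cap; we ship the printed tags unmodified and treat the
purine/pyrimidine balance rule as optional for the same reason — fidelity
to the shipped design wins over fidelity to its prose description. Tag
generation is a seeded bounded random search with a minimum pairwise
Hamming distance option; it raises an explicit exhaustion error when the
constraints are unsatisfiable.

Demultiplexing requires the layout
`tag_F + forward primer + insert + revcomp(reverse primer) +
revcomp(tag_R)` in either orientation, with **exact** tags and at most 4
mismatches per primer. Both orientations are searched because amplicon
orientation is not fixed on the flow cell. Unassigned reads carry reason
codes (`unmerged`, `too_short`, `tag_mismatch`, `unknown_tag_pair`,
`primer_mismatch`) so losses are auditable; assigned plus unassigned
always equals the input count.

## Merging and quality

Read pairs are merged by the best ungapped overlap of the forward read
against the reverse complement of its mate, scored by quality-weighted
matches (`+min(qf,qr)` for agreement, `−min(qf,qr)` for conflict).
Consensus keeps the shared base with quality `max(qf,qr)` at agreements
and the higher-Phred base with quality `|qf − qr|` at conflicts. A merge
is rejected below a 10-nt overlap (guarding against chance overlaps at
125-nt reads), a non-positive score, or under 75% agreeing overlap
positions. The downstream "quality score of 30" rule is applied as *mean
merged Phred ≥ 30*; the historical tool applies an alignment-score
criterion it does not document, and the mean rule is a simple, monotone
surrogate kept explicit in `demux_params()` so it can be swapped.

## Dereplication and abundance-graph denoising

Identical sequences within a sample are collapsed into OTUs; sequences of
different lengths are distinct OTUs, and dereplication conserves
per-sample read totals. OTUs with fewer than 3 reads in total are
dropped (inclusive threshold). Within each sample a directed graph is
built: an edge `u → v` when the sequences are within Levenshtein distance
`d = 1` and `count(v)/count(u) ≤ r = 0.05`. Any `r < 1` forces a strict
count decrease along edges, so the graph is acyclic; `r ≥ 1` is rejected.
Statuses follow from the edges: `singleton` (no incident edges),
`internal` (at least one incoming edge — incoming beats outgoing, our
recorded resolution of a case the source procedure leaves undocumented),
`head` (outgoing only). An OTU is discarded only when it is internal in
*every* sample where it occurs; this conservative cross-sample reading
never deletes a sequence that heads any sample.

Distance-1 neighbour pairs are found by key hashing (masked-position keys
for substitutions, deletion keys for indels) in time linear in total
sequence length, so tables with thousands of OTUs avoid an all-pairs
edit-distance matrix; `d > 1` falls back to `utils::adist` and is only
intended for small tables.

## Taxonomic assignment

Identity is defined once, everywhere, as matched columns over alignment
length of an end-to-end Needleman–Wunsch alignment (match +1,
mismatch/gap −1; deterministic diagonal-first traceback). The historical
workflow used two different engines with undefined identity conventions;
a single global-alignment definition keeps the 98% threshold coherent
across reference databases, and the tests pin the implementation to an
independent dynamic-programming oracle. An OTU below 98% best identity is
unassigned. Otherwise all references *tying at the best identity* vote:
the assignment is the lowest common ancestor of their lineages — species
when unanimous, genus when two species' references are identical, and so
on. Restricting the LCA to the tied best set (rather than all hits above
the threshold) keeps a unique 100% hit at species rank even when another
species sits at 98.5%.

Assignments to *Homo sapiens* are always removed (the study's standing
contaminant rule); terrestrial bycatch can be appended to the same
blocklist. Reads are rolled up to 19 higher metazoan groups; OTUs outside
the list are dropped and tallied. For 18S, groups holding strictly less
than 2% of a sample's reads are zeroed (a group at exactly 2% survives).

## Permutation statistics

All permutation machinery is implemented in the package; `vegan` and
`MASS` appear only as independent oracles in the test suite.

* **Mantel**: Pearson correlation of upper-triangle entries, permuting
  one matrix's labels jointly; two-sided on `|r|`. An exact mode
  enumerates all `n!` permutations for small `n`.
* **PERMANOVA**: pseudo-F from sums of squared distances
  (`SS_total = Σ d²/n`, within-group analogues), free label permutation,
  pairwise contrasts with the same statistic on each pair's submatrix.
  Groups of one sample are rejected.
* **PERMDISP**: principal-coordinate embedding keeping negative
  eigenvalues as imaginary axes whose squared contributions are
  subtracted; distances to group centroids; one-way F with label
  permutation of the distances (centroids are not recomputed per
  permutation, matching common practice).
* **nMDS**: isotonic regression of configuration distances on
  dissimilarity ranks plus SMACOF (Guttman transform) updates, best of
  several starts (PCoA start first, then random), stress-1 tracked and
  non-increasing up to numerical tolerance; all-equal dissimilarities are
  flagged as degenerate.
* **Rarefaction**: the analytic hypergeometric expectation
  `E[S_d] = Σ_i (1 − C(N−N_i, d)/C(N, d))`, exact at `d = N`.

Permutation p-values use the `(1 + exceedances)/(1 + n_perm)` convention:
the observed statistic counts itself, so p is never 0 and the test has
exact size at the nominal level when `(n_perm + 1) × α` is an integer.
The standardisation called "equalised unit total" divides each variable
(sequence counts or CTD measurements) by its column total.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested: a 30-species equimolar community (the artificial sample's size),
124-nt minibarcode inserts, 125-nt paired-end reads, 10^5 read pairs,
0.5% per-base substitution error, a 1% single-breakpoint two-parent
chimera fraction, and Phred qualities from a linear-decay model (mean 37,
0.02/cycle decay, SD 3, clamped to [2, 40]) — values a sequencing-era
practitioner would call typical where the design does not state one.
Species inserts derive from a common scaffold with a *guaranteed*
pairwise difference floor of `⌈0.05 × 124⌉ = 7` positions (bounded
re-drawing; unsatisfiable settings raise an error), comfortably above the
4% divergence at which species-level assignment is unambiguous at a 98%
identity threshold. Every template embeds one concrete expansion of each
primer, so amplifiability is exact by construction and any failures the
evaluator reports are planted deliberately.

The error model is substitution-only by default so planted-variant
bookkeeping stays exact for the denoising tests; chimeras are always
single-breakpoint with two parents, which suffices to exercise the
internal-OTU discard path. The generator emulates neither real
intraspecific haplotype structure, nor PCR amplification bias, nor indel
sequencing errors, nor eDNA shedding/degradation — passing tests
therefore demonstrate the correctness of the *computational chain*, not
field performance on real communities, where reference-library coverage
and primer bias dominate.

Determinism is strict: every stochastic function routes its seed through
one RNG scope, identical seeds give byte-identical FASTQ, and the
pipeline is single-threaded by contract.

## Problem sizes and numerical notes

The test suite runs the full pipeline at 10^5 read pairs (about half a
minute on one CPU) and calibrates Mantel and PERMANOVA type-I error with
1000 null simulations at 199 permutations and 12 samples, where the
rejection rate at α = 0.05 must fall within the 99% binomial band.
Oracle comparisons use 1000 random windows per printed primer, 200 random
sequence pairs up to 30 nt for the alignment DP, and 300-draw Monte-Carlo
resampling (3 SE band) for rarefaction. Floating-point ties in
permutation exceedance counts are broken with a 1e-12 slack toward
exceedance, which only ever makes p-values more conservative.

## Known limitations

* Consensus building requires pre-aligned per-species sequences; the
  package does not construct multiple alignments.
* Tag matching is exact by design; no error-correcting codebooks.
* `d > 1` denoising is quadratic and only for small tables.
* PERMANOVA is one-way with free permutation; no nested or restricted
  permutation schemes.
* The 18S path shares all machinery but its fragment-length diversity is
  only represented through the length filter and the merge-length guard.
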