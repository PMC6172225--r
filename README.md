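# ednabar

Marine eDNA metabarcoding of metazoan communities with degenerate COI
minibarcode and 18S rDNA (V8) primers, as one tested R toolkit.

Environmental DNA (eDNA) metabarcoding detects animals from the traces of
DNA they shed into seawater: filtered water is amplified with tagged,
degenerate primers, sequenced as short paired-end reads, and the reads are
traced back to species through a barcode reference library. `ednabar`
implements the full computational chain that such a study needs, for
bioinformaticians and molecular ecologists who want every step open,
testable and reproducible:

* **In silico PCR and primer evaluation** — IUPAC-degenerate primer
  matching under a mismatch budget (a primer symbol accepts a template
  symbol when the template's base set is contained in the primer's),
  binding-site scans, amplicon extraction, per-species amplifiability and
  the species-discrimination power of the excised minibarcode (pairwise
  uncorrected p-distance against a dissimilarity floor, default 2%).
* **MID-tag toolkit** — validation and generation of the fixed-length 5'
  sample tags (6 bp for COI, 4 bp for 18S) under the design rules
  (per-base multiplicity cap, no adjacent repeats, optional
  purine/pyrimidine balance), plus the printed tag and primer tables as
  packaged fixtures.
* **Read processing** — quality-weighted ungapped overlap merging of
  125-bp paired ends, mean-Phred >= 30 filtering, exact-tag /
  4-mismatch-primer demultiplexing with trimming and auditable reason
  codes, and marker-specific length filters (COI >= 100 nt, 18S >= 140 nt).
* **Denoising** — exact length-sensitive dereplication into OTUs, then an
  abundance-ratio variant graph per sample: a directed edge runs from a
  sequence to a putative error variant when they are within Levenshtein
  distance 1 and the variant holds at most r = 0.05 of the parent's reads.
  OTUs are labelled `head`, `internal` or `singleton`; internal OTUs
  (likely PCR/sequencing artifacts and chimeras) are discarded.
* **Taxonomic assignment** — global-alignment identity (Needleman-Wunsch,
  match +1, mismatch/gap -1) against a reference library at a 98%
  threshold; ties at the best identity collapse to the lowest common
  ancestor of their lineages, *Homo sapiens* (and any further blocklist)
  is removed, reads are rolled up to 19 higher metazoan groups, and 18S
  samples drop groups below 2% relative abundance.
* **Community statistics** — Euclidean and Sorensen distances, Mantel
  tests, one-way PERMANOVA with pairwise contrasts (pseudo-F from
  within/between sums of squared distances, 9999 free label
  permutations), PERMDISP (distances to group centroids in a
  principal-coordinate embedding), non-metric multidimensional scaling
  (isotonic regression + SMACOF updates) and analytic hypergeometric
  rarefaction. All permutation machinery is implemented in the package;
  `vegan` is used only as an independent cross-check in the tests.
* **Synthetic data** — a generator for barcode libraries with controlled
  inter/intra-specific divergence and planted primer sites, equimolar or
  log-normal mock communities, error-prone chimera-bearing tagged read
  pairs with Phred qualities, and CTD-like abiotic metadata, so the whole
  chain runs and is tested without any external download.

## Worked example

Simulate a 30-species reference library with the study's COI minibarcode
primers planted in every template, build an equimolar mock community,
sequence it in silico, and run the full pipeline:

```r
library(ednabar)

pars    <- sim_params(n_species = 30, seed = 1)
sim_lib <- simulate_reference_library(pars)
primers <- coi_minibarcode_primers()
primers$fwd
#> <degenerate_primer> nsCOIFo (forward) THATRATNGGNGGNTTYGGNAAHTG [25 nt, degeneracy 9216]

evaluate_amplifiability(sim_lib$library, primers$fwd, primers$rev)
#> <amplifiability_report> 30 species (0 failed, 0.0%); 30 specimens (0 failed, 0.0%)

mb <- extract_minibarcodes(sim_lib$library, primers$fwd, primers$rev)
discrimination_power(mb)
#> <discrimination_report> 30 species, 100.0% distinguishable at 2% dissimilarity; 0 confounded pair(s)

comm  <- simulate_mock_community(sim_lib)        # equimolar shares, 1/30 each
reads <- simulate_reads(sim_lib, comm, depth = 20000)

# reference DB = the fragments the primer pair can amplify (virtual PCR)
refdb <- minibarcode_refdb(sim_lib$library, primers$fwd, primers$rev)
run <- run_pipeline(reads$pairs, refdb, pipeline_config("COI"))
run
#> <pipeline_run> COI: 30 species at species rank, 30 OTUs
#>           stage input retained
#>           merge 20000    20000
#>  quality_filter 20000    20000
#>     demultiplex 20000    18852
#>   length_filter 18852    18852
#>     dereplicate 18852    18852
#>    count_filter 18852    10738
#>         denoise 10738    10029
#>          assign 10029    10029
#>          rollup 10029    10029
```

Reading the accounting table: every read pair merges (the 187-nt construct
leaves a 63-nt overlap), ~6% of reads are lost at demultiplexing because a
substitution error fell inside a tag (tags are matched exactly), the
minimum-of-three-reads filter removes the long tail of rare error
variants, denoising discards the remaining 1-substitution variants as
`internal`, and every one of the 30 planted species is recovered at
species rank with identity 1.0:

```r
head(run$species, 3)
#>               species n_otus reads
#> 1 Genus001 species001      1   343
#> 2 Genus002 species002      1   334
#> 3 Genus003 species003      1   333
```

A thin command-line wrapper over the same functions ships in
`inst/exec/ednabar` (`simulate`, `run`, `eval-primers` subcommands).

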