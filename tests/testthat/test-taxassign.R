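test_that("global identity matches direct cases and is symmetric", {
  expect_equal(global_identity("ACGT", "ACGT"), 1.0)
  expect_equal(global_identity("ACGT", "ACGA"), 0.75)
  set.seed(51)
  for (i in 1:10) {
    a <- rand_dna(sample(5:25, 1)); b <- rand_dna(sample(5:25, 1))
    expect_equal(global_identity(a, b), global_identity(b, a))
    expect_gte(global_identity(a, b), 0)
    expect_lte(global_identity(a, b), 1)
  }
  expect_error(global_identity("", "ACGT"), "non-empty")
})

test_that("alignment scores agree with exhaustive dynamic programming", {
  set.seed(52)
  for (i in 1:60) {
    a <- rand_dna(sample(5:30, 1))
    b <- rand_dna(sample(5:30, 1))
    nw <- ednabar:::cpp_nw_identity(a, b)
    expect_equal(unname(nw[1, "score"]), oracle_nw_score(a, b),
                 info = paste(a, b))
    expect_equal(unname(nw[1, "identity"]),
                 unname(nw[1, "matches"] / nw[1, "columns"]))
  }
})

toy_refdb <- function() {
  reference_library(data.frame(
    specimen_id = c("r1", "r2", "r3", "r4"),
    phylum = c("Arthropoda", "Arthropoda", "Mollusca", "Arthropoda"),
    genus = c("Carcinus", "Carcinus", "Sepiola", "Temora"),
    species = c("Carcinus maenas", "Carcinus aestuarii",
                "Sepiola tridens", "Temora longicornis"),
    sequence = c(strrep("ACGT", 25),
                 paste0(strrep("ACGT", 20), strrep("GGTA", 5)),
                 strrep("TTGA", 25),
                 strrep("CAGT", 25))))
}

test_that("unique best hits assign at species rank with identity 1", {
  db <- toy_refdb()
  a <- assign_otus(c(o1 = strrep("ACGT", 25)), db)
  expect_equal(a$taxon, "Carcinus maenas")
  expect_equal(a$rank, "species")
  expect_equal(a$best_identity, 1.0)
  expect_equal(a$phylum, "Arthropoda")
})

test_that("tied best hits collapse to the lowest common ancestor", {
  db <- toy_refdb()
  db$sequence[2] <- db$sequence[1]  # two congeneric species, identical refs
  a <- assign_otus(c(o1 = db$sequence[1]), db)
  expect_equal(a$taxon, "Carcinus")
  expect_equal(a$rank, "genus")
  expect_equal(a$n_best, 2)
  # order invariance of tie resolution
  a2 <- assign_otus(c(o1 = db$sequence[1]), db[c(4, 3, 2, 1), ])
  expect_equal(a2$taxon, a$taxon)
  expect_equal(a2$rank, a$rank)
})

test_that("identities below the 98% threshold are unassigned", {
  db <- toy_refdb()
  q <- db$sequence[1]
  for (p in c(5, 25, 45)) # 3 substitutions: identity 0.97
    substr(q, p, p) <- chartr("ACGT", "CGTA", substr(q, p, p))
  a <- assign_otus(c(o1 = q), db)
  expect_equal(a$rank, "unassigned")
  expect_true(is.na(a$taxon))
  expect_equal(a$best_identity, 0.97)
  # two substitutions (identity 0.98) stay assigned: inclusive threshold
  q2 <- db$sequence[1]
  for (p in c(5, 25))
    substr(q2, p, p) <- chartr("ACGT", "CGTA", substr(q2, p, p))
  expect_equal(assign_otus(c(o1 = q2), db)$rank, "species")
})

test_that("raising the identity threshold never rescues an unassigned OTU", {
  set.seed(53)
  db <- toy_refdb()
  for (i in 1:10) {
    q <- rand_dna(100)
    r1 <- assign_otus(c(o = q), db, assign_params(min_identity = 0.90))
    r2 <- assign_otus(c(o = q), db, assign_params(min_identity = 0.98))
    if (r1$rank == "unassigned") expect_equal(r2$rank, "unassigned")
  }
})

test_that("mutated queries recover their species on a divergent library", {
  sl <- simulate_reference_library(sim_params(n_species = 15, seed = 54))
  refdb <- sl$library
  refdb$sequence <- sl$species$insert[match(refdb$species,
                                            sl$species$species)]
  set.seed(55)
  for (i in seq_len(nrow(sl$species))) {
    q <- sl$species$insert[i]
    p <- sample.int(124, 1)  # mutate <= 1% of positions
    substr(q, p, p) <- chartr("ACGT", "CGTA", substr(q, p, p))
    a <- assign_otus(c(o = q), refdb)
    expect_equal(a$taxon, sl$species$species[i])
    expect_equal(a$rank, "species")
  }
})

test_that("blocklisted taxa are removed with an audit count", {
  asn <- data.frame(otu_id = c("o1", "o2", "o3"),
                    best_identity = 1, taxon = c("Homo sapiens", "Sus scrofa",
                                                 "Temora longicornis"),
                    rank = "species", phylum = c("Craniata", "Craniata",
                                                 "Arthropoda"),
                    n_best = 1, ref_ids = "x")
  out <- suppressMessages(remove_taxon(asn))
  expect_equal(attr(out, "removed"), 1)
  expect_false("Homo sapiens" %in% out$taxon)
  out2 <- suppressMessages(remove_taxon(asn, c("Homo sapiens", "Sus scrofa")))
  expect_equal(attr(out2, "removed"), 2)
  out3 <- suppressMessages(remove_taxon(out2))
  expect_equal(attr(out3, "removed"), 0)
  expect_equal(nrow(out3), 1)
})

test_that("phylum roll-up sums reads and drops out-of-scope groups", {
  tab <- dereplicate(list(s1 = rep(c("AAAA", "CCCC", "GGGG"), c(10, 20, 5)),
                          s2 = rep(c("AAAA", "GGGG"), c(7, 3))))
  asn <- data.frame(otu_id = tab$otu_id[match(c("AAAA", "CCCC", "GGGG"),
                                              tab$sequence)],
                    best_identity = 1,
                    taxon = c("a", "b", "c"), rank = "species",
                    phylum = c("Arthropoda", "Arthropoda", "Bacillariophyta"),
                    n_best = 1, ref_ids = "x")
  roll <- phylum_rollup(asn, tab)
  expect_equal(dim(roll), c(2, 1))
  expect_equal(unname(roll[, "Arthropoda"]), c(30, 7))
  expect_equal(attr(roll, "dropped"), 1)  # the non-metazoan OTU
  expect_true(all(rowSums(roll) <= colSums(tab$counts)))
})

test_that("the 18S abundance filter is strictly less-than 2%", {
  mat <- matrix(c(19, 20, 961, 1000, 0, 0), nrow = 2,
                dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  # s1: A = 19/1000 = 1.9% -> zeroed; s2: A = 20/1020 > ... pick exact cases
  mat <- rbind(s1 = c(A = 19, B = 981),   # 1.9%: removed
               s2 = c(A = 20, B = 980),   # exactly 2.0%: retained
               s3 = c(A = 1000, B = 0))   # single group: unchanged
  out <- abundance_filter_18s(mat, 0.02)
  expect_equal(unname(out["s1", "A"]), 0)
  expect_equal(unname(out["s2", "A"]), 20)
  expect_equal(unname(out["s3", ]), c(1000, 0))
  expect_warning(abundance_filter_18s(rbind(mat, s4 = c(0, 0))), "zero")
})

test_that("the metazoan group list has the expected shape", {
  g <- metazoan_groups()
  expect_length(g, 19)
  expect_equal(anyDuplicated(g), 0)
  expect_true(all(c("Annelida", "Xenacoelomorpha", "Craniata") %in% g))
})
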