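test_that("simulation parameters are validated", {
  expect_error(sim_params(interspecific_divergence = 0.01,
                          intraspecific_divergence = 0.02), "exceed")
  expect_error(sim_params(substitution_error_rate = 1.2), "substitution")
  expect_s3_class(sim_params(), "sim_params")
})

test_that("simulated libraries honour the pairwise divergence floor", {
  pars <- sim_params(n_species = 2, interspecific_divergence = 0.05,
                     insert_length = 124, seed = 101)
  sl <- simulate_reference_library(pars)
  h <- sum(strsplit(sl$species$insert[1], "")[[1]] !=
             strsplit(sl$species$insert[2], "")[[1]])
  expect_gte(h, ceiling(0.05 * 124))  # at least 7 differing positions

  sl30 <- simulate_reference_library(sim_params(seed = 102))
  ins <- sl30$species$insert
  hmin <- min(apply(combn(length(ins), 2), 2, function(ij)
    sum(strsplit(ins[ij[1]], "")[[1]] != strsplit(ins[ij[2]], "")[[1]])))
  expect_gte(hmin, 7)
  # every species amplifiable with zero mismatches by construction
  p <- coi_minibarcode_primers()
  rep <- evaluate_amplifiability(sl30$library, p$fwd, p$rev, max_mm = 0)
  expect_equal(rep$summary$failed_species, 0)
})

test_that("library generation is deterministic per seed", {
  a <- simulate_reference_library(sim_params(n_species = 6, seed = 103))
  b <- simulate_reference_library(sim_params(n_species = 6, seed = 103))
  expect_identical(a$library$sequence, b$library$sequence)
  c <- simulate_reference_library(sim_params(n_species = 6, seed = 104))
  expect_false(identical(a$library$sequence, c$library$sequence))
})

test_that("equimolar mock communities give uniform shares", {
  sl <- simulate_reference_library(sim_params(n_species = 10, seed = 105))
  comm <- simulate_mock_community(sl)
  expect_equal(comm$share, rep(1 / 10, 10))
  expect_equal(sum(comm$share), 1)
  sub <- simulate_mock_community(sl, n_species_subset = 4)
  expect_equal(nrow(sub), 4)
  expect_equal(sum(sub$share), 1)
  ln <- simulate_mock_community(
    simulate_reference_library(sim_params(n_species = 10, seed = 105,
                                          abundance_model = "lognormal")))
  expect_equal(sum(ln$share), 1)
  expect_gt(max(ln$share), min(ln$share))
  expect_identical(simulate_mock_community(sl, seed = 9),
                   simulate_mock_community(sl, seed = 9))
})

test_that("a lossless channel returns exactly the planted community", {
  pars <- sim_params(n_species = 8, substitution_error_rate = 0,
                     chimera_rate = 0, seed = 106)
  sl <- simulate_reference_library(pars)
  comm <- simulate_mock_community(sl)
  sr <- simulate_reads(sl, comm, depth = 2000)
  merged <- merge_pairs(sr$pairs)
  expect_true(all(merged$aligned))
  p <- coi_minibarcode_primers()
  dm <- demultiplex(merged, study_tag_scheme("COI"), p$fwd, p$rev)
  expect_equal(dm$counts$assigned, 2000)
  tab <- dereplicate(dm$samples)
  expect_setequal(unname(tab$sequence), sl$species$insert)
  got <- rowSums(tab$counts)[match(sl$species$insert, tab$sequence)]
  expect_equal(unname(got), sr$truth$species$reads)
})

test_that("read simulation is deterministic and rejects unmergeable designs", {
  sl <- simulate_reference_library(sim_params(n_species = 4, seed = 107))
  comm <- simulate_mock_community(sl)
  a <- simulate_reads(sl, comm, depth = 200, seed = 5)
  b <- simulate_reads(sl, comm, depth = 200, seed = 5)
  expect_identical(a$pairs, b$pairs)
  # FASTQ round trip is byte-stable
  r1a <- tempfile(fileext = ".fastq"); r2a <- tempfile(fileext = ".fastq")
  r1b <- tempfile(fileext = ".fastq"); r2b <- tempfile(fileext = ".fastq")
  write_paired_fastq(a$pairs, r1a, r2a)
  write_paired_fastq(b$pairs, r1b, r2b)
  expect_identical(readLines(r1a), readLines(r1b))
  back <- read_paired_fastq(r1a, r2a)
  expect_equal(back$fwd_seq, a$pairs$fwd_seq)
  expect_equal(back$rev_qual, a$pairs$rev_qual)
  unlink(c(r1a, r2a, r1b, r2b))

  long <- simulate_reference_library(sim_params(n_species = 4, seed = 108,
                                                insert_length = 220))
  expect_error(simulate_reads(long, simulate_mock_community(long),
                              depth = 10), "mergeable")
})

test_that("substitution errors appear at the configured rate", {
  sl <- simulate_reference_library(sim_params(n_species = 1, seed = 109,
                                              substitution_error_rate = 0.01,
                                              chimera_rate = 0))
  comm <- simulate_mock_community(sl)
  sr <- simulate_reads(sl, comm, depth = 4000, seed = 6)
  clean <- simulate_reads(sl, comm,
                          params = sim_params(n_species = 1, seed = 109,
                                              substitution_error_rate = 0,
                                              chimera_rate = 0),
                          depth = 4000, seed = 6)
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               sr$pairs$fwd_seq, clean$pairs$fwd_seq)
  rate <- mean(mm) / 125
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("abiotic metadata tracks the pressure gradient", {
  md <- simulate_abiotic_metadata(12, correlation = 0.95, seed = 110)
  expect_equal(nrow(md), 12)
  expect_true(all(diff(md$pressure) > 0))
  expect_lt(cor(md$pressure, md$temperature), -0.7)
  expect_gt(cor(md$pressure, md$salinity), 0.7)
  expect_identical(simulate_abiotic_metadata(12, seed = 3),
                   simulate_abiotic_metadata(12, seed = 3))
  expect_error(simulate_abiotic_metadata(1), "two samples")
  std <- standardize_unit_total(md[, c("pressure", "salinity")])
  expect_equal(unname(colSums(std)), c(1, 1))
})
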