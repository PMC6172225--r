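# toy demux setting used throughout: plain primers, study COI tags
FWD <- "ACGTACGTAA"
REV <- "AATTGGCCAA"          # 5'->3'; plus strand carries TTGGCCAATT
SCHEME <- study_tag_scheme("COI")

construct_read <- function(insert, sample = "sample1", scheme = SCHEME) {
  row <- scheme$sample_map[scheme$sample_map$sample == sample, ]
  paste0(toupper(row$forward_tag), FWD, insert, rc(REV),
         rc(toupper(row$reverse_tag)))
}

test_that("exact complementary mates reassemble the amplicon", {
  set.seed(21)
  amp <- rand_dna(180)
  rl <- 125
  pairs <- data.frame(read_id = "p1",
                      fwd_seq = substr(amp, 1, rl),
                      rev_seq = rc(substr(amp, 181 - rl, 180)),
                      fwd_qual = strrep("I", rl), rev_qual = strrep("I", rl))
  class(pairs) <- c("read_pairs", "data.frame")
  m <- merge_pairs(pairs)
  expect_true(m$aligned)
  expect_equal(m$sequence, amp)
  expect_equal(m$overlap_length, 2 * rl - 180)
})

test_that("unrelated mates fail to merge", {
  set.seed(22)
  pairs <- data.frame(read_id = "p1", fwd_seq = rand_dna(100),
                      rev_seq = rand_dna(100),
                      fwd_qual = strrep("I", 100), rev_qual = strrep("I", 100))
  class(pairs) <- c("read_pairs", "data.frame")
  m <- merge_pairs(pairs)
  expect_false(m$aligned)
  expect_true(is.na(m$sequence))
})

test_that("overlap conflicts keep the higher-quality base", {
  set.seed(23)
  amp <- rand_dna(30)
  rl <- 20
  fwd <- substr(amp, 1, rl)
  rev_plus <- substr(amp, 11, 30)
  # conflict at amplicon position 15 (reverse read position 16 after revcomp)
  old <- substr(rev_plus, 5, 5)
  new <- chartr("ACGT", "CGTA", old)
  substr(rev_plus, 5, 5) <- new
  rev_read <- rc(rev_plus)
  rq <- strrep("I", rl)                       # Phred 40
  substr(rq, 16, 16) <- "5"                   # Phred 20 at the conflict
  pairs <- data.frame(read_id = "p1", fwd_seq = fwd, rev_seq = rev_read,
                      fwd_qual = strrep("I", rl), rev_qual = rq)
  class(pairs) <- c("read_pairs", "data.frame")
  m <- merge_pairs(pairs)
  expect_true(m$aligned)
  expect_equal(m$sequence, amp)               # forward (Phred 40) base wins
  # consensus quality at the conflict is the Phred difference (40 - 20)
  expect_equal(utf8ToInt(substr(m$quality, 15, 15)) - 33, 20)
  # agreements keep max quality
  expect_equal(utf8ToInt(substr(m$quality, 20, 20)) - 33, 40)
})

test_that("mean-quality filter applies an inclusive Phred-30 boundary", {
  m <- as_merged(rep(strrep("A", 20), 3),
                 qual = c(strrep("I", 20),                 # mean 40
                          strrep("5", 20),                 # mean 20
                          paste0(strrep("I", 10), strrep("5", 10))))  # mean 30
  expect_equal(quality_filter(m), c(TRUE, FALSE, TRUE))
  m$aligned[2] <- FALSE
  expect_error(quality_filter(m), "aligned")
})

test_that("demultiplexing assigns exact constructs and trims flanks", {
  set.seed(24)
  ins <- rand_dna(124)
  m <- as_merged(construct_read(ins, "sample2"))
  dm <- demultiplex(m, SCHEME, FWD, REV)
  expect_equal(dm$counts$assigned, 1)
  expect_equal(dm$assignments$sample, "sample2")
  expect_equal(dm$assignments$insert, ins)
  expect_equal(dm$samples$sample2, ins)
})

test_that("reverse-complemented reads assign identically", {
  set.seed(25)
  ins <- rand_dna(124)
  m <- as_merged(c(construct_read(ins, "sample3"),
                   rc(construct_read(ins, "sample3"))))
  dm <- demultiplex(m, SCHEME, FWD, REV)
  expect_equal(dm$counts$assigned, 2)
  expect_equal(unique(dm$assignments$sample), "sample3")
  expect_equal(unique(dm$assignments$insert), ins)
})

test_that("tags are exact but primers tolerate the mismatch budget", {
  set.seed(26)
  ins <- rand_dna(124)
  good <- construct_read(ins, "sample1")

  tag_bad <- good
  substr(tag_bad, 1, 1) <- "C"   # actgac -> cctgac, not a listed tag
  dm <- demultiplex(as_merged(tag_bad), SCHEME, FWD, REV)
  expect_equal(dm$counts$assigned, 0)
  expect_equal(dm$unassigned$reason, "tag_mismatch")

  # 4 substitutions in the forward primer: still assigned
  p4 <- good
  substr(p4, 7, 10) <- chartr("ACGT", "CGTA", substr(p4, 7, 10))
  dm4 <- demultiplex(as_merged(p4), SCHEME, FWD, REV)
  expect_equal(dm4$counts$assigned, 1)
  # 5 substitutions: rejected
  p5 <- good
  substr(p5, 7, 11) <- chartr("ACGT", "CGTA", substr(p5, 7, 11))
  dm5 <- demultiplex(as_merged(p5), SCHEME, FWD, REV)
  expect_equal(dm5$counts$assigned, 0)
  expect_equal(dm5$unassigned$reason, "primer_mismatch")
})

test_that("listed but unmapped tag pairs are reported as unknown", {
  set.seed(27)
  ins <- rand_dna(124)
  swapped <- paste0(toupper(SCHEME$forward_tags[1]), FWD, ins, rc(REV),
                    rc(toupper(SCHEME$reverse_tags[2])))
  dm <- demultiplex(as_merged(swapped), SCHEME, FWD, REV)
  expect_equal(dm$counts$assigned, 0)
  expect_equal(dm$unassigned$reason, "unknown_tag_pair")
})

test_that("demultiplexing conserves reads and flags unmerged input", {
  set.seed(28)
  m <- as_merged(c(construct_read(rand_dna(124)), rand_dna(60)))
  m <- rbind(m, data.frame(read_id = "r999", sequence = NA,
                           quality = NA, overlap_length = 0, aligned = FALSE))
  class(m) <- c("merged_reads", "data.frame")
  dm <- demultiplex(m, SCHEME, FWD, REV)
  expect_equal(dm$counts$assigned + dm$counts$unassigned, nrow(m))
  expect_true("unmerged" %in% dm$unassigned$reason)
})

test_that("length filter is inclusive at the marker thresholds", {
  set.seed(29)
  samples <- list(s1 = vapply(c(99, 100, 101), rand_dna, ""),
                  s2 = character(0))
  kept <- length_filter(samples, "COI")
  expect_equal(nchar(kept$s1), c(100, 101))
  expect_equal(kept$s2, character(0))
  kept18 <- length_filter(list(s1 = vapply(c(139, 140), rand_dna, "")), "18S")
  expect_equal(nchar(kept18$s1), 140)
  expect_error(length_filter(samples, "16S"), "length threshold")
})
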