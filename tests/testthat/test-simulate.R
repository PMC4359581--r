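test_that("random fragments start and end with a recognition match", {
  frags <- random_fragments(200, "ApeKI", 60, 200, seed = 31)
  lens <- nchar(frags)
  expect_true(all(lens >= 60 & lens <= 200))
  for (f in frags) {
    expect_equal(site_mismatches("GCWGC", substr(f, 1, 5)), 0L)
    expect_equal(site_mismatches("GCWGC", substr(f, nchar(f) - 4, nchar(f))),
                 0L)
  }
  # min == max pins the length
  same <- random_fragments(10, "ApeKI", 80, 80, seed = 32)
  expect_true(all(nchar(same) == 80L))
})

test_that("reference-mode fragment building matches the digest report", {
  set.seed(33)
  genome <- data.frame(id = "c1", sequence = rand_dna(9000))
  dg <- digest_genome(genome, "ApeKI", min_fragment = 60, max_fragment = 200)
  frags <- build_fragment_fasta(genome, "ApeKI", min_len = 60, max_len = 200)
  expect_length(frags, dg$report$n_selected)
  for (f in frags) {
    expect_equal(site_mismatches("GCWGC", substr(f, 1, 5)), 0L)
    expect_equal(site_mismatches("GCWGC", substr(f, nchar(f) - 4, nchar(f))),
                 0L)
  }
})

test_that("simulation is deterministic, conserves counts and splits ends
           evenly", {
  frags <- random_fragments(20, "ApeKI", 60, 120, seed = 41)
  bc <- data.frame(barcode = c("ACGTACGT", "TTGGAACCA"), enzyme = "ApeKI")
  cfg <- sim_config(reads_per_locus = 4, error_rate = 0.01, seed = 42)
  s1 <- simulate_reads(frags, bc, cfg)
  s2 <- simulate_reads(frags, bc, cfg)
  expect_identical(s1$r1, s2$r1)
  expect_identical(s1$r2, s2$r2)

  # reads = barcodes x fragments x reads_per_locus
  expect_equal(nrow(s1$r1), 2L * 20L * 4L)
  ends <- table(s1$truth$sample, s1$truth$end)
  expect_true(all(ends[, "fwd"] == ends[, "rev"]))
  expect_true(all(nchar(s1$r1$sequence) == 100L))
})

test_that("zero-noise reads equal their template prefixes", {
  frags <- random_fragments(10, "ApeKI", 60, 90, seed = 51)
  bc <- data.frame(barcode = "ACGTACGT", enzyme = "ApeKI")
  s <- simulate_reads(frags, bc,
                      sim_config(reads_per_locus = 2, error_rate = 0,
                                 seed = 52))
  fwd <- s$truth$end == "fwd"
  templ <- paste0("ACGTACGT", unname(frags[s$truth$fragment[fwd]]),
                  "AGATCGGAAGAGCG", strrep("A", 100))
  expect_equal(s$r1$sequence[fwd], substr(templ, 1, 100))
  # read 2 of the same loci: reverse complement geometry
  templ2 <- paste0(revcomp_dna(paste0("ACGTACGT",
                                      unname(frags[s$truth$fragment[fwd]]))),
                   "AGATCGGAAGAGCG", strrep("A", 100))
  expect_equal(s$r2$sequence[fwd], substr(templ2, 1, 100))
  expect_equal(sum(s$truth$bc_errors), 0L)
})

test_that("the substitution rate matches the binomial error model", {
  frags <- random_fragments(30, "ApeKI", 100, 200, seed = 61)
  bc <- data.frame(barcode = "ACGTACGT", enzyme = "ApeKI")
  noisy <- simulate_reads(frags, bc,
                          sim_config(reads_per_locus = 4, error_rate = 0.01,
                                     seed = 62))
  clean <- simulate_reads(frags, bc,
                          sim_config(reads_per_locus = 4, error_rate = 0,
                                     seed = 62))
  n_bases <- sum(nchar(clean$r1$sequence))
  expect_gt(n_bases, 1e4)
  diffs <- sum(vapply(seq_len(nrow(clean$r1)), function(i) {
    sum(strsplit(noisy$r1$sequence[i], "")[[1]] !=
          strsplit(clean$r1$sequence[i], "")[[1]])
  }, numeric(1)))
  p <- 0.01
  sd3 <- 3 * sqrt(n_bases * p * (1 - p))
  expect_lt(abs(diffs - n_bases * p), sd3)
})

test_that("the truth log's barcode-region errors equal an independent diff", {
  frags <- random_fragments(15, "ApeKI", 60, 120, seed = 71)
  bc <- data.frame(barcode = c("ACGTACGT", "CCAATTGGCC"), enzyme = "ApeKI")
  noisy <- simulate_reads(frags, bc,
                          sim_config(reads_per_locus = 2, error_rate = 0.05,
                                     seed = 72))
  for (i in seq_len(nrow(noisy$r1))) {
    b <- bc$barcode[match(noisy$truth$sample[i], c("S01", "S02"))]
    observed <- substr(noisy$r1$sequence[i], 1, nchar(b))
    diff <- sum(strsplit(observed, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(noisy$truth$bc_errors[i], diff)
  }
})

test_that("simulator input validation", {
  frags <- random_fragments(3, "ApeKI", 60, 80, seed = 81)
  bc <- data.frame(barcode = strrep("A", 30), enzyme = "ApeKI")
  expect_error(simulate_reads(frags, bc, sim_config(read_length = 20)),
               "barcode longer")
  expect_error(sim_config(reads_per_locus = 3), "reads_per_locus")
})
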