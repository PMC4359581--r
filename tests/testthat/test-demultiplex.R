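apeki <- get_enzyme("ApeKI")

simple_sheet <- data.frame(sample = "S1", barcode = "ACGTACGT",
                           enzyme = "ApeKI", stringsAsFactors = FALSE)

test_that("read matching honours mismatch budgets and trims the probe", {
  cfg <- demux_config("gbs")
  reads <- c(
    paste0("ACGTACGT", "GCAGC", strrep("T", 60)),  # exact
    paste0("ACGAACGT", "GCAGC", strrep("T", 60)),  # 1 barcode mismatch
    paste0("ACGAACGA", "GCAGC", strrep("T", 60)),  # 2 barcode mismatches
    paste0("ACGTACGT", "GGAGC", strrep("T", 60)),  # 1 enzyme mismatch
    paste0("ACGTACGT", "GGAGG", strrep("T", 60))   # 2 enzyme mismatches
  )
  m <- match_reads(reads, simple_sheet, cfg)
  expect_equal(m$sample, c("S1", "S1", NA, "S1", NA))
  expect_equal(m$bc_mm, c(0L, 1L, NA, 0L, NA))
  expect_equal(m$en_mm, c(0L, 0L, NA, 1L, NA))
  expect_equal(m$prefix_len, c(13L, 13L, NA, 13L, NA))

  # W in the recognition site accepts both A and T without penalty
  m2 <- match_reads(paste0("ACGTACGT", "GCTGC", strrep("A", 60)),
                    simple_sheet, cfg)
  expect_equal(m2$en_mm, 0L)

  # inline mode ignores the enzyme column entirely
  m3 <- match_reads(paste0("ACGTACGT", strrep("G", 60)), simple_sheet,
                    demux_config("inline"))
  expect_equal(m3$sample, "S1")
  expect_equal(m3$prefix_len, 8L)

  # keep_enzyme_5prime leaves the site on the read
  m4 <- match_reads(reads[1], simple_sheet,
                    demux_config("gbs", keep_enzyme_5prime = TRUE))
  expect_equal(m4$prefix_len, 8L)

  # reads shorter than the probe are undetermined
  m5 <- match_reads("ACGTACGTGCA", simple_sheet, cfg)
  expect_true(is.na(m5$sample))
})

test_that("ambiguous reads go to undetermined; the tie-break prefers fewer
           mismatches then longer barcodes", {
  sheet <- data.frame(sample = c("A", "B"),
                      barcode = c("AAAAAAAA", "AAAAAAAT"),
                      enzyme = "ApeKI", stringsAsFactors = FALSE)
  cfg <- demux_config("gbs")
  site_tail <- paste0("GCAGC", strrep("C", 40))
  # exactly between the two barcodes: one mismatch to each -> tie
  m <- match_reads(paste0("AAAAAAAG", site_tail), sheet, cfg)
  expect_true(is.na(m$sample))
  # exact match beats a 1-mismatch rival
  expect_equal(match_reads(paste0("AAAAAAAT", site_tail), sheet, cfg)$sample,
               "B")
  # longer barcode wins among equal-mismatch candidates
  sheet2 <- data.frame(sample = c("short", "long"),
                       barcode = c("GGGGGGGG", "GGGGGGGGGCAGC"),
                       enzyme = "ApeKI", stringsAsFactors = FALSE)
  m2 <- match_reads(paste0("GGGGGGGG", "GCAGC", "GCAGC", strrep("T", 40)),
                    sheet2, cfg)
  expect_equal(m2$sample, "long")
})

test_that("3' trimming needs the full site plus a matching adapter start", {
  cfg <- demux_config("gbs", adapter = ADAPTER)
  # site (W=T) at position 8, then 8 bases of truncated adapter
  r <- paste0("TTTTACGT", "GCTGC", "AGATCGGA")
  t1 <- trim_3prime_read1(r, strrep("I", nchar(r)), apeki, cfg)
  expect_equal(t1$sequence, "TTTTACGT")
  expect_equal(nchar(t1$quality), 8L)

  # no site anywhere -> unchanged
  r2 <- strrep("T", 40)
  expect_equal(trim_3prime_read1(r2, strrep("I", 40), apeki, cfg)$sequence, r2)

  # site present but the following bases are not adapter -> unchanged
  r3 <- paste0("TTTTACGT", "GCTGC", "CCCCCCCCCCCC")
  expect_equal(trim_3prime_read1(r3, strrep("I", nchar(r3)), apeki,
                                 cfg)$sequence, r3)

  # site flush with the read end (zero adapter overlap) is trimmed
  r4 <- paste0("TTTTACGT", "GCTGC")
  expect_equal(trim_3prime_read1(r4, strrep("I", 13), apeki, cfg)$sequence,
               "TTTTACGT")

  # rad mode ignores the site and needs >= 3 adapter bases
  cfg_rad <- demux_config("rad", adapter = ADAPTER)
  r5 <- paste0("TTTTACGTGCTGC", "AGAT")
  expect_equal(trim_3prime_read1(r5, strrep("I", nchar(r5)), apeki,
                                 cfg_rad)$sequence, "TTTTACGTGCTGC")
  r6 <- paste0("TTTTACGTGCTGC", "AG")
  expect_equal(trim_3prime_read1(r6, strrep("I", nchar(r6)), apeki,
                                 cfg_rad)$sequence, r6)
})

test_that("read 2 is trimmed at site + reverse-complemented barcode", {
  cfg <- demux_config("gbs", adapter = ADAPTER)
  bc <- "ACGTACGT"
  r <- paste0("TTACGTAAAA", "GCTGC", revcomp_dna(bc), "AGAT")
  t2 <- trim_3prime_read2(r, strrep("I", nchar(r)), apeki, bc, cfg)
  expect_equal(t2$sequence, "TTACGTAAAA")

  # one substitution inside the reverse-complemented barcode still trims
  rc <- strsplit(revcomp_dna(bc), "")[[1]]
  rc[3] <- setdiff(c("A", "C", "G", "T"), rc[3])[1]
  r2 <- paste0("TTACGTAAAA", "GCTGC", paste(rc, collapse = ""), "AGAT")
  expect_equal(trim_3prime_read2(r2, strrep("I", nchar(r2)), apeki, bc,
                                 cfg)$sequence, "TTACGTAAAA")

  # long insert: no site/barcode within the read -> unchanged
  r3 <- strrep("C", 50)
  expect_equal(trim_3prime_read2(r3, strrep("I", 50), apeki, bc,
                                 cfg)$sequence, r3)
})

test_that("pair reconciliation trims the long mate or restores the short one", {
  cfg <- demux_config("gbs", adapter = ADAPTER)
  insert <- "GCAGCTTTTACGTAGCAGC"  # 19 bp fragment, sites at both ends

  # R1 correctly trimmed to the 9-bp interior, R2 3'-trim missed: R2
  # (5'-site already removed) holds the reverse-complemented interior,
  # the terminal site and read-through junk
  interior <- substr(insert, 6, 14)
  r1 <- list(sequence = interior, quality = strrep("I", 9), trimmed = TRUE)
  r2full <- paste0(revcomp_dna(interior), "GCTGC", strrep("G", 6))
  r2 <- list(sequence = r2full, quality = strrep("I", nchar(r2full)),
             trimmed = FALSE)
  orig1 <- list(sequence = paste0(interior, "GCAGCAAAA"),
                quality = strrep("I", 18))
  orig2 <- list(sequence = r2full, quality = strrep("I", nchar(r2full)))
  rec <- reconcile_pairs(r1, r2, orig1, orig2, apeki, max_barcode_len = 8L,
                         config = cfg)
  expect_equal(rec$r2$sequence, substr(r2full, 1, 9))
  expect_equal(rec$r1$sequence, interior)

  # equal lengths: untouched
  req <- reconcile_pairs(r1, list(sequence = interior, quality = strrep("I", 9),
                                  trimmed = TRUE),
                         orig1, orig2, apeki, 8L, cfg)
  expect_equal(req$r2$sequence, interior)

  # over-trimmed R1 (spurious site), R2 longer and correct, no genuine
  # overlap -> R1 restored from its original to R2's length
  r1_bad <- list(sequence = "TTTTTT", quality = strrep("I", 6),
                 trimmed = TRUE)
  r2_ok <- list(sequence = strrep("C", 12), quality = strrep("I", 12),
                trimmed = TRUE)
  orig1b <- list(sequence = paste0("TTTTTT", "GCAGCAAAAAAAAAA"),
                 quality = strrep("I", 21))
  rec2 <- reconcile_pairs(r1_bad, r2_ok, orig1b, orig2, apeki, 8L, cfg)
  expect_equal(rec2$r1$sequence, substr(orig1b$sequence, 1, 12))
})

test_that("a full run conserves reads, writes per-sample files and stats", {
  sheet <- fixture_sheet(5, seed = 2)
  frags <- random_fragments(60, "ApeKI", 60, 150, seed = 6)
  bc <- data.frame(barcode = sheet$barcode, enzyme = "ApeKI")
  out <- withr::local_tempdir()
  sim <- simulate_reads(frags, bc,
                        sim_config(reads_per_locus = 2, error_rate = 0,
                                   seed = 8),
                        out_dir = out)
  cfg <- demux_config("gbs", adapter = ADAPTER)
  dm <- demultiplex_run(file.path(out, "reads.R1.fastq"),
                        file.path(out, "reads.R2.fastq"), sheet, cfg,
                        file.path(out, "demux"), collect = TRUE,
                        chunk_size = 123L)
  expect_equal(sum(dm$stats$reads), dm$n_total)
  expect_equal(dm$n_total, nrow(sim$truth))
  expect_equal(dm$n_undetermined, 0L)
  # error-free data: every read goes to its true sample
  idx <- match(dm$assignments$id, sim$truth$id)
  expect_equal(dm$assignments$sample, sim$truth$sample[idx])
  for (s in sheet$sample) {
    expect_true(file.exists(file.path(out, "demux",
                                      paste0(s, ".R1.fastq"))))
    expect_true(file.exists(file.path(out, "demux",
                                      paste0(s, ".R2.fastq"))))
  }
  expect_true(file.exists(file.path(out, "demux", "demux_stats.tsv")))
  stats <- utils::read.table(file.path(out, "demux", "demux_stats.tsv"),
                             sep = "\t", header = TRUE)
  expect_equal(sum(stats$reads), dm$n_total)
  # constant-quality simulation: mean quality is Phred 40
  expect_true(all(abs(stats$mean_quality[seq_len(5)] - 40) < 1e-9))
})

test_that("assignments are stable across pairing and monotone in the budget", {
  sheet <- fixture_sheet(4, seed = 12)
  frags <- random_fragments(40, "ApeKI", 60, 150, seed = 13)
  bc <- data.frame(barcode = sheet$barcode, enzyme = "ApeKI")
  out <- withr::local_tempdir()
  simulate_reads(frags, bc,
                 sim_config(reads_per_locus = 2, error_rate = 0.02,
                            seed = 14),
                 out_dir = out)
  r1 <- file.path(out, "reads.R1.fastq")
  r2 <- file.path(out, "reads.R2.fastq")
  cfg <- demux_config("gbs", adapter = ADAPTER)

  paired <- demultiplex_run(r1, r2, sheet, cfg,
                            file.path(out, "d_pe"), collect = TRUE)
  single <- demultiplex_run(r1, NULL, sheet, cfg,
                            file.path(out, "d_se"), collect = TRUE)
  # the barcode lives on read 1: identical assignments either way
  pe <- paired$assignments[order(paired$assignments$id), c("id", "sample")]
  se <- single$assignments[order(single$assignments$id), c("id", "sample")]
  expect_equal(pe, se, ignore_attr = TRUE)

  # gbs and rad only differ in 3' trimming, never in assignment
  rad <- demultiplex_run(r1, r2, sheet, demux_config("rad", adapter = ADAPTER),
                         file.path(out, "d_rad"), collect = TRUE)
  ra <- rad$assignments[order(rad$assignments$id), c("id", "sample")]
  expect_equal(pe, ra, ignore_attr = TRUE)

  # a larger barcode budget never loses assigned reads
  strict <- demultiplex_run(r1, NULL, sheet,
                            demux_config("gbs", barcode_mismatches = 0,
                                         adapter = ADAPTER),
                            file.path(out, "d_mm0"), collect = TRUE)
  loose <- demultiplex_run(r1, NULL, sheet,
                           demux_config("gbs", barcode_mismatches = 2,
                                        adapter = ADAPTER),
                           file.path(out, "d_mm2"), collect = TRUE)
  expect_lte(nrow(strict$assignments), nrow(single$assignments))
  expect_lte(nrow(single$assignments), nrow(loose$assignments))
})

test_that("unequal paired inputs and unknown enzymes are rejected", {
  out <- withr::local_tempdir()
  r1 <- file.path(out, "a.fastq")
  r2 <- file.path(out, "b.fastq")
  write_fastq(data.frame(id = c("x", "y"), sequence = c("ACGT", "ACGT"),
                         quality = c("IIII", "IIII")), r1)
  write_fastq(data.frame(id = "x", sequence = "ACGT", quality = "IIII"), r2)
  expect_error(
    demultiplex_run(r1, r2, simple_sheet, demux_config("gbs"),
                    file.path(out, "d")),
    "unequal record counts"
  )
  bad_sheet <- data.frame(sample = "S1", barcode = "ACGTACGT",
                          enzyme = "NoSuchEnzyme")
  expect_error(
    demultiplex_run(r1, NULL, bad_sheet, demux_config("gbs"),
                    file.path(out, "d2")),
    "unknown enzyme"
  )
})
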