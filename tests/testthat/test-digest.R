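apeki <- get_enzyme("ApeKI")

test_that("cut sites are found IUPAC-aware, with overlaps, on both strands", {
  expect_equal(find_cut_sites("TTGCAGCTT", apeki), 3L)
  expect_equal(find_cut_sites("AAAAAA", apeki), integer(0))
  # overlapping matches at 0 and 3 -> cuts at 1 and 4
  expect_equal(find_cut_sites("GCAGCAGC", apeki), c(1L, 4L))

  # non-palindromic recognition: reverse-complement strand is scanned too
  mlu <- enzyme("TestI", "A^ACGT")  # revcomp ACGTT
  seq <- paste0("TT", "AACGT", "GG", "ACGTT", "TT")
  # forward match at 2 -> cut 3; reverse match at 9 -> cut 9 + (5-1) = 13
  expect_equal(find_cut_sites(seq, mlu), c(3L, 13L))

  # N in the reference never spawns a cut
  expect_equal(find_cut_sites("GCNGC", apeki), integer(0))
})

test_that("fragments tile the chromosome and size selection is inclusive", {
  fr <- fragments_from_cuts(18L, c(3L, 12L))
  expect_equal(fr$start, c(0L, 3L, 12L))
  expect_equal(fr$end, c(3L, 12L, 18L))
  expect_equal(fr$length, c(3L, 9L, 6L))
  expect_equal(sum(fr$length), 18L)
  expect_equal(fr$left_enzyme, c("chrom_end", "E1", "E1"))

  # no cuts -> single boundary-to-boundary fragment
  f1 <- fragments_from_cuts(10L, integer(0))
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$length, 10L)

  # cuts at 0 and L produce no empty fragments
  f2 <- fragments_from_cuts(10L, c(0L, 10L))
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$left_enzyme, "E1")

  # only the interior fragment qualifies; bounds are inclusive
  expect_equal(select_fragments(fr, 4, 10)$length, 9L)
  expect_equal(select_fragments(fr, 9, 9)$length, 9L)
  expect_equal(nrow(select_fragments(fr, 10, 20)), 0L)
})

test_that("sequenced intervals cover both fragment ends and merge on overlap", {
  frag <- data.frame(chrom = "c1", start = 3L, end = 12L,
                     left_enzyme = "ApeKI", right_enzyme = "ApeKI",
                     name = "f1")
  iv <- sequenced_intervals(frag, read_length = 4)
  expect_equal(iv$start, c(3L, 8L))
  expect_equal(iv$end, c(7L, 12L))

  merged <- sequenced_intervals(frag, read_length = 6)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(3L, 12L))

  # full-site extension: ApeKI cut offset 1, site length 5 -> frame [2,16)
  ext <- sequenced_intervals(frag, read_length = 4, include_full_site = TRUE,
                             chrom_length = 100L)
  expect_equal(ext$start, c(2L, 12L))
  expect_equal(ext$end, c(6L, 16L))
})

test_that("constructed genome with known sites digests to the built truth", {
  set.seed(21)
  n_sites <- 12
  inserts <- replicate(n_sites + 1, strrep("T", sample(30:60, 1)))
  genome <- paste0(paste0(inserts[-length(inserts)], "GCAGC", collapse = ""),
                   inserts[length(inserts)])
  dg <- digest_genome(data.frame(id = "c1", sequence = genome), "ApeKI",
                      min_fragment = 1, max_fragment = nchar(genome))
  expect_equal(unname(dg$report$cut_counts["ApeKI"]), n_sites)
  expect_equal(dg$report$n_fragments, n_sites + 1L)
  expect_equal(dg$report$n_selected, n_sites - 1L)  # interior fragments
  expect_equal(sum(dg$fragments$length), nchar(genome))
})

test_that("digest equals the brute-force oracle on random genomes", {
  set.seed(31)
  for (rep in 1:20) {
    L <- sample(2000:10000, 1)
    seq <- rand_dna(L)
    dg <- digest_genome(data.frame(id = "c", sequence = seq), "ApeKI",
                        min_fragment = 60, max_fragment = 200,
                        read_length = 50)
    orc <- oracle_digest(seq, "GCWGC", 1L, 60L, 200L)
    cuts <- find_cut_sites(seq, apeki)
    expect_equal(cuts, orc$cuts)
    expect_equal(dg$fragments$start, orc$starts)
    expect_equal(dg$fragments$end, orc$ends)
    expect_equal(dg$selected$start, orc$selected$start)
    expect_equal(dg$selected$end, orc$selected$end)
    expect_equal(sum(dg$fragments$length), L)
    # BED stays within bounds and intervals within a fragment never overlap
    expect_true(all(dg$bed$start >= 0 & dg$bed$end <= L))
    expect_true(all(dg$bed$end > dg$bed$start))
  }
})

test_that("widening the size range never loses fragments", {
  set.seed(41)
  seq <- rand_dna(8000)
  genome <- data.frame(id = "c", sequence = seq)
  n_narrow <- digest_genome(genome, "ApeKI", min_fragment = 80,
                            max_fragment = 150)$report$n_selected
  n_wide <- digest_genome(genome, "ApeKI", min_fragment = 60,
                          max_fragment = 200)$report$n_selected
  expect_gte(n_wide, n_narrow)
})

test_that("two-enzyme digests merge cuts and report categories", {
  set.seed(51)
  seq <- rand_dna(6000)
  genome <- data.frame(id = "c", sequence = seq)
  both <- digest_genome(genome, "ApeKI", enzyme2 = "EcoRI",
                        min_fragment = 1, max_fragment = 6000)
  solo <- digest_genome(genome, "ApeKI", min_fragment = 1,
                        max_fragment = 6000)
  # categories partition all fragments
  expect_equal(sum(both$report$category_counts), both$report$n_fragments)
  # a second enzyme without matches leaves the digest unchanged
  degenerate <- digest_genome(genome, "ApeKI", enzyme2 = "None:TTTTTTTTTTTT",
                              min_fragment = 1, max_fragment = 6000)
  expect_equal(degenerate$fragments$start, solo$fragments$start)
  # total cut count of the merged digest matches the solo scans
  ecori_cuts <- length(find_cut_sites(seq, get_enzyme("EcoRI")))
  expect_equal(unname(both$report$cut_counts),
               c(length(find_cut_sites(seq, apeki)), ecori_cuts))

  # third-enzyme screening counts selected fragments with an internal site
  third <- digest_genome(genome, "ApeKI", enzyme3 = "MspI",
                         min_fragment = 60, max_fragment = 200)
  sel <- third$selected
  manual <- sum(vapply(seq_len(nrow(sel)), function(i) {
    s <- substr(seq, sel$start[i] + 1, sel$end[i])
    grepl("CCGG", s, fixed = TRUE)
  }, logical(1)))
  expect_equal(third$report$n_selected_with_third_site, manual)
})

test_that("digest writes a BED and report; empty FASTA errors", {
  set.seed(61)
  out <- withr::local_tempdir()
  genome <- data.frame(id = "c", sequence = rand_dna(4000))
  dg <- digest_genome(genome, "ApeKI", out_dir = out)
  expect_true(file.exists(file.path(out, "digest.bed")))
  expect_true(file.exists(file.path(out, "digest_report.tsv")))
  bed <- utils::read.table(file.path(out, "digest.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(dg$bed))
  expect_error(digest_genome(genome[0, ], "ApeKI"), "empty FASTA")
})
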