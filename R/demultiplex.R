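# In-line barcode demultiplexing and trimming.
#
# The matching/trimming engine is vectorised: each chunk of reads is laid
# out as a character matrix (positions x reads, space-padded past the read
# end; the pad character never matches anything), barcode columns are
# compared as plain characters (read-side N counts as a mismatch) and
# enzyme/adapter columns through IUPAC bitmasks.

# column sums of IUPAC mismatches of a pattern against mask-matrix rows
# (bitwAnd strips dim attributes, hence the explicit re-wrap)
.mm_colsums <- function(rm_rows, pm) {
  colSums(matrix(bitwAnd(rm_rows, pm) == 0L, nrow = length(pm)))
}

.pad_char_matrix <- function(seqs, width) {
  clipped <- substr(seqs, 1L, width)
  padded <- formatC(clipped, width = width, flag = "-")
  matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
         nrow = width)
}

#' Demultiplexer configuration
#'
#' @param mode `"gbs"` (barcode + restriction site at the read start,
#'   site + adapter trimming at the 3' end), `"rad"` (barcode + site at the
#'   start, adapter-only 3' trimming) or `"inline"` (barcode only).
#' @param barcode_mismatches Maximum mismatches in the barcode (default 1).
#' @param enzyme_mismatches Maximum mismatches in the recognition site
#'   (default 1; ignored in inline mode).
#' @param adapter Common adapter sequence used for 3' trimming, or `NULL`.
#' @param adapter_mismatch_rate Fraction of compared adapter bases allowed
#'   to mismatch (default 0.1; the budget is `floor(a * rate)` for an
#'   overlap of `a` bases).
#' @param keep_enzyme_5prime Keep the recognition site at the 5' end
#'   instead of trimming it with the barcode.
#' @return A list of class `demux_config`.
#' @export
demux_config <- function(mode = c("gbs", "rad", "inline"),
                         barcode_mismatches = 1L, enzyme_mismatches = 1L,
                         adapter = NULL, adapter_mismatch_rate = 0.1,
                         keep_enzyme_5prime = FALSE) {
  mode <- match.arg(mode)
  stopifnot(barcode_mismatches >= 0L, enzyme_mismatches >= 0L,
            adapter_mismatch_rate >= 0, adapter_mismatch_rate < 1)
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    if (!.is_dna(adapter)) stop("adapter must be a DNA sequence", call. = FALSE)
  }
  structure(list(mode = mode,
                 barcode_mismatches = as.integer(barcode_mismatches),
                 enzyme_mismatches = as.integer(enzyme_mismatches),
                 adapter = adapter,
                 adapter_mismatch_rate = adapter_mismatch_rate,
                 keep_enzyme_5prime = isTRUE(keep_enzyme_5prime)),
            class = "demux_config")
}

#' Read a demultiplexing sample sheet
#'
#' Tab-delimited `sample<TAB>barcode[<TAB>enzyme]`; the enzyme column is
#' optional in inline mode. Lines starting with `#` are ignored.
#'
#' @param path Path to the sample sheet.
#' @param enzymes Enzyme table for name resolution.
#' @return data.frame with columns `sample`, `barcode`, `enzyme`.
#' @export
read_sample_sheet <- function(path, enzymes = default_enzymes()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, fill = TRUE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("sample sheet needs sample and barcode columns",
                          call. = FALSE)
  if (ncol(df) == 2L) df$V3 <- ""
  df <- df[, 1:3]
  names(df) <- c("sample", "barcode", "enzyme")
  df$barcode <- toupper(df$barcode)
  .validate_sheet(df, enzymes)
  df
}

.validate_sheet <- function(sheet, enzymes) {
  if (anyDuplicated(sheet$sample)) stop("duplicate sample names", call. = FALSE)
  if (anyDuplicated(sheet$barcode)) stop("duplicate barcodes", call. = FALSE)
  if (!all(.is_dna(sheet$barcode))) {
    stop("sample sheet contains non-DNA barcodes", call. = FALSE)
  }
  for (e in unique(sheet$enzyme)) {
    if (!is.na(e) && nzchar(e)) get_enzyme(e, enzymes)
  }
  invisible(sheet)
}

# Resolve per-sample probes once per run.
.resolve_sheet <- function(sheet, config, enzymes) {
  sheet$enzyme[is.na(sheet$enzyme)] <- ""
  if (config$mode %in% c("gbs", "rad")) {
    if (any(!nzchar(sheet$enzyme))) {
      stop(config$mode, " mode requires an enzyme for every sample",
           call. = FALSE)
    }
    sheet$recognition <- vapply(sheet$enzyme, function(e) {
      get_enzyme(e, enzymes)$recognition
    }, character(1))
  } else {
    sheet$recognition <- ""
  }
  sheet$bc_len <- nchar(sheet$barcode)
  sheet$probe_len <- sheet$bc_len + nchar(sheet$recognition)
  sheet
}

#' Match reads against a sample sheet
#'
#' Checks the start of each read against every sample's probe
#' (barcode, plus recognition site outside inline mode). Barcode mismatches
#' are counted as plain character differences; site mismatches are
#' IUPAC-aware. A sample is a candidate when both mismatch counts are
#' within budget; the winner has the fewest barcode mismatches, then the
#' fewest site mismatches, then the longest barcode. Remaining ties, and
#' reads with no candidate, are undetermined (`NA`).
#'
#' @param seqs Character vector of read sequences.
#' @param sheet Sample sheet data.frame (`sample`, `barcode`, `enzyme`).
#' @param config A [demux_config()].
#' @param enzymes Enzyme table.
#' @return data.frame with columns `sample` (NA = undetermined), `bc_mm`,
#'   `en_mm`, `prefix_len` (bases to remove at the 5' end).
#' @export
match_reads <- function(seqs, sheet, config = demux_config(),
                        enzymes = default_enzymes()) {
  sheet <- .resolve_sheet(sheet, config, enzymes)
  n <- length(seqs)
  ns <- nrow(sheet)
  lens <- nchar(seqs)
  maxp <- max(sheet$probe_len)
  M <- .pad_char_matrix(seqs, maxp)
  RM <- matrix(.read_mask(M), nrow = maxp)

  best_score <- rep(Inf, n)
  best_idx <- rep(NA_integer_, n)
  tie <- rep(FALSE, n)
  bc_mm_all <- matrix(NA_integer_, nrow = ns, ncol = n)
  en_mm_all <- matrix(0L, nrow = ns, ncol = n)

  for (i in seq_len(ns)) {
    bl <- sheet$bc_len[i]
    bchars <- strsplit(sheet$barcode[i], "", fixed = TRUE)[[1]]
    bc_mm <- colSums(M[seq_len(bl), , drop = FALSE] != bchars)
    en_mm <- numeric(n)
    k <- nchar(sheet$recognition[i])
    if (k > 0L) {
      pm <- .pattern_mask(strsplit(sheet$recognition[i], "", fixed = TRUE)[[1]])
      en_mm <- .mm_colsums(RM[bl + seq_len(k), , drop = FALSE], pm)
    }
    bc_mm_all[i, ] <- bc_mm
    en_mm_all[i, ] <- en_mm
    cand <- bc_mm <= config$barcode_mismatches &
      en_mm <= config$enzyme_mismatches &
      lens >= sheet$probe_len[i]
    score <- bc_mm * 1e6 + en_mm * 1e3 + (999 - bl)
    score[!cand] <- Inf
    is_tie <- is.finite(score) & score == best_score
    better <- score < best_score
    tie[is_tie] <- TRUE
    tie[better] <- FALSE
    best_idx[better] <- i
    best_score[better] <- score[better]
  }
  und <- tie | is.na(best_idx)
  best_idx[und] <- NA_integer_
  pick <- cbind(best_idx, seq_len(n))
  bc_mm <- ifelse(und, NA_integer_, bc_mm_all[pick])
  en_mm <- ifelse(und, NA_integer_, en_mm_all[pick])
  prefix_len <- rep(NA_integer_, n)
  ok <- !und
  if (config$keep_enzyme_5prime) {
    prefix_len[ok] <- sheet$bc_len[best_idx[ok]]
  } else {
    prefix_len[ok] <- sheet$probe_len[best_idx[ok]]
  }
  data.frame(sample = ifelse(und, NA_character_, sheet$sample[best_idx]),
             bc_mm = as.integer(bc_mm), en_mm = as.integer(en_mm),
             prefix_len = prefix_len, stringsAsFactors = FALSE)
}

# Generic 3'-trim scan.
# site: IUPAC pattern that must match completely (<= site_mm mismatches)
#       at the trim point, or NULL;
# tail: concrete sequence expected after the site, compared over
#       a = min(nchar(tail), bases remaining) bases; budget is either
#       proportional (floor(a * rate)) or a constant;
# min_overlap: minimum a when site is NULL (adapter-only scans);
# best: FALSE takes the leftmost qualifying position, TRUE the position
#       with the fewest total mismatches (leftmost among ties) -- used for
#       the read-2 site+barcode scan, whose short tail makes near-miss
#       decoys likely enough that a later exact junction must win.
# Returns the 0-based trim position, or NA when no position qualifies.
.scan_trim3 <- function(seqs, site, site_mm, tail, tail_budget,
                        proportional, min_overlap, best = FALSE) {
  n <- length(seqs)
  lens <- nchar(seqs)
  W <- max(lens, 1L)
  pos <- rep(NA_integer_, n)
  best_mm <- rep(Inf, n)
  if (n == 0L || (is.null(site) && is.null(tail))) return(pos)
  M <- .pad_char_matrix(seqs, W)
  RM <- matrix(.read_mask(M), nrow = W)
  ks <- if (is.null(site)) 0L else nchar(site)
  pm_site <- if (ks > 0L) .pattern_mask(strsplit(site, "", fixed = TRUE)[[1]])
  nt <- if (is.null(tail)) 0L else nchar(tail)
  pm_tail <- if (nt > 0L) .pattern_mask(strsplit(tail, "", fixed = TRUE)[[1]])

  for (j in seq_len(max(W - ks + 1L, 0L))) {
    if (ks > 0L && j + ks - 1L > W) break
    fits <- j + ks - 1L <= lens
    if (!any(fits)) break
    if (ks > 0L) {
      s_mm <- numeric(n)
      for (k in seq_len(ks)) {
        s_mm <- s_mm + (bitwAnd(RM[j + k - 1L, ], pm_site[k]) == 0L)
      }
      site_ok <- s_mm <= site_mm
    } else {
      site_ok <- rep(TRUE, n)
    }
    a <- pmin(nt, pmax(lens - (j - 1L) - ks, 0L))
    tail_mm <- numeric(n)
    if (nt > 0L) {
      s <- numeric(n)
      for (t in seq_len(nt)) {
        row <- j + ks + t - 1L
        if (row > W) break
        s <- s + (bitwAnd(RM[row, ], pm_tail[t]) == 0L)
        hit <- a == t
        if (any(hit)) tail_mm[hit] <- s[hit]
      }
    }
    allowed <- if (proportional) floor(a * tail_budget) else tail_budget
    if (is.null(site)) {
      tail_ok <- a >= min_overlap & tail_mm <= allowed
    } else {
      tail_ok <- tail_mm <= allowed  # a == 0 (site flush with read end) is fine
    }
    if (best) {
      total <- (if (ks > 0L) s_mm else 0) + tail_mm
      cond <- fits & site_ok & tail_ok & total < best_mm
      if (any(cond)) {
        pos[cond] <- j - 1L
        best_mm[cond] <- total[cond]
      }
    } else {
      cond <- fits & site_ok & tail_ok & is.na(pos)
      if (any(cond)) pos[cond] <- j - 1L
      if (!anyNA(pos)) break
    }
  }
  pos
}

#' 3'-trim read 1
#'
#' In `gbs` mode, scans for the leftmost complete recognition-site match
#' (within the enzyme mismatch budget) followed by the start of the common
#' adapter (within `floor(a * adapter_mismatch_rate)` mismatches over the
#' `a` compared bases; `a` may be 0 when the site ends flush with the
#' read). In `rad` and `inline` mode, scans for the adapter alone with a
#' minimum overlap of 3 bases. Reads without a qualifying position are
#' returned unchanged.
#'
#' @param seqs,quals Character vectors (5'-trimmed reads).
#' @param enz `gbs_enzyme` of the matched samples (ignored in inline mode).
#' @param config A [demux_config()].
#' @return List with `sequence`, `quality`, `trimmed` (logical).
#' @export
trim_3prime_read1 <- function(seqs, quals, enz, config = demux_config()) {
  pos <- switch(config$mode,
    gbs = .scan_trim3(seqs, site = enz$recognition,
                      site_mm = config$enzyme_mismatches,
                      tail = config$adapter,
                      tail_budget = config$adapter_mismatch_rate,
                      proportional = TRUE, min_overlap = 0L),
    rad = ,
    inline = if (is.null(config$adapter)) rep(NA_integer_, length(seqs)) else
      .scan_trim3(seqs, site = NULL, site_mm = 0L, tail = config$adapter,
                  tail_budget = config$adapter_mismatch_rate,
                  proportional = TRUE, min_overlap = 3L)
  )
  .apply_trim(seqs, quals, pos)
}

#' 3'-trim read 2
#'
#' Scans for the recognition site followed by the reverse complement of the
#' matched sample's barcode (mismatch budgets: `enzyme_mismatches` for the
#' site, `barcode_mismatches` for the compared barcode bases; a partial
#' barcode at the read end is allowed). Because this tail is short, the
#' best-scoring position wins (leftmost among ties) rather than the
#' leftmost qualifying one: a later exact junction must beat an earlier
#' near-miss decoy. In inline mode the adapter-only rule of read 1 is used
#' instead.
#'
#' @param seqs,quals Character vectors (5'-handled read 2 sequences).
#' @param enz `gbs_enzyme` of the matched sample.
#' @param barcode The matched sample's barcode.
#' @param config A [demux_config()].
#' @return List with `sequence`, `quality`, `trimmed` (logical).
#' @export
trim_3prime_read2 <- function(seqs, quals, enz, barcode,
                              config = demux_config()) {
  if (config$mode == "inline") {
    return(trim_3prime_read1(seqs, quals, enz, config))
  }
  pos <- .scan_trim3(seqs, site = enz$recognition,
                     site_mm = config$enzyme_mismatches,
                     tail = revcomp_dna(barcode),
                     tail_budget = config$barcode_mismatches,
                     proportional = FALSE, min_overlap = 0L, best = TRUE)
  .apply_trim(seqs, quals, pos)
}

.apply_trim <- function(seqs, quals, pos) {
  trimmed <- !is.na(pos)
  if (any(trimmed)) {
    seqs[trimmed] <- substr(seqs[trimmed], 1L, pos[trimmed])
    quals[trimmed] <- substr(quals[trimmed], 1L, pos[trimmed])
  }
  list(sequence = seqs, quality = quals, trimmed = trimmed)
}

# 5' handling of read 2: trim a leading recognition-site match (within the
# enzyme budget) unless keep_enzyme_5prime; symmetric with read 1.
.trim_5prime_read2 <- function(seqs, quals, enz, config) {
  if (config$mode == "inline" || config$keep_enzyme_5prime) {
    return(list(sequence = seqs, quality = quals))
  }
  k <- nchar(enz$recognition)
  pm <- .pattern_mask(strsplit(enz$recognition, "", fixed = TRUE)[[1]])
  M <- .pad_char_matrix(seqs, k)
  RM <- matrix(.read_mask(M), nrow = k)
  mm <- .mm_colsums(RM, pm)
  hit <- mm <= config$enzyme_mismatches & nchar(seqs) >= k
  seqs[hit] <- substr(seqs[hit], k + 1L, nchar(seqs[hit]))
  quals[hit] <- substr(quals[hit], k + 1L, nchar(quals[hit]))
  list(sequence = seqs, quality = quals)
}

#' Mate-pair trimming consistency correction
#'
#' Short GBS inserts make read 1 and read 2 overlap, so correctly trimmed
#' mates have equal lengths. When at least one read of a pair was
#' 3'-trimmed but the lengths differ, the start of the longer read is
#' compared against the reverse complement of the end of the shorter read
#' over a window of site length + `max_barcode_len` bases (mismatch budget:
#' enzyme + barcode budgets combined). On a match the longer read is cut to
#' the shorter read's length; otherwise the longer read is taken as correct
#' and the shorter read is restored from its original (5'-trimmed,
#' 3'-untrimmed) sequence, cut to the longer read's length.
#'
#' @param r1,r2 Lists with `sequence`, `quality`, `trimmed` as returned by
#'   the 3' trimmers.
#' @param orig1,orig2 Lists with the original (5'-trimmed only) `sequence`
#'   and `quality`.
#' @param enz `gbs_enzyme` (window sizing and budget).
#' @param max_barcode_len Longest barcode in the sample sheet.
#' @param config A [demux_config()].
#' @return List with `r1` and `r2` (each `sequence`, `quality`).
#' @export
reconcile_pairs <- function(r1, r2, orig1, orig2, enz, max_barcode_len,
                            config = demux_config()) {
  l1 <- nchar(r1$sequence)
  l2 <- nchar(r2$sequence)
  k <- if (config$mode == "inline") 0L else nchar(enz$recognition)
  w <- k + max_barcode_len
  budget <- config$enzyme_mismatches + config$barcode_mismatches
  fix <- which((r1$trimmed | r2$trimmed) & l1 != l2)
  for (i in fix) {
    if (l1[i] > l2[i]) {
      long_seq <- r1$sequence[i]; nshort <- l2[i]; short_seq <- r2$sequence[i]
    } else {
      long_seq <- r2$sequence[i]; nshort <- l1[i]; short_seq <- r1$sequence[i]
    }
    m <- min(w, nshort)
    head_long <- substr(long_seq, 1L, m)
    tail_short <- revcomp_dna(substr(short_seq, nshort - m + 1L, nshort))
    mm <- if (m > 0L) {
      sum(strsplit(head_long, "", fixed = TRUE)[[1]] !=
            strsplit(tail_short, "", fixed = TRUE)[[1]])
    } else Inf
    if (mm <= budget) {
      # overlap confirmed: the shorter read's trim point is right
      if (l1[i] > l2[i]) {
        r1$sequence[i] <- substr(r1$sequence[i], 1L, nshort)
        r1$quality[i] <- substr(r1$quality[i], 1L, nshort)
      } else {
        r2$sequence[i] <- substr(r2$sequence[i], 1L, nshort)
        r2$quality[i] <- substr(r2$quality[i], 1L, nshort)
      }
    } else {
      # the longer read is deemed correct; restore the shorter read from
      # its untrimmed original, cut to the longer read's length
      if (l1[i] > l2[i]) {
        keep <- min(l1[i], nchar(orig2$sequence[i]))
        r2$sequence[i] <- substr(orig2$sequence[i], 1L, keep)
        r2$quality[i] <- substr(orig2$quality[i], 1L, keep)
      } else {
        keep <- min(l2[i], nchar(orig1$sequence[i]))
        r1$sequence[i] <- substr(orig1$sequence[i], 1L, keep)
        r1$quality[i] <- substr(orig1$quality[i], 1L, keep)
      }
    }
  }
  list(r1 = r1[c("sequence", "quality")], r2 = r2[c("sequence", "quality")])
}

#' Demultiplex one run into per-sample FASTQ files
#'
#' Streams the input in chunks, assigns each read (pair) to a sample via
#' [match_reads()], trims 5' (barcode + site unless `keep_enzyme_5prime`)
#' and 3' per mode, applies the paired-end consistency correction, and
#' writes per-sample FASTQ files plus an untrimmed `undetermined` file and
#' a tab-delimited statistics table (`demux_stats.tsv`).
#'
#' @param r1_path FASTQ file of read 1 (plain or gzip).
#' @param r2_path Optional FASTQ file of read 2 (paired-end).
#' @param sheet Sample sheet data.frame or path (see [read_sample_sheet()]).
#' @param config A [demux_config()].
#' @param out_dir Output directory (created if needed).
#' @param gzip Compress output FASTQ files.
#' @param chunk_size Reads per streamed chunk.
#' @param collect Also return per-read assignments (id, sample, trimmed
#'   lengths) in memory; used by the evaluator and tests.
#' @param enzymes Enzyme table.
#' @return List of class `gbs_demux` with `stats` (per-sample data.frame),
#'   `n_total`, `n_undetermined` and, when `collect`, `assignments`.
#' @export
demultiplex_run <- function(r1_path, r2_path = NULL, sheet,
                            config = demux_config(), out_dir,
                            gzip = FALSE, chunk_size = 50000L,
                            collect = FALSE, enzymes = default_enzymes()) {
  if (is.character(sheet) && length(sheet) == 1L) {
    sheet <- read_sample_sheet(sheet, enzymes)
  }
  .validate_sheet(sheet, enzymes)
  rsheet <- .resolve_sheet(sheet, config, enzymes)
  paired <- !is.null(r2_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  path_of <- function(sample, mate) {
    file.path(out_dir, paste0(sample, ".R", mate, ext))
  }
  all_names <- c(sheet$sample, "undetermined")
  for (s in all_names) {
    write_fastq(data.frame(id = character(0), sequence = character(0),
                           quality = character(0)), path_of(s, 1L),
                compress = gzip)
    if (paired) {
      write_fastq(data.frame(id = character(0), sequence = character(0),
                             quality = character(0)), path_of(s, 2L),
                  compress = gzip)
    }
  }

  max_bl <- max(rsheet$bc_len)
  nmm <- config$barcode_mismatches + 1L
  stats_env <- new.env()
  for (s in all_names) {
    assign(s, list(reads = 0L, mm = integer(nmm), bp = 0, qsum = 0,
                   qn = 0), envir = stats_env)
  }
  n_total <- 0L
  assignments <- if (collect) list()

  reader1 <- fastq_chunk_reader(r1_path, chunk_size)
  reader2 <- if (paired) fastq_chunk_reader(r2_path, chunk_size)

  repeat {
    chunk1 <- reader1()
    chunk2 <- if (paired) reader2()
    if (is.null(chunk1)) {
      if (paired && !is.null(chunk2)) {
        stop("paired FASTQ files have unequal record counts", call. = FALSE)
      }
      break
    }
    if (paired && (is.null(chunk2) || nrow(chunk2) != nrow(chunk1))) {
      stop("paired FASTQ files have unequal record counts", call. = FALSE)
    }
    n <- nrow(chunk1)
    n_total <- n_total + n
    m <- match_reads(chunk1$sequence, sheet, config, enzymes)

    # undetermined reads are written untrimmed (evidence for discovery)
    und <- is.na(m$sample)
    if (any(und)) {
      write_fastq(chunk1[und, ], path_of("undetermined", 1L),
                  compress = gzip, append = TRUE)
      if (paired) {
        write_fastq(chunk2[und, ], path_of("undetermined", 2L),
                    compress = gzip, append = TRUE)
      }
      st <- get("undetermined", envir = stats_env)
      st$reads <- st$reads + sum(und)
      assign("undetermined", st, envir = stats_env)
    }

    for (i in seq_len(nrow(sheet))) {
      s <- sheet$sample[i]
      sel <- which(!und & m$sample == s)
      if (collect && length(sel) == 0L) next
      if (length(sel) == 0L) next
      enz_i <- if (config$mode == "inline") NULL else
        get_enzyme(sheet$enzyme[i], enzymes)
      seq1 <- substr(chunk1$sequence[sel], m$prefix_len[sel] + 1L,
                     nchar(chunk1$sequence[sel]))
      qual1 <- substr(chunk1$quality[sel], m$prefix_len[sel] + 1L,
                      nchar(chunk1$quality[sel]))
      orig1 <- list(sequence = seq1, quality = qual1)
      t1 <- trim_3prime_read1(seq1, qual1, enz_i, config)
      if (paired) {
        r2_5 <- .trim_5prime_read2(chunk2$sequence[sel], chunk2$quality[sel],
                                   enz_i, config)
        orig2 <- r2_5
        t2 <- trim_3prime_read2(r2_5$sequence, r2_5$quality, enz_i,
                                sheet$barcode[i], config)
        rec <- reconcile_pairs(t1, t2, orig1, orig2, enz_i, max_bl, config)
        out1 <- rec$r1; out2 <- rec$r2
      } else {
        out1 <- t1[c("sequence", "quality")]
        out2 <- NULL
      }
      write_fastq(data.frame(id = chunk1$id[sel], sequence = out1$sequence,
                             quality = out1$quality), path_of(s, 1L),
                  compress = gzip, append = TRUE)
      if (paired) {
        write_fastq(data.frame(id = chunk2$id[sel], sequence = out2$sequence,
                               quality = out2$quality), path_of(s, 2L),
                    compress = gzip, append = TRUE)
      }
      st <- get(s, envir = stats_env)
      st$reads <- st$reads + length(sel)
      mmtab <- tabulate(m$bc_mm[sel] + 1L, nbins = nmm)
      st$mm <- st$mm + mmtab
      bp <- sum(nchar(out1$sequence)) +
        if (paired) sum(nchar(out2$sequence)) else 0
      st$bp <- st$bp + bp
      qcat <- paste(c(out1$quality, if (paired) out2$quality), collapse = "")
      if (nzchar(qcat)) {
        st$qsum <- st$qsum + sum(utf8ToInt(qcat) - 33L)
        st$qn <- st$qn + nchar(qcat)
      }
      assign(s, st, envir = stats_env)
      if (collect) {
        assignments[[length(assignments) + 1L]] <- data.frame(
          id = chunk1$id[sel], sample = s, bc_mm = m$bc_mm[sel],
          len_r1 = nchar(out1$sequence),
          len_r2 = if (paired) nchar(out2$sequence) else NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  stats <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
    st <- get(sheet$sample[i], envir = stats_env)
    row <- data.frame(sample = sheet$sample[i], barcode = sheet$barcode[i],
                      enzyme = sheet$enzyme[i], reads = st$reads,
                      pct = if (n_total) round(100 * st$reads / n_total, 2) else 0,
                      stringsAsFactors = FALSE)
    for (j in seq_len(nmm)) row[[paste0("mm_", j - 1L)]] <- st$mm[j]
    row$basepairs <- st$bp
    row$mean_quality <- if (st$qn) round(st$qsum / st$qn, 2) else NA_real_
    row
  }))
  undc <- get("undetermined", envir = stats_env)$reads
  und_row <- stats[1, ]
  und_row$sample <- "undetermined"
  und_row$barcode <- ""
  und_row$enzyme <- ""
  und_row$reads <- undc
  und_row$pct <- if (n_total) round(100 * undc / n_total, 2) else 0
  for (j in seq_len(nmm)) und_row[[paste0("mm_", j - 1L)]] <- NA_integer_
  und_row$basepairs <- NA_real_
  und_row$mean_quality <- NA_real_
  stats <- rbind(stats, und_row)
  utils::write.table(stats, file.path(out_dir, "demux_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  res <- list(stats = stats, n_total = n_total, n_undetermined = undc,
              out_dir = out_dir, paired = paired, config = config)
  if (collect) {
    res$assignments <- if (length(assignments)) {
      do.call(rbind, assignments)
    } else {
      data.frame(id = character(0), sample = character(0),
                 bc_mm = integer(0), len_r1 = integer(0),
                 len_r2 = integer(0))
    }
  }
  class(res) <- "gbs_demux"
  res
}

#' @export
print.gbs_demux <- function(x, ...) {
  cat("<demultiplexing run>", x$n_total, "reads,",
      x$n_total - x$n_undetermined, "assigned,",
      x$n_undetermined, "undetermined\n")
  invisible(x)
}
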