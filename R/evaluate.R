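# Evaluation of demultiplexing and trimming against simulator ground truth.
#
# Trimming correctness is judged on read 1 (the read that carries the
# barcode; pairs are counted once). The expected trimmed length is pure
# geometry, derived from the fragment length, barcode length, site length,
# read length and mode -- never from the trimmer itself:
#
#   read 1 after 5' trimming holds L1 bases of insert (+ adapter), the
#   correct 3' trim point sits where genomic content gives way to the
#   terminal restriction site / adapter. In paired mode the consistency
#   correction harmonises both mates to the site-start trim point.

#' Expected trimmed read-1 length
#'
#' Geometric truth for a read simulated from a fragment of length
#' `frag_len` that starts and ends with a complete recognition-site match.
#' Vectorised over all arguments.
#'
#' Conventions (5' trim removes barcode plus site outside inline mode):
#' `gbs` trims read 1 back to the start of the terminal site
#' (`frag_len - 2 * site_len`); `rad` trims at the adapter, keeping the
#' terminal site single-end (`frag_len - site_len`) but harmonising to the
#' site start in paired mode via the mate correction; `inline` keeps both
#' sites (`frag_len`). All trim points are capped at the available read
#' length.
#'
#' @param frag_len Fragment length (bp), including both terminal sites.
#' @param barcode_len Barcode length (bp).
#' @param site_len Recognition-site length (bp).
#' @param read_length Raw read length (bp).
#' @param mode `"gbs"`, `"rad"` or `"inline"`.
#' @param paired Was the run paired-end (mate consistency correction
#'   active)?
#' @return Integer vector of expected read-1 lengths after all trimming.
#' @export
expected_read1_length <- function(frag_len, barcode_len, site_len,
                                  read_length, mode = "gbs",
                                  paired = TRUE) {
  k <- site_len
  L1 <- read_length - barcode_len - switch(mode, inline = 0L, k)
  trim_point <- switch(mode,
    gbs = frag_len - 2L * k,
    rad = if (paired) frag_len - 2L * k else frag_len - k,
    inline = frag_len
  )
  as.integer(pmin(trim_point, L1))
}

#' Demultiplexing sensitivity (percent)
#'
#' @param n_correct Correctly demultiplexed reads.
#' @param n_total Total simulated reads.
#' @return Percentage, rounded to two decimals.
#' @examples
#' demux_sensitivity(12394916, 12579549)  # 98.53
#' @export
demux_sensitivity <- function(n_correct, n_total) {
  round(100 * n_correct / n_total, 2)
}

#' Trimming sensitivity (percent of demultiplexed reads)
#'
#' @param n_correct_trim Correctly trimmed reads.
#' @param n_demultiplexed Correctly demultiplexed reads (the denominator:
#'   trimming is judged on the reads that were demultiplexed).
#' @return Percentage, rounded to two decimals.
#' @examples
#' trimming_sensitivity(12381497, 12394916)  # 99.89
#' @export
trimming_sensitivity <- function(n_correct_trim, n_demultiplexed) {
  round(100 * n_correct_trim / n_demultiplexed, 2)
}

#' Trimming errors per thousand demultiplexed reads
#'
#' @param n_correct_trim Correctly trimmed reads.
#' @param n_demultiplexed Correctly demultiplexed reads.
#' @return Errors per thousand (unrounded).
#' @export
trimming_errors_per_thousand <- function(n_correct_trim, n_demultiplexed) {
  1000 * (n_demultiplexed - n_correct_trim) / n_demultiplexed
}

#' Evaluate a demultiplexing run against simulator ground truth
#'
#' Compares per-sample demultiplexer output with the simulator's truth
#' table: sensitivity (correctly assigned / total simulated), misassignment
#' rate per million, and trimming correctness (read-1 trimmed length equal
#' to the geometric expectation of [expected_read1_length()]; any
#' deviation, over- or under-trimming, counts as incorrect).
#'
#' @param truth Truth data.frame from [simulate_reads()] (or path to a
#'   truth TSV).
#' @param demux A `gbs_demux` result (run with `collect = TRUE`), or the
#'   output directory of a run, from which per-sample R1 files are read.
#' @param mode,paired Demultiplexing mode and pairing used (defaults taken
#'   from `demux` when it is a `gbs_demux` object).
#' @param read_length Raw simulated read length (bp).
#' @return List of class `gbs_eval`: counts (`n_total`, `n_assigned`,
#'   `n_correct`, `n_misassigned`, `n_undetermined`, `n_correct_trim`) and
#'   rates (`sensitivity_pct`, `misassigned_per_million`,
#'   `trim_sensitivity_pct`, `trim_errors_per_thousand`).
#' @export
evaluate_demux <- function(truth, demux, mode = NULL, paired = NULL,
                           read_length = 100L) {
  if (is.character(truth) && length(truth) == 1L) {
    truth <- utils::read.table(truth, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  }
  if (inherits(demux, "gbs_demux")) {
    if (is.null(demux$assignments)) {
      stop("run demultiplex_run() with collect = TRUE, or pass its output ",
           "directory", call. = FALSE)
    }
    asg <- demux$assignments
    if (is.null(mode)) mode <- demux$config$mode
    if (is.null(paired)) paired <- demux$paired
  } else {
    files <- list.files(demux, pattern = "\\.R1\\.fastq(\\.gz)?$",
                        full.names = TRUE)
    files <- files[!grepl("undetermined", basename(files))]
    asg <- do.call(rbind, lapply(files, function(f) {
      recs <- read_fastq(f)
      sample <- sub("\\.R1\\.fastq(\\.gz)?$", "", basename(f))
      if (nrow(recs) == 0L) return(NULL)
      data.frame(id = recs$id, sample = sample,
                 len_r1 = nchar(recs$sequence), stringsAsFactors = FALSE)
    }))
    if (is.null(asg)) {
      asg <- data.frame(id = character(0), sample = character(0),
                        len_r1 = integer(0))
    }
    if (is.null(mode) || is.null(paired)) {
      stop("mode and paired must be given when evaluating from files",
           call. = FALSE)
    }
  }
  if (!all(asg$id %in% truth$id)) {
    stop("demultiplexer output contains read ids absent from the truth ",
         "table", call. = FALSE)
  }
  n_total <- nrow(truth)
  idx <- match(asg$id, truth$id)
  correct <- asg$sample == truth$sample[idx]
  n_correct <- sum(correct)
  n_mis <- sum(!correct)
  expected <- expected_read1_length(
    truth$frag_len[idx], truth$barcode_len[idx], truth$site_len[idx],
    read_length, mode = mode, paired = paired
  )
  trim_ok <- correct & asg$len_r1 == expected
  n_trim <- sum(trim_ok)

  structure(list(
    n_total = n_total,
    n_assigned = nrow(asg),
    n_correct = n_correct,
    n_misassigned = n_mis,
    n_undetermined = n_total - nrow(asg),
    n_correct_trim = n_trim,
    sensitivity_pct = demux_sensitivity(n_correct, n_total),
    misassigned_per_million = round(1e6 * n_mis / n_total, 1),
    trim_sensitivity_pct = trimming_sensitivity(n_trim, n_correct),
    trim_errors_per_thousand = trimming_errors_per_thousand(n_trim, n_correct),
    mode = mode, paired = paired
  ), class = "gbs_eval")
}

#' @export
print.gbs_eval <- function(x, ...) {
  cat("<demultiplexing evaluation>", x$mode,
      if (x$paired) "paired-end" else "single-end", "\n")
  cat(sprintf("  sensitivity: %0.2f%% (%d / %d)\n", x$sensitivity_pct,
              x$n_correct, x$n_total))
  cat(sprintf("  misassigned per million: %0.1f\n", x$misassigned_per_million))
  cat(sprintf("  trimming sensitivity: %0.2f%% (%d / %d)\n",
              x$trim_sensitivity_pct, x$n_correct_trim, x$n_correct))
  cat(sprintf("  trimming errors per thousand: %0.2f\n",
              x$trim_errors_per_thousand))
  invisible(x)
}

#' Write an evaluation report as tab-delimited text
#'
#' @param eval A `gbs_eval` object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  fields <- c("mode", "paired", "n_total", "n_assigned", "n_correct",
              "n_misassigned", "n_undetermined", "n_correct_trim",
              "sensitivity_pct", "misassigned_per_million",
              "trim_sensitivity_pct", "trim_errors_per_thousand")
  writeLines(paste(fields, vapply(fields, function(f) {
    as.character(eval[[f]])
  }, character(1)), sep = "\t"), path)
  invisible(path)
}
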