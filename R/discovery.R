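# Candidate in-line barcode discovery: counts read prefixes of each length,
# keyed by the enzyme whose recognition site follows the prefix.

#' Discover candidate in-line barcodes in a FASTQ file
#'
#' For every read and every candidate length `L` in `[min_len, max_len]`,
#' the first `L` bases are taken as a candidate barcode. For every enzyme
#' whose recognition site matches (IUPAC-aware, zero mismatches) at offset
#' `L`, the (prefix, enzyme) pair is counted; with `include_no_enzyme` the
#' prefix is additionally counted unconditionally under enzyme `"none"`.
#' Prefixes containing `N` are skipped (tallied separately). Typical use:
#' run on the demultiplexer's undetermined output to recover barcodes
#' missing from the sample sheet.
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param enzymes Enzyme table to screen (default: built-ins).
#' @param min_len,max_len Candidate barcode length range (defaults 6-16).
#' @param include_no_enzyme Also count prefixes with no site requirement.
#' @param out_dir If non-`NULL`, write one `barcodes_L<length>.tsv` per
#'   length (columns `barcode`, `enzyme`, `count`, sorted by descending
#'   count).
#' @return Named list (one element per length) of data.frames with columns
#'   `barcode`, `enzyme`, `count`; attribute `skipped` holds the per-length
#'   tally of N-containing prefixes.
#' @export
discover_barcodes <- function(fastq, enzymes = default_enzymes(),
                              min_len = 6L, max_len = 16L,
                              include_no_enzyme = FALSE, out_dir = NULL) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  reads <- read_fastq(fastq)
  seqs <- reads$sequence
  lens <- nchar(seqs)
  out <- list()
  skipped <- integer(0)
  enz_names <- vapply(enzymes, function(e) e$name, character(1))
  recs <- vapply(enzymes, function(e) e$recognition, character(1))

  for (L in seq(min_len, max_len)) {
    key <- paste0("L", L)
    long_enough <- lens >= L
    prefix <- substr(seqs, 1L, L)
    has_n <- grepl("N", prefix, fixed = TRUE)
    usable <- long_enough & !has_n
    skipped[key] <- sum(long_enough & has_n)
    tabs <- list()
    if (any(usable)) {
      for (ei in seq_along(enzymes)) {
        k <- nchar(recs[ei])
        ok <- usable & lens >= L + k
        if (!any(ok)) next
        window <- substr(seqs[ok], L + 1L, L + k)
        pm <- .pattern_mask(strsplit(recs[ei], "", fixed = TRUE)[[1]])
        wm <- matrix(.read_mask(.pad_char_matrix(window, k)), nrow = k)
        hit <- .mm_colsums(wm, pm) == 0L
        if (any(hit)) {
          tab <- table(prefix[ok][hit])
          tabs[[length(tabs) + 1L]] <- data.frame(
            barcode = names(tab), enzyme = unname(enz_names[ei]),
            count = as.integer(tab), stringsAsFactors = FALSE
          )
        }
      }
      if (include_no_enzyme) {
        tab <- table(prefix[usable])
        tabs[[length(tabs) + 1L]] <- data.frame(
          barcode = names(tab), enzyme = "none",
          count = as.integer(tab), stringsAsFactors = FALSE
        )
      }
    }
    df <- if (length(tabs)) do.call(rbind, tabs) else
      data.frame(barcode = character(0), enzyme = character(0),
                 count = integer(0))
    df <- df[order(-df$count, df$barcode), , drop = FALSE]
    rownames(df) <- NULL
    out[[key]] <- df
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(df, file.path(out_dir, paste0("barcodes_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  attr(out, "skipped") <- skipped
  out
}
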