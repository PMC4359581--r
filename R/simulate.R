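# GBS read simulator with per-read ground truth.
#
# Reads are generated from restriction fragments (sequences starting and
# ending with a concrete recognition-site match), completed with the common
# adapter and poly-A padding when the template is exhausted. An equal
# number of reads comes from each fragment end. Substitution errors are
# independent per base (probability error_rate) to a uniformly random
# different symbol from {A,C,G,T,N}. Qualities are constant 'I' (Phred 40).

.DEFAULT_ADAPTER <- "AGATCGGAAGAGCG"  # 14 bp common adapter

#' Simulation configuration
#'
#' @param read_length Read length in bp (default 100).
#' @param reads_per_locus Total reads (single-end) or pairs (paired-end)
#'   generated per sample per fragment; must be even (split equally over
#'   the two fragment ends).
#' @param paired Generate read pairs.
#' @param error_rate Independent per-base substitution probability
#'   (default 0.01, i.e. on average one error every 100 bases).
#' @param adapter Common adapter appended after the insert (+barcode
#'   read-through on read 2).
#' @param seed Optional RNG seed for fully deterministic output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(read_length = 100L, reads_per_locus = 2L,
                       paired = TRUE, error_rate = 0.01,
                       adapter = .DEFAULT_ADAPTER, seed = NULL) {
  stopifnot(read_length > 0L, reads_per_locus >= 2L,
            reads_per_locus %% 2L == 0L, error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 reads_per_locus = as.integer(reads_per_locus),
                 paired = isTRUE(paired), error_rate = error_rate,
                 adapter = toupper(adapter), seed = seed),
            class = "sim_config")
}

# draw one concrete expansion of a degenerate IUPAC sequence
.concretize <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  picks <- vapply(chars, function(ch) {
    mask <- .IUPAC_MASK[[ch]]
    opts <- c("A", "C", "G", "T")[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste(picks, collapse = "")
}

.random_seq <- function(len) {
  if (len <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate random restriction fragments
#'
#' Synthesises fragments directly: a concrete expansion of the recognition
#' site, a random insert, and another concrete site expansion, with total
#' lengths uniform over `[min_len, max_len]`. Every sequence starts and
#' ends with a recognition-site match, and -- as in any complete digest,
#' where an internal site would itself have been cut -- inserts containing
#' an internal recognition match are redrawn.
#'
#' @param n Number of fragments.
#' @param enz Enzyme (name or `gbs_enzyme`).
#' @param min_len,max_len Fragment length range (bp), inclusive.
#' @param seed Optional RNG seed.
#' @return Named character vector of fragment sequences.
#' @export
random_fragments <- function(n, enz, min_len = 60L, max_len = 200L,
                             seed = NULL) {
  enz <- get_enzyme(enz)
  k <- nchar(enz$recognition)
  stopifnot(min_len >= 2L * k + 1L, min_len <= max_len)
  if (!is.null(seed)) set.seed(seed)
  lens <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
  frags <- vapply(lens, function(L) {
    repeat {
      f <- paste0(.concretize(enz$recognition), .random_seq(L - 2L * k),
                  .concretize(enz$recognition))
      # a fragment of a complete digest carries no internal cut site
      inner <- Biostrings::matchPattern(enz$recognition,
                                        Biostrings::DNAString(f),
                                        fixed = "subject")
      starts <- BiocGenerics::start(inner)
      if (all(starts %in% c(1L, L - k + 1L))) return(f)
    }
  }, character(1))
  stats::setNames(frags, sprintf("frag%05d", seq_len(n)))
}

#' Build a fragment FASTA for the simulator
#'
#' Either synthesises random fragments (`reference = NULL`) or digests a
#' reference genome and extracts the size-selected fragments with their
#' frames extended over the flanking recognition sites, so every output
#' sequence starts and ends with a site match.
#'
#' @param reference Optional path to (or data.frame of) a reference FASTA.
#' @param enz Enzyme (name or `gbs_enzyme`).
#' @param n Number of fragments in random mode.
#' @param min_len,max_len Fragment size selection (bp).
#' @param seed Optional RNG seed (random mode).
#' @param out Optional output FASTA path.
#' @param enzymes Enzyme table.
#' @return Named character vector of fragment sequences.
#' @export
build_fragment_fasta <- function(reference = NULL, enz = "ApeKI", n = 500L,
                                 min_len = 60L, max_len = 200L, seed = NULL,
                                 out = NULL, enzymes = default_enzymes()) {
  enz <- get_enzyme(enz, enzymes)
  if (is.null(reference)) {
    frags <- random_fragments(n, enz, min_len, max_len, seed)
  } else {
    genome <- if (is.data.frame(reference)) reference else
      read_fasta(reference)
    dg <- digest_genome(genome, enz, min_fragment = min_len,
                        max_fragment = max_len, enzymes = enzymes)
    sel <- dg$selected
    k <- nchar(enz$recognition)
    o <- enz$cut_offset
    frags <- character(0)
    for (ch in unique(sel$chrom)) {
      s <- genome$sequence[genome$id == ch][1]
      rows <- sel[sel$chrom == ch, , drop = FALSE]
      start <- pmax(0L, rows$start - o)
      end <- pmin(nchar(s), rows$end + (k - o))
      fr <- substring(s, start + 1L, end)
      names(fr) <- sprintf("%s_%d_%d", ch, start, end)
      frags <- c(frags, fr)
    }
  }
  if (!is.null(out)) write_fasta(frags, out)
  frags
}

.inject_errors <- function(seqs, error_rate) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  if (error_rate <= 0 || n == 0L) {
    return(list(sequence = seqs,
                errors = matrix(FALSE, nrow = L, ncol = n)))
  }
  M <- .pad_char_matrix(seqs, L)
  err <- matrix(stats::runif(L * n) < error_rate, nrow = L)
  idx <- which(err)
  if (length(idx)) {
    cur <- M[idx]
    # replace with a uniformly random *different* symbol from {A,C,G,T,N}
    symbols <- c("A", "C", "G", "T", "N")
    alt <- vapply(symbols, function(s) setdiff(symbols, s),
                  character(4))  # 4 x 5 matrix, column = current symbol
    pick <- sample.int(4L, length(idx), replace = TRUE)
    M[idx] <- alt[cbind(pick, match(cur, symbols))]
  }
  seqs <- do.call(paste0, lapply(seq_len(L), function(r) M[r, ]))
  list(sequence = seqs, errors = err)
}

#' Simulate GBS reads with ground truth
#'
#' For each (barcode, fragment, end) combination, read 1 is the first
#' `read_length` bases of `barcode + fragment + adapter + AAA...` and
#' read 2 (paired) the first `read_length` bases of
#' `revcomp(barcode + fragment) + adapter + AAA...`; reads from the
#' opposite fragment end use the reverse-complemented fragment. Errors are
#' injected per [sim_config()]. Sample names `S01, S02, ...` are assigned
#' to the barcodes in order.
#'
#' @param fragments Named character vector of fragment sequences (or a path
#'   to a fragment FASTA).
#' @param barcodes data.frame with columns `barcode`, `enzyme` (or a path
#'   to a barcode file).
#' @param config A [sim_config()].
#' @param out_dir If non-`NULL`, write `reads.R1.fastq`, `reads.R2.fastq`
#'   (paired), `truth.tsv` and `summary.tsv` there.
#' @param enzymes Enzyme table.
#' @return List of class `gbs_sim` with `r1`, `r2` (record data.frames),
#'   `truth` (per-pair sample, fragment, end, fragment length, barcode
#'   length, site length, barcode-region error count) and `summary`
#'   (reads by barcode-region error count).
#' @export
simulate_reads <- function(fragments, barcodes, config = sim_config(),
                           out_dir = NULL, enzymes = default_enzymes()) {
  if (is.character(fragments) && length(fragments) == 1L &&
      file.exists(fragments)) {
    fa <- read_fasta(fragments)
    fragments <- stats::setNames(fa$sequence, fa$id)
  }
  if (is.character(barcodes) && length(barcodes) == 1L &&
      file.exists(barcodes)) {
    barcodes <- read_barcode_file(barcodes, enzymes)
  }
  stopifnot(length(fragments) >= 1L, nrow(barcodes) >= 1L)
  if (any(nchar(barcodes$barcode) > config$read_length)) {
    stop("barcode longer than the read length", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$read_length
  reps <- config$reads_per_locus %/% 2L
  samples <- sprintf("S%02d", seq_len(nrow(barcodes)))
  site_len <- vapply(barcodes$enzyme, function(e) {
    nchar(get_enzyme(e, enzymes)$recognition)
  }, integer(1))

  grid <- expand.grid(frag = seq_along(fragments),
                      samp = seq_len(nrow(barcodes)),
                      end = c("fwd", "rev"), rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  bc <- barcodes$barcode[grid$samp]
  frag_seq <- unname(fragments[grid$frag])
  frag_seq[grid$end == "rev"] <- revcomp_dna(frag_seq[grid$end == "rev"])
  ids <- paste(samples[grid$samp], names(fragments)[grid$frag], grid$end,
               grid$rep, sep = ":")

  template1 <- paste0(bc, frag_seq, config$adapter)
  r1 <- substr(template1, 1L, L)
  pad <- pmax(0L, L - nchar(r1))
  r1 <- paste0(r1, strrep("A", pad))
  e1 <- .inject_errors(r1, config$error_rate)

  truth <- data.frame(
    id = ids, sample = samples[grid$samp],
    fragment = names(fragments)[grid$frag], end = grid$end,
    frag_len = nchar(frag_seq), barcode_len = nchar(bc),
    site_len = site_len[grid$samp], stringsAsFactors = FALSE
  )
  # barcode-region errors from the injection mask itself, independent of
  # any downstream matching
  bl <- nchar(bc)
  truth$bc_errors <- vapply(seq_along(ids), function(i) {
    sum(e1$errors[seq_len(bl[i]), i])
  }, integer(1))

  qual <- strrep("I", L)
  r1_df <- data.frame(id = ids, sequence = e1$sequence, quality = qual,
                      stringsAsFactors = FALSE)
  r2_df <- NULL
  if (config$paired) {
    template2 <- paste0(revcomp_dna(paste0(bc, frag_seq)), config$adapter)
    r2 <- substr(template2, 1L, L)
    pad2 <- pmax(0L, L - nchar(r2))
    r2 <- paste0(r2, strrep("A", pad2))
    e2 <- .inject_errors(r2, config$error_rate)
    r2_df <- data.frame(id = ids, sequence = e2$sequence, quality = qual,
                        stringsAsFactors = FALSE)
  }

  summary <- as.data.frame(table(bc_errors = truth$bc_errors),
                           stringsAsFactors = FALSE)
  names(summary) <- c("barcode_errors", "reads")

  res <- structure(list(r1 = r1_df, r2 = r2_df, truth = truth,
                        summary = summary, config = config),
                   class = "gbs_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(r1_df, file.path(out_dir, "reads.R1.fastq"))
    if (config$paired) {
      write_fastq(r2_df, file.path(out_dir, "reads.R2.fastq"))
    }
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  res
}

#' @export
print.gbs_sim <- function(x, ...) {
  cat("<simulated GBS reads>", nrow(x$r1),
      if (!is.null(x$r2)) "pairs" else "reads",
      "from", length(unique(x$truth$fragment)), "fragments x",
      length(unique(x$truth$sample)), "samples\n")
  invisible(x)
}
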