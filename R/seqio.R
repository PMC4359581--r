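# Streaming readers/writers for FASTQ (plain or gzip), FASTA and BED.
# FASTQ records are plain data.frames with columns id, sequence, quality;
# sequences are uppercased on ingest, qualities are never altered.

.open_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # gzfile() inspects the magic bytes, so plain and gzip-compressed files
  # are read identically regardless of extension.
  gzfile(path, open = "rt")
}

.parse_fastq_lines <- function(lines, first_record = 1L) {
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ: truncated record at record ",
         first_record + n %/% 4L, call. = FALSE)
  }
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record at record ", first_record + bad[1] - 1L,
         call. = FALSE)
  }
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism)) {
    stop("FASTQ sequence/quality length mismatch at record ",
         first_record + mism[1] - 1L, call. = FALSE)
  }
  data.frame(
    id = sub("^@", "", ids),
    sequence = toupper(seqs),
    quality = quals,
    stringsAsFactors = FALSE
  )
}

#' Read a FASTQ file
#'
#' Reads a plain or gzip-compressed FASTQ file (compression is detected from
#' the file content, not the extension). Sequences are uppercased; qualities
#' are kept verbatim (Phred+33 assumed).
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- .open_read(path)
  on.exit(close(con))
  .parse_fastq_lines(readLines(con, warn = FALSE))
}

#' Chunked FASTQ reader
#'
#' Returns a closure that yields successive chunks of records as
#' data.frames, or `NULL` when the file is exhausted. Used by the
#' demultiplexer to stream arbitrarily large inputs.
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @param chunk_size Number of records per chunk.
#' @return A function `function() -> data.frame | NULL`.
#' @export
fastq_chunk_reader <- function(path, chunk_size = 50000L) {
  con <- .open_read(path)
  done <- FALSE
  record_at <- 1L
  function() {
    if (done) return(NULL)
    lines <- readLines(con, n = 4L * chunk_size, warn = FALSE)
    if (length(lines) == 0L) {
      done <<- TRUE
      close(con)
      return(NULL)
    }
    recs <- .parse_fastq_lines(lines, first_record = record_at)
    record_at <<- record_at + nrow(recs)
    if (length(lines) < 4L * chunk_size) {
      done <<- TRUE
      close(con)
    }
    recs
  }
}

#' Write a FASTQ file
#'
#' @param records data.frame with columns `id`, `sequence`, `quality`.
#' @param path Destination path.
#' @param compress Write gzip-compressed output.
#' @param append Append to an existing file instead of truncating.
#' @return Number of records written, invisibly.
#' @export
write_fastq <- function(records, path, compress = FALSE, append = FALSE) {
  con <- if (compress) {
    gzfile(path, open = if (append) "ab" else "wb")
  } else {
    file(path, open = if (append) "at" else "wt")
  }
  on.exit(close(con))
  n <- nrow(records)
  if (n > 0L) {
    lines <- as.vector(rbind(paste0("@", records$id), records$sequence,
                             "+", records$quality))
    writeLines(lines, con)
  } else if (!append) {
    # truncate to an empty file
  }
  invisible(n)
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; multi-line sequences
#' are concatenated and sequence identifiers are taken as the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence` (uppercased).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(id = ids, sequence = toupper(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences, or a data.frame with
#'   columns `id` and `sequence`.
#' @param path Destination path.
#' @param width Line width for sequence wrapping.
#' @return Number of records written, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) {
    seqs <- stats::setNames(seqs$sequence, seqs$id)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(length(seqs))
}

#' Write a BED4 file
#'
#' Intervals are 0-based, half-open `[start, end)` per the BED standard.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `name`.
#' @param path Destination path.
#' @return Number of intervals written, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$end <= intervals$start)) {
    stop("BED intervals must satisfy end > start", call. = FALSE)
  }
  utils::write.table(
    intervals[, c("chrom", "start", "end", "name")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(nrow(intervals))
}
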