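# Random self-correcting in-line barcode design.
#
# Barcodes are prefixes of Hamming(15,11) nucleotide codewords (see
# hamming.R). A barcode of target length l <= 15 is built by drawing a
# random 11-nucleotide data word whose trailing data positions (codeword
# positions > l) are forced to A -- the polyA padding -- encoding it, and
# keeping the first l positions. Re-appending A up to length 15 recovers a
# valid codeword, so single-substitution correction is retained. Lengths of
# at least 8 keep all four parity positions, which gives the algebraic
# distance-3 guarantee between same-length barcodes; everything else
# (cross-length separation, enzyme-site avoidance, prefix collisions) is
# enforced by explicit rejection. Length 16 extends a full 15-frame
# codeword by one random base and relies on the rejection checks alone.

.MIN_ALGEBRAIC_LEN <- 8L
.FRAME_LEN <- 15L

# positions of the codeword (1-based) that carry data symbols
.frame_data_positions <- function() .H_DATA

.random_barcode <- function(len) {
  if (len >= .FRAME_LEN) {
    data <- paste(sample(c("A", "C", "G", "T"), .H_K, replace = TRUE),
                  collapse = "")
    word <- encode_hamming(data)
    if (len == .FRAME_LEN) return(word)
    return(paste0(word, paste(sample(c("A", "C", "G", "T"), len - .FRAME_LEN,
                                     replace = TRUE), collapse = "")))
  }
  data_chars <- sample(c("A", "C", "G", "T"), .H_K, replace = TRUE)
  # polyA padding: data symbols living at codeword positions beyond the
  # barcode length are forced to A so truncation is reversible
  data_chars[.H_DATA > len] <- "A"
  word <- encode_hamming(paste(data_chars, collapse = ""))
  substr(word, 1L, len)
}

#' Pad a barcode back to its length-15 codeword frame
#'
#' Re-appends the polyA padding removed at design time. Only meaningful for
#' barcodes of length <= 15.
#'
#' @param barcode Barcode string.
#' @return 15-nucleotide string.
#' @export
barcode_frame <- function(barcode) {
  l <- nchar(barcode)
  if (l > .FRAME_LEN) stop("barcode longer than the codeword frame",
                           call. = FALSE)
  paste0(barcode, strrep("A", .FRAME_LEN - l))
}

# any IUPAC-aware match of the recognition site inside barcode+recognition,
# other than the legitimate one at the junction, disqualifies a candidate
.has_internal_site <- function(barcode, recognition) {
  s <- paste0(barcode, recognition)
  k <- nchar(recognition)
  legit <- nchar(barcode) + 1L
  pm <- .pattern_mask(strsplit(recognition, "", fixed = TRUE)[[1]])
  sm <- c(.read_mask(strsplit(barcode, "", fixed = TRUE)[[1]]),
          .pattern_mask(strsplit(recognition, "", fixed = TRUE)[[1]]))
  for (i in seq_len(nchar(s) - k + 1L)) {
    if (i == legit) next
    if (all(bitwAnd(pm, sm[i:(i + k - 1L)]) > 0L)) return(TRUE)
  }
  FALSE
}

#' Prefix-aligned distance between two barcodes in their enzyme context
#'
#' Appends the enzyme recognition sequence to both barcodes and counts
#' mismatching positions over the common prefix. A position where either
#' side carries a degenerate code counts 0 when the expansions intersect
#' (worst case: separability is never overestimated). This is the distance
#' the demultiplexer effectively sees when reads start with
#' barcode+restriction site, and the quantity the design keeps >= 3.
#'
#' @param b1,b2 Barcode strings.
#' @param enz A `gbs_enzyme` (or name resolvable via [get_enzyme()]).
#' @return Integer distance.
#' @examples
#' apeki <- get_enzyme("ApeKI")
#' combined_distance("ACGTACGT", "ACGTACGT", apeki)  # 0
#' @export
combined_distance <- function(b1, b2, enz) {
  enz <- get_enzyme(enz)
  s1 <- paste0(toupper(b1), enz$recognition)
  s2 <- paste0(toupper(b2), enz$recognition)
  n <- min(nchar(s1), nchar(s2))
  m1 <- .pattern_mask(strsplit(substr(s1, 1, n), "", fixed = TRUE)[[1]])
  m2 <- .pattern_mask(strsplit(substr(s2, 1, n), "", fixed = TRUE)[[1]])
  sum(bitwAnd(m1, m2) == 0L)
}

.candidate_valid <- function(cand, accepted, enz) {
  rec <- enz$recognition
  if (.has_internal_site(cand, rec)) return(FALSE)
  for (acc in accepted) {
    if (combined_distance(cand, acc, enz) < 3L) return(FALSE)
    # prefix rule: a barcode must not be a (IUPAC-compatible) prefix of
    # another barcode's sequence+recognition string
    if (.compatible_prefix(cand, paste0(acc, rec)) &&
        nchar(cand) <= nchar(paste0(acc, rec))) return(FALSE)
    if (.compatible_prefix(acc, paste0(cand, rec)) &&
        nchar(acc) <= nchar(paste0(cand, rec))) return(FALSE)
  }
  TRUE
}

#' Generate a random self-correcting barcode set
#'
#' Draws random Hamming-coded barcodes with lengths cycling over
#' `[min_len, max_len]`, rejecting candidates that contain (or create at the
#' enzyme junction) a recognition site, collide as prefixes, or fall below
#' the pairwise combined distance of 3. Among the valid candidates collected
#' for each slot, the one that best balances per-position nucleotide usage
#' across the set so far is kept. Deterministic under a fixed `seed`.
#'
#' @param n Number of barcodes.
#' @param enz Design enzyme (name or `gbs_enzyme`).
#' @param min_len,max_len Barcode length range (defaults 8-16; lengths up
#'   to 15 carry the full algebraic guarantee, length 16 is check-enforced).
#' @param seed Optional RNG seed (`set.seed`) for reproducible sets.
#' @param max_attempts Candidate draws allowed per barcode slot before
#'   giving up.
#' @param pool_size Valid candidates collected per slot before the
#'   balance-based choice.
#' @return Object of class `gbs_barcode_set`: list with `barcodes`
#'   (character vector) and `enzyme`.
#' @examples
#' set <- generate_barcodes(6, "ApeKI", seed = 1)
#' validate_barcode_set(set)   # zero-row violation report
#' @export
generate_barcodes <- function(n, enz, min_len = 8L, max_len = 16L,
                              seed = NULL, max_attempts = 5000L,
                              pool_size = 8L) {
  stopifnot(n >= 1L)
  if (min_len < .MIN_ALGEBRAIC_LEN || max_len > 16L || min_len > max_len) {
    stop("barcode lengths must satisfy 8 <= min_len <= max_len <= 16",
         call. = FALSE)
  }
  enz <- get_enzyme(enz)
  if (!is.null(seed)) set.seed(seed)
  lens <- rep(seq(min_len, max_len), length.out = n)
  accepted <- character(0)
  # per-position nucleotide counts over accepted barcodes, for balancing
  counts <- matrix(0L, nrow = 4L, ncol = max_len,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (slot in seq_len(n)) {
    target <- lens[slot]
    pool <- character(0)
    attempts <- 0L
    while (length(pool) < pool_size && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- .random_barcode(target)
      if (cand %in% pool) next
      if (.candidate_valid(cand, accepted, enz)) pool <- c(pool, cand)
    }
    if (length(pool) == 0L) {
      stop("could not generate barcode ", slot, " of ", n,
           " within the attempt budget; try fewer barcodes or a wider ",
           "length range", call. = FALSE)
    }
    # prefer the candidate whose bases are rarest at their positions
    score <- vapply(pool, function(b) {
      ch <- strsplit(b, "", fixed = TRUE)[[1]]
      sum(counts[cbind(match(ch, rownames(counts)), seq_along(ch))])
    }, numeric(1))
    best <- pool[which.min(score)]
    ch <- strsplit(best, "", fixed = TRUE)[[1]]
    idx <- cbind(match(ch, rownames(counts)), seq_along(ch))
    counts[idx] <- counts[idx] + 1L
    accepted <- c(accepted, best)
  }
  structure(list(barcodes = accepted, enzyme = enz),
            class = "gbs_barcode_set")
}

#' Validate a barcode set against all design constraints
#'
#' Checks pairwise combined distance (>= 3), prefix collisions,
#' internal/junction enzyme-site content and length bounds. The generator's
#' output always yields an empty report.
#'
#' @param set A `gbs_barcode_set`, or a character vector of barcodes plus
#'   `enz`.
#' @param enz Enzyme, required when `set` is a plain character vector.
#' @return data.frame of violations (`type`, `barcode1`, `barcode2`,
#'   `detail`); zero rows when the set is valid.
#' @export
validate_barcode_set <- function(set, enz = NULL) {
  if (inherits(set, "gbs_barcode_set")) {
    barcodes <- set$barcodes
    enz <- set$enzyme
  } else {
    barcodes <- set
    enz <- get_enzyme(enz)
  }
  rec <- enz$recognition
  v <- list()
  add <- function(type, b1, b2, detail) {
    v[[length(v) + 1L]] <<- data.frame(type = type, barcode1 = b1,
                                       barcode2 = b2, detail = detail)
  }
  for (i in seq_along(barcodes)) {
    b <- barcodes[i]
    if (!.is_dna(b)) add("alphabet", b, NA, "not a plain DNA sequence")
    if (nchar(b) < 1L) add("length", b, NA, "empty barcode")
    if (.has_internal_site(b, rec)) {
      add("site_content", b, NA,
          paste0("contains or creates a ", enz$name, " site"))
    }
  }
  if (anyDuplicated(barcodes)) {
    add("duplicate", barcodes[duplicated(barcodes)][1], NA, "duplicate barcode")
  }
  if (length(barcodes) >= 2L) {
    for (i in seq_len(length(barcodes) - 1L)) {
      for (j in seq(i + 1L, length(barcodes))) {
        d <- combined_distance(barcodes[i], barcodes[j], enz)
        if (d < 3L) {
          add("distance", barcodes[i], barcodes[j],
              paste0("combined distance ", d, " < 3"))
        }
        si <- barcodes[i]; sj <- barcodes[j]
        if ((.compatible_prefix(si, paste0(sj, rec)) &&
             nchar(si) <= nchar(paste0(sj, rec))) ||
            (.compatible_prefix(sj, paste0(si, rec)) &&
             nchar(sj) <= nchar(paste0(si, rec)))) {
          add("prefix", si, sj, "one barcode is a prefix of the other's barcode+site")
        }
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(type = character(0), barcode1 = character(0),
               barcode2 = character(0), detail = character(0))
}

#' @export
print.gbs_barcode_set <- function(x, ...) {
  cat("<barcode set>", length(x$barcodes), "barcodes, enzyme",
      x$enzyme$name, "\n")
  cat("  lengths:", paste(range(nchar(x$barcodes)), collapse = "-"), "\n")
  invisible(x)
}

#' Write a barcode file (barcode<TAB>enzyme)
#'
#' The format consumed by the simulator; prepend sample names to obtain a
#' demultiplexer sample sheet.
#'
#' @param set A `gbs_barcode_set`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_barcode_file <- function(set, path) {
  writeLines(paste(set$barcodes, set$enzyme$name, sep = "\t"), path)
  invisible(path)
}

#' Read a barcode file (barcode<TAB>enzyme)
#'
#' @param path Path to a tab-delimited barcode file.
#' @param enzymes Enzyme table for name resolution.
#' @return data.frame with columns `barcode`, `enzyme`.
#' @export
read_barcode_file <- function(path, enzymes = default_enzymes()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:2] <- c("barcode", "enzyme")
  df$barcode <- toupper(df$barcode)
  if (!all(.is_dna(df$barcode))) {
    stop("barcode file contains non-DNA barcodes", call. = FALSE)
  }
  for (e in unique(df$enzyme)) get_enzyme(e, enzymes)
  df[, c("barcode", "enzyme")]
}
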