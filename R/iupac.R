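# IUPAC nucleotide codes as bitmasks over {A=1, C=2, G=4, T=8}.
# Two alphabets are distinguished throughout the package:
#   * pattern characters (enzyme recognition sequences) may be degenerate,
#     N on the pattern side matches every base;
#   * read characters are observed bases, N on the read side matches
#     nothing and always counts as a mismatch.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.READ_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.pattern_mask <- function(chars) {
  m <- .IUPAC_MASK[chars]
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(m)
}

# Unknown read characters (N, pad characters, ...) get mask 0: never match.
.read_mask <- function(chars) {
  m <- .READ_MASK[chars]
  m[is.na(m)] <- 0L
  unname(m)
}

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet (degenerate codes are complemented as
#' sets, e.g. `W -> W`, `R -> Y`). Vectorised over `x`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp_dna("GCWGC")  # "GCWGC": ApeKI's site is its own reverse complement
#' @export
revcomp_dna <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Does a degenerate pattern character match an observed base?
#'
#' An observed `N` matches nothing: it inflates mismatch counts rather than
#' letting N-rich reads match every sample.
#'
#' @param pattern_char Single IUPAC code (pattern side).
#' @param base Single observed base, one of A, C, G, T, N.
#' @return `TRUE` if `base` is in the expansion of `pattern_char`.
#' @examples
#' iupac_match("W", "A")  # TRUE
#' iupac_match("W", "C")  # FALSE
#' iupac_match("W", "N")  # FALSE: read-side N never matches
#' @export
iupac_match <- function(pattern_char, base) {
  bitwAnd(.pattern_mask(pattern_char), .read_mask(base)) > 0L
}

#' Count mismatches between a degenerate pattern and a read window
#'
#' Position-wise comparison of an IUPAC pattern against an equal-length
#' window of observed bases; a position counts as a mismatch when the
#' observed base is not in the pattern expansion (see [iupac_match()]).
#'
#' @param pattern IUPAC pattern string.
#' @param window Observed bases, same length as `pattern`.
#' @return Integer mismatch count.
#' @examples
#' site_mismatches("GCWGC", "GCAGC")  # 0
#' site_mismatches("GCWGC", "GCACC")  # 1
#' @export
site_mismatches <- function(pattern, window) {
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal length", call. = FALSE)
  }
  pm <- .pattern_mask(strsplit(toupper(pattern), "", fixed = TRUE)[[1]])
  rm <- .read_mask(strsplit(toupper(window), "", fixed = TRUE)[[1]])
  sum(bitwAnd(pm, rm) == 0L)
}

# Do the IUPAC expansions of two (possibly degenerate) strings intersect at
# every position of their common prefix? Used for prefix-collision checks.
.compatible_prefix <- function(s1, s2) {
  n <- min(nchar(s1), nchar(s2))
  if (n == 0L) return(TRUE)
  m1 <- .pattern_mask(strsplit(substr(s1, 1L, n), "", fixed = TRUE)[[1]])
  m2 <- .pattern_mask(strsplit(substr(s2, 1L, n), "", fixed = TRUE)[[1]])
  all(bitwAnd(m1, m2) > 0L)
}

.is_dna <- function(x, alphabet = c("A", "C", "G", "T")) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)
  vapply(chars, function(ch) length(ch) > 0L && all(ch %in% alphabet), logical(1))
}

.is_iupac <- function(x) .is_dna(x, alphabet = names(.IUPAC_MASK))
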