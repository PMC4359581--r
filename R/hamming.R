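# Hamming(15,11) over nucleotides, implemented per bit plane.
#
# Each nucleotide carries 2 bits (A=00, C=01, G=10, T=11). The high and low
# bit planes of an 11-nucleotide data word are each encoded with the binary
# Hamming(15,11) code (parity bits at 1-based positions 1, 2, 4, 8; data at
# the remaining positions) and the two 15-bit codewords are recombined into
# a 15-nucleotide word. Consequences:
#   * any two codewords differ in >= 3 nucleotide positions (each nonzero
#     plane difference has Hamming weight >= 3 and nucleotide differences
#     are the union of the plane supports);
#   * a single nucleotide substitution flips 1-2 bits at one position, i.e.
#     at most one bit per plane, so per-plane syndrome decoding corrects it.

.H_PARITY <- c(1L, 2L, 4L, 8L)
.H_DATA <- setdiff(1:15, .H_PARITY)
.H_N <- 15L
.H_K <- 11L

.nt2val <- function(chars) {
  v <- match(chars, c("A", "C", "G", "T")) - 1L
  if (anyNA(v)) stop("sequence must be over A,C,G,T", call. = FALSE)
  v
}

.val2nt <- function(vals) c("A", "C", "G", "T")[vals + 1L]

.encode_plane <- function(databits) {
  cw <- integer(.H_N)
  cw[.H_DATA] <- databits
  for (p in .H_PARITY) {
    covered <- setdiff(which(bitwAnd(1:.H_N, p) > 0L), p)
    cw[p] <- sum(cw[covered]) %% 2L
  }
  cw
}

.decode_plane <- function(bits) {
  syndrome <- Reduce(bitwXor, which(bits == 1L), 0L)
  corrected <- 0L
  if (syndrome > 0L && syndrome <= .H_N) {
    bits[syndrome] <- 1L - bits[syndrome]
    corrected <- syndrome
  }
  list(data = bits[.H_DATA], corrected = corrected)
}

#' Encode 11 nucleotides into a 15-nucleotide Hamming codeword
#'
#' @param data String of 11 bases over A,C,G,T.
#' @return 15-nucleotide codeword string.
#' @examples
#' encode_hamming("AAAAAAAAAAA")  # all-zero codeword "AAAAAAAAAAAAAAA"
#' @export
encode_hamming <- function(data) {
  data <- toupper(data)
  if (nchar(data) != .H_K) stop("data must be 11 nucleotides", call. = FALSE)
  v <- .nt2val(strsplit(data, "", fixed = TRUE)[[1]])
  hi <- .encode_plane(v %/% 2L)
  lo <- .encode_plane(v %% 2L)
  paste(.val2nt(2L * hi + lo), collapse = "")
}

#' Decode a 15-nucleotide Hamming codeword
#'
#' Corrects any single nucleotide substitution (one or two bit flips at one
#' position) by per-plane syndrome decoding. An `N` in the word is replaced
#' by `A` and its position flagged as corrected. Words with two or more
#' substitutions still decode to some codeword; they show up as corrections
#' at multiple positions.
#'
#' @param word 15-nucleotide string over A,C,G,T,N.
#' @return List with `data` (11-nucleotide string) and `corrected`
#'   (sorted integer vector of corrected positions, 1-based; empty when the
#'   word was a valid codeword).
#' @export
decode_hamming <- function(word) {
  word <- toupper(word)
  if (nchar(word) != .H_N) stop("word must be 15 nucleotides", call. = FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n_pos <- which(chars == "N")
  chars[n_pos] <- "A"
  v <- .nt2val(chars)
  hi <- .decode_plane(v %/% 2L)
  lo <- .decode_plane(v %% 2L)
  data_v <- 2L * hi$data + lo$data
  corrected <- sort(unique(c(hi$corrected, lo$corrected, n_pos)))
  corrected <- corrected[corrected > 0L]
  list(data = paste(.val2nt(data_v), collapse = ""), corrected = corrected)
}
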