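# Shared fixtures and independent brute-force oracles.

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_records <- function(n, min_len = 20, max_len = 80) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  data.frame(
    id = sprintf("read%04d some description", seq_len(n)),
    sequence = vapply(lens, rand_dna, character(1)),
    quality = vapply(lens, function(l) {
      paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1]], l,
                   replace = TRUE), collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

# independent IUPAC expansion sets, written out longhand
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# per-position loop oracle for mismatch counting (read-side N matches
# nothing)
oracle_site_mm <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  stopifnot(length(p) == length(w))
  mm <- 0L
  for (i in seq_along(p)) {
    if (!(w[i] %in% IUPAC_SETS[[p[i]]])) mm <- mm + 1L
  }
  mm
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# brute-force sliding-window cut-site scan over both strands
oracle_find_cuts <- function(seq, recognition, cut_offset) {
  k <- nchar(recognition)
  L <- nchar(seq)
  cuts <- integer(0)
  patterns <- list(list(p = recognition, fwd = TRUE))
  rc <- oracle_revcomp(recognition)
  if (!identical(rc, recognition)) {
    patterns <- c(patterns, list(list(p = rc, fwd = FALSE)))
  }
  if (L >= k) {
    for (s in 0:(L - k)) {
      win <- substr(seq, s + 1, s + k)
      for (pt in patterns) {
        if (oracle_site_mm(pt$p, win) == 0L) {
          cuts <- c(cuts, if (pt$fwd) s + cut_offset else s + k - cut_offset)
        }
      }
    }
  }
  sort(unique(cuts))
}

# brute-force single-enzyme digest: cuts -> tiled fragments -> filter
oracle_digest <- function(seq, recognition, cut_offset, min_len, max_len) {
  cuts <- oracle_find_cuts(seq, recognition, cut_offset)
  L <- nchar(seq)
  bounds <- unique(c(0L, cuts, L))
  starts <- utils::head(bounds, -1)
  ends <- bounds[-1]
  interior <- starts %in% cuts & ends %in% cuts
  lens <- ends - starts
  list(cuts = cuts,
       starts = starts, ends = ends,
       selected = data.frame(start = starts, end = ends)[
         interior & lens >= min_len & lens <= max_len, , drop = FALSE])
}

# small in-memory sample sheet + barcode pair for demux tests
fixture_sheet <- function(n = 5, seed = 2) {
  set <- generate_barcodes(n, "ApeKI", seed = seed)
  data.frame(sample = sprintf("S%02d", seq_len(n)),
             barcode = set$barcodes, enzyme = "ApeKI",
             stringsAsFactors = FALSE)
}

ADAPTER <- "AGATCGGAAGAGCG"
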