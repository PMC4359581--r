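# In silico restriction digest: cut-site finding, fragment construction,
# size selection, predicted-sequenced-bases BED and per-enzyme statistics.
# Coordinates are 0-based half-open throughout; a fragment is the interval
# between two consecutive top-strand cut points.

.BOUNDARY <- "chrom_end"

.is_iupac_palindrome <- function(recognition) {
  identical(revcomp_dna(recognition), recognition)
}

#' Find restriction cut sites on one sequence
#'
#' Scans the top strand for IUPAC-aware matches of the recognition sequence
#' (overlapping matches allowed, the reference is taken literally so `N`
#' stretches never match). For non-palindromic recognition sequences the
#' reverse-complement pattern is scanned as well and the two match sets are
#' merged, deduplicated by cut position.
#'
#' @param seq DNA sequence (character scalar) or a one-row data.frame from
#'   [read_fasta()].
#' @param enz A `gbs_enzyme`.
#' @return Sorted integer vector of 0-based top-strand cut positions.
#' @examples
#' apeki <- get_enzyme("ApeKI")
#' find_cut_sites("TTGCAGCTT", apeki)  # 3
#' @export
find_cut_sites <- function(seq, enz) {
  if (is.data.frame(seq)) seq <- seq$sequence[1]
  subject <- Biostrings::DNAString(seq)
  rec <- enz$recognition
  k <- nchar(rec)
  hits <- Biostrings::matchPattern(rec, subject, fixed = "subject")
  cuts <- BiocGenerics::start(hits) - 1L + enz$cut_offset
  if (!.is_iupac_palindrome(rec)) {
    rc <- revcomp_dna(rec)
    hits2 <- Biostrings::matchPattern(rc, subject, fixed = "subject")
    # a match of the reverse-complement pattern means the enzyme sits on the
    # bottom strand; its top-strand cut point lies cut_offset bases from the
    # match *end*
    cuts2 <- BiocGenerics::start(hits2) - 1L + (k - enz$cut_offset)
    cuts <- c(cuts, cuts2)
  }
  sort(unique(as.integer(cuts)))
}

#' Build fragments from merged cut positions
#'
#' Fragments tile the chromosome exactly: `[0,c1), [c1,c2), ..., [ck,L)`.
#' Flanking enzyme labels come from the cuts; chromosome ends are labelled
#' `"chrom_end"`. Zero-length end fragments (cut at 0 or L) are dropped.
#'
#' @param seq_length Chromosome length.
#' @param cuts data.frame with columns `position`, `enzyme` (or an integer
#'   vector, in which case the label `"E1"` is used).
#' @param chrom Chromosome name recorded on the fragments.
#' @return data.frame with columns `chrom`, `start`, `end`, `length`,
#'   `left_enzyme`, `right_enzyme`.
#' @export
fragments_from_cuts <- function(seq_length, cuts, chrom = "chr") {
  if (!is.data.frame(cuts)) {
    cuts <- data.frame(position = as.integer(cuts),
                       enzyme = rep("E1", length(cuts)))
  }
  cuts <- cuts[order(cuts$position), , drop = FALSE]
  if (any(cuts$position < 0L | cuts$position > seq_length)) {
    stop("cut positions out of range", call. = FALSE)
  }
  # collapse duplicate positions (two enzymes cutting at the same point)
  if (anyDuplicated(cuts$position)) {
    lab <- tapply(cuts$enzyme, cuts$position,
                  function(e) paste(sort(unique(e)), collapse = "+"))
    cuts <- data.frame(position = as.integer(names(lab)), enzyme = unname(lab))
    cuts <- cuts[order(cuts$position), , drop = FALSE]
  }
  starts <- c(0L, cuts$position)
  ends <- c(cuts$position, seq_length)
  left <- c(.BOUNDARY, cuts$enzyme)
  right <- c(cuts$enzyme, .BOUNDARY)
  keep <- ends > starts
  data.frame(
    chrom = chrom, start = starts[keep], end = ends[keep],
    length = ends[keep] - starts[keep],
    left_enzyme = left[keep], right_enzyme = right[keep],
    stringsAsFactors = FALSE
  )
}

#' Size-select sequencable fragments
#'
#' Retains interior fragments (both flanks restriction cuts, not chromosome
#' ends) whose length lies in `[min_fragment, max_fragment]`, both bounds
#' inclusive.
#'
#' @param fragments data.frame from [fragments_from_cuts()].
#' @param min_fragment,max_fragment Inclusive fragment-length bounds (bp).
#' @return Filtered data.frame.
#' @export
select_fragments <- function(fragments, min_fragment, max_fragment) {
  stopifnot(min_fragment > 0, min_fragment <= max_fragment)
  interior <- fragments$left_enzyme != .BOUNDARY &
    fragments$right_enzyme != .BOUNDARY
  inrange <- fragments$length >= min_fragment &
    fragments$length <= max_fragment
  fragments[interior & inrange, , drop = FALSE]
}

#' Predicted sequenced intervals of one fragment
#'
#' A sequencable fragment is read from both ends: intervals
#' `[start, start+read_length)` and `[end-read_length, end)`, merged when
#' they overlap. With `include_full_site` the frame is first extended so the
#' complete recognition site of each flanking enzyme is included: the start
#' moves left by the left enzyme's cut offset, the end moves right by
#' (site length - cut offset) of the right enzyme, clamped to the
#' chromosome.
#'
#' @param fragment One-row data.frame (`chrom`, `start`, `end`, plus
#'   `left_enzyme`/`right_enzyme` names when extending).
#' @param read_length Read length (bp).
#' @param include_full_site Extend the fragment frame over the flanking
#'   recognition sites.
#' @param enzymes Enzyme table used to resolve flanking enzymes when
#'   `include_full_site` is `TRUE`.
#' @param chrom_length Chromosome length for clamping (default `Inf`).
#' @return data.frame of 1-2 BED intervals (`chrom`, `start`, `end`, `name`).
#' @export
sequenced_intervals <- function(fragment, read_length,
                                include_full_site = FALSE,
                                enzymes = default_enzymes(),
                                chrom_length = Inf) {
  s <- fragment$start
  e <- fragment$end
  if (include_full_site) {
    le <- get_enzyme(fragment$left_enzyme, enzymes)
    re <- get_enzyme(fragment$right_enzyme, enzymes)
    s <- max(0L, s - le$cut_offset)
    e <- min(chrom_length, e + (nchar(re$recognition) - re$cut_offset))
  }
  name <- if (!is.null(fragment$name)) fragment$name else {
    paste0(fragment$chrom, "_", s)
  }
  if (s + read_length >= e - read_length) {
    out <- data.frame(chrom = fragment$chrom, start = s, end = e, name = name)
  } else {
    out <- data.frame(
      chrom = fragment$chrom,
      start = c(s, e - read_length),
      end = c(s + read_length, e),
      name = paste0(name, c("_fwd", "_rev"))
    )
  }
  out$start <- as.integer(pmax(0, out$start))
  out$end <- as.integer(pmin(chrom_length, out$end))
  out
}

#' In silico digest of a genome
#'
#' Digests every contig of a FASTA file with one or two enzymes, builds
#' fragments from the merged cut positions, size-selects sequencable
#' fragments and reports per-enzyme cut counts, per-flank fragment
#' categories, a fragment-length histogram, the predicted sequenced base
#' count (union of BED intervals) and, with a third enzyme, the number of
#' retained fragments containing at least one third-enzyme site strictly
#' inside the fragment.
#'
#' @param fasta Path to a FASTA file, or a data.frame from [read_fasta()].
#' @param enzyme1 First (required) enzyme: name, inline definition or
#'   `gbs_enzyme`.
#' @param enzyme2,enzyme3 Optional second (co-digest) and third (screening)
#'   enzymes.
#' @param min_fragment,max_fragment Inclusive size-selection bounds (bp).
#' @param read_length Read length used for the sequenced-bases prediction.
#' @param include_full_site Extend sequenced intervals over the flanking
#'   recognition sites.
#' @param bin_width Fragment-length histogram bin width (bp).
#' @param enzymes Enzyme table for name resolution.
#' @param out_dir If non-`NULL`, write `digest.bed` and `digest_report.tsv`
#'   there.
#' @return A list of class `gbs_digest` with elements `report` (named
#'   statistics), `fragments` (all fragments), `selected` (retained
#'   sequencable fragments), `bed` (predicted sequenced intervals) and
#'   `histogram`.
#' @export
digest_genome <- function(fasta, enzyme1, enzyme2 = NULL, enzyme3 = NULL,
                          min_fragment = 60L, max_fragment = 200L,
                          read_length = 100L, include_full_site = FALSE,
                          bin_width = 10L, enzymes = default_enzymes(),
                          out_dir = NULL) {
  genome <- if (is.data.frame(fasta)) fasta else read_fasta(fasta)
  if (nrow(genome) == 0L) stop("empty FASTA input", call. = FALSE)
  e1 <- get_enzyme(enzyme1, enzymes)
  e2 <- if (!is.null(enzyme2)) get_enzyme(enzyme2, enzymes)
  e3 <- if (!is.null(enzyme3)) get_enzyme(enzyme3, enzymes)

  all_frags <- list()
  bed <- list()
  cut_counts <- c(stats::setNames(0L, e1$name),
                  if (!is.null(e2)) stats::setNames(0L, e2$name))
  third_count <- 0L
  table_local <- enzymes
  table_local[[tolower(e1$name)]] <- e1
  if (!is.null(e2)) table_local[[tolower(e2$name)]] <- e2

  for (i in seq_len(nrow(genome))) {
    chrom <- genome$id[i]
    s <- genome$sequence[i]
    L <- nchar(s)
    c1 <- find_cut_sites(s, e1)
    cut_counts[e1$name] <- cut_counts[e1$name] + length(c1)
    cuts <- data.frame(position = c1, enzyme = rep(e1$name, length(c1)))
    if (!is.null(e2)) {
      c2 <- find_cut_sites(s, e2)
      cut_counts[e2$name] <- cut_counts[e2$name] + length(c2)
      cuts <- rbind(cuts,
                    data.frame(position = c2, enzyme = rep(e2$name, length(c2))))
    }
    frags <- fragments_from_cuts(L, cuts, chrom = chrom)
    all_frags[[i]] <- frags
    sel <- select_fragments(frags, min_fragment, max_fragment)
    if (nrow(sel) > 0L) {
      sel$name <- sprintf("%s_frag%06d", chrom, seq_len(nrow(sel)))
      for (j in seq_len(nrow(sel))) {
        bed[[length(bed) + 1L]] <- sequenced_intervals(
          sel[j, , drop = FALSE], read_length,
          include_full_site = include_full_site,
          enzymes = table_local, chrom_length = L
        )
      }
      if (!is.null(e3)) {
        seqs <- substring(s, sel$start + 1L, sel$end)
        nhit <- Biostrings::vcountPattern(
          e3$recognition, Biostrings::DNAStringSet(seqs), fixed = "subject"
        )
        if (!.is_iupac_palindrome(e3$recognition)) {
          nhit <- nhit + Biostrings::vcountPattern(
            revcomp_dna(e3$recognition), Biostrings::DNAStringSet(seqs),
            fixed = "subject"
          )
        }
        third_count <- third_count + sum(nhit > 0L)
      }
    }
  }

  fragments <- do.call(rbind, all_frags)
  selected <- select_fragments(fragments, min_fragment, max_fragment)
  bed <- if (length(bed)) do.call(rbind, bed) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))

  interior <- fragments[fragments$left_enzyme != .BOUNDARY &
                          fragments$right_enzyme != .BOUNDARY, , drop = FALSE]
  category <- function(fr) {
    if (is.null(e2)) return(stats::setNames(nrow(fr), paste0(e1$name, "-", e1$name)))
    lab <- paste(pmin(fr$left_enzyme, fr$right_enzyme),
                 pmax(fr$left_enzyme, fr$right_enzyme), sep = "-")
    tab <- table(lab)
    stats::setNames(as.integer(tab), names(tab))
  }
  n_boundary <- nrow(fragments) - nrow(interior)

  # predicted sequenced bases = union of BED intervals
  seq_bases <- 0L
  if (nrow(bed) > 0L) {
    for (ch in unique(bed$chrom)) {
      b <- bed[bed$chrom == ch, , drop = FALSE]
      red <- IRanges::reduce(IRanges::IRanges(start = b$start + 1L, end = b$end))
      seq_bases <- seq_bases + sum(IRanges::width(red))
    }
  }

  hist_breaks <- seq(0L, max(c(interior$length, bin_width)) + bin_width,
                     by = bin_width)
  histogram <- if (nrow(interior)) {
    h <- graphics::hist(interior$length, breaks = hist_breaks, plot = FALSE)
    data.frame(bin_start = utils::head(h$breaks, -1), count = h$counts)
  } else {
    data.frame(bin_start = integer(0), count = integer(0))
  }
  histogram <- histogram[histogram$count > 0, , drop = FALSE]

  report <- list(
    enzymes = c(e1$name, if (!is.null(e2)) e2$name),
    cut_counts = cut_counts,
    n_fragments = nrow(fragments),
    n_interior = nrow(interior),
    n_boundary = n_boundary,
    category_counts = c(category(interior), chrom_end = n_boundary),
    n_selected = nrow(selected),
    min_fragment = min_fragment, max_fragment = max_fragment,
    read_length = read_length,
    predicted_sequenced_bases = seq_bases,
    third_enzyme = if (!is.null(e3)) e3$name,
    n_selected_with_third_site = if (!is.null(e3)) third_count
  )

  res <- structure(
    list(report = report, fragments = fragments, selected = selected,
         bed = bed, histogram = histogram),
    class = "gbs_digest"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(bed, file.path(out_dir, "digest.bed"))
    write_digest_report(res, file.path(out_dir, "digest_report.tsv"))
  }
  res
}

#' Write a digest report as labelled tab-delimited text
#'
#' @param digest A `gbs_digest` object from [digest_genome()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_digest_report <- function(digest, path) {
  r <- digest$report
  lines <- c(
    paste0("enzymes\t", paste(r$enzymes, collapse = ",")),
    paste0("cut_count_", names(r$cut_counts), "\t", r$cut_counts),
    paste0("fragments_total\t", r$n_fragments),
    paste0("fragments_interior\t", r$n_interior),
    paste0("fragments_chrom_end\t", r$n_boundary),
    paste0("fragments_", names(r$category_counts), "\t", r$category_counts),
    paste0("size_range\t", r$min_fragment, "-", r$max_fragment),
    paste0("fragments_selected\t", r$n_selected),
    paste0("read_length\t", r$read_length),
    paste0("predicted_sequenced_bases\t", r$predicted_sequenced_bases)
  )
  if (!is.null(r$third_enzyme)) {
    lines <- c(lines,
               paste0("third_enzyme\t", r$third_enzyme),
               paste0("selected_with_third_site\t",
                      r$n_selected_with_third_site))
  }
  lines <- c(lines, "", "length_bin_start\tcount",
             paste0(digest$histogram$bin_start, "\t", digest$histogram$count))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gbs_digest <- function(x, ...) {
  r <- x$report
  cat("<in silico digest>\n")
  cat("  enzymes:", paste(r$enzymes, collapse = " + "), "\n")
  cat("  cuts:", paste(names(r$cut_counts), r$cut_counts, collapse = ", "), "\n")
  cat("  fragments:", r$n_fragments, "(", r$n_interior, "interior )\n")
  cat("  selected", paste0("[", r$min_fragment, "-", r$max_fragment, "bp]:"),
      r$n_selected, "\n")
  cat("  predicted sequenced bases:", r$predicted_sequenced_bases, "\n")
  invisible(x)
}
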