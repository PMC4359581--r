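#' Restriction enzyme definition
#'
#' An enzyme is a named recognition sequence over the IUPAC alphabet plus a
#' cut offset: the number of bases 5' of the top-strand cut point inside the
#' recognition sequence. In annotation files and inline definitions the cut
#' position is written with a caret, e.g. `G^CWGC` for ApeKI (cut offset 1).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence; may contain one `^` marking the
#'   cut position. Degenerate IUPAC codes are allowed.
#' @param cut_offset Cut offset in `[0, nchar(recognition)]`; ignored when
#'   `recognition` carries a caret.
#' @param remnant Optional alternative sequence used instead of the full
#'   recognition sequence when matching real ligation products (the
#'   post-cut remnant); `NULL` means the full site is used.
#' @return An object of class `gbs_enzyme`.
#' @examples
#' enzyme("ApeKI", "G^CWGC")
#' @export
enzyme <- function(name, recognition, cut_offset = NULL, remnant = NULL) {
  recognition <- toupper(recognition)
  caret <- gregexpr("^", recognition, fixed = TRUE)[[1]]
  if (caret[1] != -1L) {
    if (length(caret) > 1L) {
      stop("recognition sequence has more than one '^': ", recognition,
           call. = FALSE)
    }
    cut_offset <- as.integer(caret[1]) - 1L
    recognition <- sub("^", "", recognition, fixed = TRUE)
  }
  if (is.null(cut_offset)) cut_offset <- 0L
  cut_offset <- as.integer(cut_offset)
  if (!nzchar(recognition) || !.is_iupac(recognition)) {
    stop("invalid recognition sequence for enzyme ", name, ": ", recognition,
         call. = FALSE)
  }
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut offset out of bounds for enzyme ", name, call. = FALSE)
  }
  if (!is.null(remnant)) {
    remnant <- toupper(remnant)
    if (!.is_iupac(remnant)) {
      stop("invalid remnant sequence for enzyme ", name, call. = FALSE)
    }
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset,
         remnant = remnant),
    class = "gbs_enzyme"
  )
}

#' @export
print.gbs_enzyme <- function(x, ...) {
  rec <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                substr(x$recognition, x$cut_offset + 1L, nchar(x$recognition)))
  cat("<enzyme>", x$name, rec,
      if (!is.null(x$remnant)) paste0("(remnant ", x$remnant, ")"), "\n")
  invisible(x)
}

#' Built-in enzyme annotation table
#'
#' Parses the annotation file shipped with the package (a standard set of
#' GBS/RAD enzymes). Entries can be overridden or extended with
#' [parse_enzyme_file()].
#'
#' @return Named list of `gbs_enzyme` objects (an enzyme table).
#' @export
default_enzymes <- function() {
  path <- system.file("extdata", "enzymes.tsv", package = "gbskit",
                      mustWork = TRUE)
  parse_enzyme_file(path, base_table = list())
}

#' Parse an enzyme annotation file
#'
#' Tab-delimited lines `name<TAB>recognition[<TAB>remnant]`; the recognition
#' sequence may carry one caret marking the cut position (absent caret means
#' cut offset 0). Lines starting with `#` and blank lines are ignored. File
#' entries override/extend `base_table`.
#'
#' @param path Path to the annotation file.
#' @param base_table Enzyme table to extend; defaults to the built-ins.
#' @return Named list of `gbs_enzyme` objects.
#' @export
parse_enzyme_file <- function(path, base_table = default_enzymes()) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  table <- base_table
  seen <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop("enzyme file line ", i, " is not tab-delimited name/recognition: ",
           lines[i], call. = FALSE)
    }
    nm <- trimws(fields[1])
    if (tolower(nm) %in% tolower(seen)) {
      stop("duplicate enzyme name at line ", i, ": ", nm, call. = FALSE)
    }
    seen <- c(seen, nm)
    rem <- if (length(fields) >= 3L && nzchar(trimws(fields[3]))) {
      trimws(fields[3])
    }
    e <- tryCatch(
      enzyme(nm, trimws(fields[2]), remnant = rem),
      error = function(err) {
        stop("enzyme file line ", i, ": ", conditionMessage(err),
             call. = FALSE)
      }
    )
    table[[tolower(nm)]] <- e
  }
  table
}

#' Look up an enzyme by name (case-insensitive)
#'
#' Also accepts inline definitions of the form `NAME:RECOGNITION` where the
#' recognition sequence may carry a caret, e.g. `"MyEnz:GG^CC"`.
#'
#' @param name Enzyme name or inline definition.
#' @param table Enzyme table (default: built-ins).
#' @return A `gbs_enzyme` object.
#' @export
get_enzyme <- function(name, table = default_enzymes()) {
  if (inherits(name, "gbs_enzyme")) return(name)
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    return(enzyme(parts[1], parts[2]))
  }
  e <- table[[tolower(name)]]
  if (is.null(e)) stop("unknown enzyme: ", name, call. = FALSE)
  e
}

# The sequence the demultiplexer/simulator actually matches at read starts:
# full recognition site by default (matching the simulator's fragments).
.enzyme_probe <- function(e, use_remnant = FALSE) {
  if (use_remnant && !is.null(e$remnant)) e$remnant else e$recognition
}
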