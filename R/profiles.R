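#' Construct a binding profile
#'
#' A binding profile is the list of genomic locations bound (directly or
#' indirectly) by one DNA-associated factor (DAF), e.g. the peak calls of a
#' ChIP-chip or DamID experiment.  Coordinates follow the BED convention:
#' 0-based, half-open `[start, end)`.
#'
#' Duplicate coordinates are permitted; each interval is treated as an
#' independent location.  Strand is ignored throughout.
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`.
#' @param factor single character name of the factor.
#' @return An object of class `binding_profile`: a list with elements
#'   `factor` and `intervals`.
#' @examples
#' binding_profile(data.frame(contig = "chr2L",
#'                            start = c(100L, 300L), end = c(200L, 400L)),
#'                 factor = "Pc")
#' @export
binding_profile <- function(intervals, factor) {
  if (!is.character(factor) || length(factor) != 1L || is.na(factor) ||
      !nzchar(factor))
    stop("'factor' must be a single non-empty character string")
  if (!is.data.frame(intervals) ||
      !all(c("contig", "start", "end") %in% names(intervals)))
    stop("'intervals' must be a data.frame with columns contig, start, end")
  intervals <- data.frame(contig = as.character(intervals$contig),
                          start = as.integer(intervals$start),
                          end = as.integer(intervals$end),
                          stringsAsFactors = FALSE)
  if (nrow(intervals)) {
    if (anyNA(intervals$start) || anyNA(intervals$end))
      stop("interval coordinates must be integers")
    if (any(intervals$start < 0L))
      stop("interval coordinates must be non-negative")
    if (any(intervals$start >= intervals$end))
      stop("intervals must satisfy start < end")
  }
  structure(list(factor = factor, intervals = intervals),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("Binding profile:", x$factor, "--", nrow(x$intervals), "locations on",
      length(unique(x$intervals$contig)), "contig(s)\n")
  invisible(x)
}

#' Number of locations in a binding profile
#'
#' @param x a `binding_profile`.
#' @return Integer count of intervals (the `n` of the tested factor).
#' @export
profile_size <- function(x) {
  stopifnot(inherits(x, "binding_profile"))
  nrow(x$intervals)
}

parse_bed_lines <- function(lines, path) {
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop(sprintf("%s: line %d: expected at least 3 columns, got %d",
                 path, lineno[which(ncol < 3L)[1L]], min(ncol)))
  contig <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop(sprintf("%s: line %d: malformed interval '%s'",
                 path, lineno[bad[1L]],
                 trimws(lines[keep][bad[1L]])))
  name <- if (all(ncol >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  data.frame(contig = contig, start = start, end = end,
             name = if (is.null(name)) NA_character_ else name,
             stringsAsFactors = FALSE)
}

#' Read a binding profile from a BED file
#'
#' Reads a BED3+ file (whitespace- or tab-separated; `track`, `browser` and
#' `#` comment lines are skipped).  Columns beyond the third are ignored.
#' Malformed lines (fewer than 3 columns, non-integer coordinates,
#' `start >= end`) raise an error naming the offending line.
#'
#' @param path path to the BED file.
#' @param factor factor name; defaults to the filename without its extension.
#' @return A [binding_profile()].
#' @export
read_bed <- function(path, factor = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(factor))
    factor <- sub("\\.[^.]*$", "", basename(path))
  tab <- parse_bed_lines(readLines(path), path)
  binding_profile(tab[c("contig", "start", "end")], factor)
}

#' Read several binding profiles at once
#'
#' Accepts either a directory (every `*.bed` file becomes one profile named
#' after its filename) or a single multi-factor BED file whose fourth
#' column carries the factor name.
#'
#' @param path directory of `.bed` files, or a BED file with factor names
#'   in column 4.
#' @return Named list of [binding_profile()] objects, sorted by factor name.
#' @export
read_profiles <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.bed$", full.names = TRUE))
    if (!length(files)) stop("no .bed files found in ", path)
    profs <- lapply(files, read_bed)
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    tab <- parse_bed_lines(readLines(path), path)
    if (anyNA(tab$name))
      stop(path, ": multi-factor input requires a 4th column of factor names")
    profs <- lapply(split(tab, tab$name), function(d)
      binding_profile(d[c("contig", "start", "end")], d$name[1L]))
  }
  names(profs) <- vapply(profs, `[[`, "", "factor")
  if (anyDuplicated(names(profs)))
    stop("duplicate factor names: ",
         paste(unique(names(profs)[duplicated(names(profs))]), collapse = ", "))
  profs[order(names(profs))]
}
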