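#' Do two genomic intervals overlap?
#'
#' Intervals are 0-based half-open.  Overlap requires the same contig and at
#' least one shared base, so abutting intervals (`end == start`) do not
#' overlap.
#'
#' @param a,b lists (or 1-row data.frames) with elements `contig`, `start`,
#'   `end`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' interval_overlap(list(contig = "chr1", start = 0, end = 100),
#'                  list(contig = "chr1", start = 99, end = 150))   # TRUE
#' interval_overlap(list(contig = "chr1", start = 0, end = 100),
#'                  list(contig = "chr1", start = 100, end = 150))  # FALSE
#' @export
interval_overlap <- function(a, b) {
  as.character(a$contig) == as.character(b$contig) &&
    max(a$start, b$start) < min(a$end, b$end)
}

#' Build the co-occurrence matrix of a set of binding profiles
#'
#' All profiles are concatenated into a joint pool of location records (a
#' location bound by k factors appears as k records).  For every unordered
#' pair of records on the same contig whose intervals share at least one
#' base, a weight is stored: 1 under the `binary` policy, or the number of
#' shared bases under the `bases` policy.  The diagonal weight of a record
#' is its self-overlap score (1, or its length in bases).  The matrix is
#' symmetric and sparse: absent entries are zero, and records on different
#' contigs never receive a weight.
#'
#' Overlap detection runs one contig at a time (via interval trees from the
#' IRanges package); the result is identical to a whole-genome all-pairs
#' scan because cross-contig pairs can never overlap.
#'
#' @param profiles a `binding_profile` or list of them.
#' @param policy `"binary"` (count overlapping pairs) or `"bases"` (weight
#'   each pair by the number of bases shared).
#' @return An object of class `cooccur_matrix`: a list with the pool size
#'   `n`, parallel edge vectors `ei`, `ej`, `w` (unordered pairs, `ei < ej`),
#'   diagonal weights `diag`, per-record `origin`, `contig`, `start`, `end`,
#'   the `policy`, and `sizes` (records per factor).
#' @seealso [cooccur_statistic()], [observed_statistic()], [partition_pool()]
#' @export
build_cooccurrence <- function(profiles, policy = c("binary", "bases")) {
  policy <- match.arg(policy)
  if (inherits(profiles, "binding_profile")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, inherits, TRUE,
                                       "binding_profile")))
    stop("'profiles' must be one or more binding_profile objects")
  fnames <- vapply(profiles, `[[`, "", "factor")
  if (anyDuplicated(fnames))
    stop("duplicate factor names: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "))
  origin <- rep(fnames, vapply(profiles, profile_size, 0L))
  iv <- do.call(rbind, lapply(profiles, `[[`, "intervals"))
  n <- length(origin)
  ei <- ej <- w <- integer(0)
  if (n) {
    rownames(iv) <- NULL
    by_contig <- split(seq_len(n), iv$contig)
    pieces <- lapply(by_contig, function(idx) {
      # BED half-open -> 1-based closed; abutting intervals then disjoint
      ir <- IRanges::IRanges(start = iv$start[idx] + 1L, end = iv$end[idx])
      hits <- IRanges::findOverlaps(ir, drop.self = TRUE,
                                    drop.redundant = TRUE)
      q <- idx[S4Vectors::queryHits(hits)]
      s <- idx[S4Vectors::subjectHits(hits)]
      wt <- if (policy == "bases")
        pmin(iv$end[q], iv$end[s]) - pmax(iv$start[q], iv$start[s])
      else rep(1L, length(q))
      cbind(i = pmin(q, s), j = pmax(q, s), w = wt)
    })
    edges <- do.call(rbind, pieces)
    if (length(edges)) {
      ord <- order(edges[, "i"], edges[, "j"])
      ei <- unname(edges[ord, "i"])
      ej <- unname(edges[ord, "j"])
      w <- unname(edges[ord, "w"])
    }
  }
  dg <- if (policy == "bases") iv$end - iv$start else rep(1L, n)
  structure(list(n = n, ei = ei, ej = ej, w = w, diag = dg,
                 origin = origin, contig = iv$contig,
                 start = iv$start, end = iv$end, policy = policy,
                 sizes = table(factor(origin, levels = fnames))),
            class = "cooccur_matrix")
}

#' @export
print.cooccur_matrix <- function(x, ...) {
  cat("Co-occurrence matrix (", x$policy, " policy)\n", sep = "")
  cat("  joint pool:", x$n, "records from",
      length(x$sizes), "factor(s) on",
      length(unique(x$contig)), "contig(s)\n")
  cat("  stored off-diagonal weights:", length(x$w), "\n")
  invisible(x)
}

#' @describeIn build_cooccurrence dense matrix form (small pools only);
#'   rows/columns are joint-pool records in input order.
#' @param x a `cooccur_matrix`.
#' @param ... unused.
#' @export
as.matrix.cooccur_matrix <- function(x, ...) {
  m <- diag(as.numeric(x$diag), nrow = x$n)
  if (length(x$w)) {
    m[cbind(x$ei, x$ej)] <- x$w
    m[cbind(x$ej, x$ei)] <- x$w
  }
  dimnames(m) <- list(x$origin, x$origin)
  m
}

#' Restrict a co-occurrence matrix to a subset of factors
#'
#' Keeps the records originating from the named factors, re-indexing the
#' joint pool densely.  Used internally by the pair-pool tests (permutation,
#' independent, hybrid), whose joint pool is built from the two tested
#' profiles only.
#'
#' @param cm a `cooccur_matrix`.
#' @param factors character vector of factor names to keep.
#' @return A `cooccur_matrix` over the retained records.
#' @export
subset_cooccurrence <- function(cm, factors) {
  stopifnot(inherits(cm, "cooccur_matrix"))
  missing <- setdiff(factors, names(cm$sizes))
  if (length(missing))
    stop("unknown factor(s): ", paste(missing, collapse = ", "))
  keep <- which(cm$origin %in% factors)
  map <- integer(cm$n)
  map[keep] <- seq_along(keep)
  ke <- cm$ei %in% keep & cm$ej %in% keep
  structure(list(n = length(keep),
                 ei = map[cm$ei[ke]], ej = map[cm$ej[ke]], w = cm$w[ke],
                 diag = cm$diag[keep], origin = cm$origin[keep],
                 contig = cm$contig[keep], start = cm$start[keep],
                 end = cm$end[keep], policy = cm$policy,
                 sizes = table(factor(cm$origin[keep],
                                      levels = intersect(names(cm$sizes),
                                                         factors)))),
            class = "cooccur_matrix")
}
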