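#' Screen all factor pairs for significant co-occurrence
#'
#' Evaluates every unordered pair of factors (k factors give `k(k-1)/2`
#' pairs) with the requested resampling methods, using the two-stage
#' survey-then-full optimisation: a short survey run discards pairs whose
#' estimated p-value exceeds `survey_cutoff` before the full run is spent.
#' Per-pair seeds are derived deterministically from `seed`, so a screen is
#' reproducible, and the pair-pool methods (permutation, independent,
#' hybrid) depend only on the two profiles of each pair — adding or
#' removing other factors can change only the pooled (`fl`) p-values.
#'
#' @param profiles named list of [binding_profile()] objects (>= 2).
#' @param methods subset of `c("hybrid", "fl", "permutation",
#'   "independent")`.
#' @param iterations full-run resamples per pair and method.
#' @param survey_iterations survey-run resamples (0 disables the survey).
#' @param survey_cutoff survey p-value cut-off.
#' @param alpha significance threshold for the `significant` column.
#' @param seed integer seed for the whole screen.
#' @param policy scoring policy, see [build_cooccurrence()].
#' @return A data.frame of class `cooccur_screen`, one row per pair,
#'   sorted by factor names: per-factor overlapped/total location counts
#'   (a location counts as overlapped if it has at least one cross-factor
#'   overlap with the partner), one `p_*` and `iter_*` column per method,
#'   a tiered `flag` column (`***` < 0.001, `*` < 0.05, `.` < 0.1,
#'   computed from the smallest method p-value) and a logical
#'   `significant` column at `alpha`.
#' @examples
#' profs <- make_fl_scenario(10, replicates = 1)
#' screen_pairs(profs, methods = "hybrid", iterations = 200, seed = 1)
#' @export
screen_pairs <- function(profiles,
                         methods = c("hybrid", "fl"),
                         iterations = 5000, survey_iterations = 100,
                         survey_cutoff = 0.1, alpha = 0.05, seed = NULL,
                         policy = c("binary", "bases")) {
  methods <- match.arg(methods, c("hybrid", "fl", "permutation",
                                  "independent"), several.ok = TRUE)
  policy <- match.arg(policy)
  stopifnot(length(profiles) >= 2L)
  fnames <- vapply(profiles, `[[`, "", "factor")
  if (anyDuplicated(fnames))
    stop("duplicate factor names: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "))
  names(profiles) <- fnames
  cm <- build_cooccurrence(profiles, policy)
  pairs <- utils::combn(sort(fnames), 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    pair_cm <- subset_cooccurrence(cm, c(a, b))
    pp <- partition_pool(pair_cm, a, b)
    ov_origin <- pair_cm$origin[pp$overlapped]
    row <- data.frame(factor1 = a, factor2 = b,
                      overlapped1 = sum(ov_origin == a),
                      total1 = sum(pair_cm$origin == a),
                      overlapped2 = sum(ov_origin == b),
                      total2 = sum(pair_cm$origin == b),
                      stringsAsFactors = FALSE)
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      # seed derived from the pair's names, not its index, so that the
      # pair-pool tests are unaffected by other factors in the dataset
      pair_seed <- if (is.null(seed)) NULL else
        (seed + 7919L * (sum(utf8ToInt(a)) * 31L + sum(utf8ToInt(b))) +
           1009L * mi) %% .Machine$integer.max
      res <- cooccur_test(if (m == "fl") cm else pair_cm, a, b, method = m,
                          iterations = iterations, seed = pair_seed,
                          survey_iterations = survey_iterations,
                          survey_cutoff = survey_cutoff)
      row[[paste0("p_", m)]] <- res$p_value
      row[[paste0("iter_", m)]] <- res$iterations
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  pmin_row <- do.call(pmin, out[paste0("p_", methods)])
  out$flag <- cut(pmin_row, c(-Inf, 0.001, 0.05, 0.1, Inf),
                  labels = c("***", "*", ".", ""), right = FALSE)
  out$flag <- as.character(out$flag)
  out$significant <- pmin_row < alpha
  attr(out, "methods") <- methods
  attr(out, "alpha") <- alpha
  class(out) <- c("cooccur_screen", "data.frame")
  out
}

fmt_frac <- function(overlapped, total) {
  pct <- ifelse(total > 0, 100 * overlapped / total, 0)
  sprintf("%d/%d (%.3g%%)", overlapped, total, pct)
}

#' Write a screening report as a tab-separated table
#'
#' One row per factor pair with per-factor overlap fractions rendered as
#' `"overlapped/total (percent%)"` and one p-value column per method.
#' P-value estimates with zero exceedances are rendered as a bound,
#' e.g. `"< 2e-04"` for 5000 iterations.
#'
#' @param screen a `cooccur_screen` from [screen_pairs()].
#' @param path output file path, or `""` for standard output.
#' @return Invisibly, the character version of the table that was written.
#' @export
write_report <- function(screen, path = "") {
  stopifnot(inherits(screen, "cooccur_screen"))
  methods <- attr(screen, "methods")
  out <- data.frame(factor1 = screen$factor1, factor2 = screen$factor2,
                    overlap1 = fmt_frac(screen$overlapped1, screen$total1),
                    overlap2 = fmt_frac(screen$overlapped2, screen$total2),
                    stringsAsFactors = FALSE)
  for (m in methods)
    out[[paste0("p_", m)]] <- format_pvalue(screen[[paste0("p_", m)]],
                                            screen[[paste0("iter_", m)]])
  out$flag <- screen$flag
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' @export
print.cooccur_screen <- function(x, ...) {
  cat("All-pairs co-occurrence screen:", nrow(x), "pairs, methods:",
      paste(attr(x, "methods"), collapse = ", "), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
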