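# Run expr with a locally seeded RNG, restoring the caller's stream after.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

mc_result <- function(method, factors, observed, exceed, iterations, seed,
                      n_pool, n_a, n_b, screened = FALSE, null_sample = NULL) {
  structure(list(method = method, factors = factors, observed = observed,
                 iterations = iterations, exceed = exceed,
                 p_value = exceed / iterations, seed = seed,
                 n_pool = n_pool, n_a = n_a, n_b = n_b,
                 screened = screened, null_sample = null_sample),
            class = "cooccur_test")
}

# Each engine returns function() -> one null statistic score.
draw_permutation <- function(cm, n_a) {
  n <- cm$n
  ei <- cm$ei; ej <- cm$ej; w <- cm$w
  function() {
    inA <- logical(n)
    inA[sample.int(n, n_a)] <- TRUE
    # setB is the complement: an edge scores iff its ends are split
    if (length(w)) sum(w * (inA[ei] != inA[ej])) else 0
  }
}

draw_independent <- function(cm, n_a, n_b) {
  n <- cm$n
  function() {
    inA <- inB <- logical(n)
    inA[sample.int(n, n_a)] <- TRUE
    inB[sample.int(n, n_b)] <- TRUE
    score_assignment(cm, inA, inB)
  }
}

draw_hybrid <- function(cm, n_a, n_b, pools) {
  n <- cm$n
  ov <- pools$overlapped
  sg <- pools$singleton
  function() {
    inA <- inB <- logical(n)
    inA[sample.int(n, n_a)] <- TRUE
    avail <- c(ov[!inA[ov]], sg)
    if (n_b > length(avail))
      stop("hybrid draw infeasible: need ", n_b, " locations for B but only ",
           length(avail), " are assignable")
    inB[avail[sample.int(length(avail), n_b)]] <- TRUE
    score_assignment(cm, inA, inB)
  }
}

draw_fl <- function(cm, n_a, n_b) {
  n <- cm$n
  if (n_a + n_b > n)
    stop("FL pool smaller than the two profiles combined")
  function() {
    inA <- inB <- logical(n)
    inA[sample.int(n, n_a)] <- TRUE
    rest <- which(!inA)
    # with a two-factor dataset B takes the whole remainder: exactly the
    # permutation test, draw for draw
    if (n_b == n - n_a) inB[rest] <- TRUE
    else inB[rest[sample.int(n - n_a, n_b)]] <- TRUE
    score_assignment(cm, inA, inB)
  }
}

run_engine <- function(draw, observed, iterations, keep_null) {
  exceed <- 0L
  null_sample <- if (keep_null) numeric(iterations)
  for (it in seq_len(iterations)) {
    s <- draw()
    if (s >= observed) exceed <- exceed + 1L
    if (keep_null) null_sample[it] <- s
  }
  list(exceed = exceed, null_sample = null_sample)
}

#' Resampling test for binding-site co-occurrence of two factors
#'
#' Estimates the p-value of the observed co-occurrence statistic of factors
#' `a` and `b` against one of four resampled null distributions:
#'
#' * `"permutation"` — the joint pool of the two profiles is split
#'   exhaustively: `n_a` records are drawn without replacement for A and
#'   the remainder assigned to B.  No record is left out or dually
#'   assigned.
#' * `"independent"` — A and B are redrawn as two independent
#'   without-replacement samples from the joint pool; the same record may
#'   be assigned to both factors.
#' * `"hybrid"` — the pool is partitioned by [partition_pool()]:
#'   heterogeneously overlapped records may be assigned to at most one
#'   factor, singletons to either or both.  A is drawn first from the whole
#'   pool; B is then drawn from the unassigned overlapped records plus all
#'   singletons.  With no singletons this reduces to the permutation test;
#'   with no overlapped records to two independent draws
#'   (see [hybrid_limit_pmf()]).
#' * `"fl"` — the pooled multi-factor scheme: the null pool holds the
#'   records of *every* factor in `x`; `n_a` records are drawn for A, then
#'   `n_b` from the remainder for B, and scored against the whole-dataset
#'   matrix.  With a two-factor dataset this is identical to the
#'   permutation test.
#'
#' The estimate is `p = exceed / iterations` with ties counted as
#' exceedances (`null >= observed`).  When no resample reaches the observed
#' value the printed result is reported as `< 1/iterations`.
#'
#' An optional two-stage survey mode reproduces the screening runtime
#' optimisation: a short survey run of `survey_iterations` resamples is
#' evaluated first and, if its p-value estimate exceeds `survey_cutoff`,
#' returned immediately with `screened = TRUE`; otherwise a fresh full run
#' of `iterations` resamples is performed.
#'
#' @param x a list of [binding_profile()] objects or a prebuilt
#'   `cooccur_matrix`.  For the pair-pool methods only the records of `a`
#'   and `b` are used; for `"fl"` all factors in `x` form the null pool.
#' @param a,b names of the two tested factors.
#' @param method resampling scheme, see Details.
#' @param iterations number of Monte-Carlo resamples.
#' @param seed integer seed; identical seed and arguments give a
#'   bit-identical result.  The caller's RNG stream is left untouched.
#' @param policy scoring policy passed to [build_cooccurrence()] when `x`
#'   is a list of profiles.
#' @param survey_iterations if > 0, run the two-stage survey with this many
#'   screening resamples (0 disables).
#' @param survey_cutoff survey-stage p-value cut-off above which the pair
#'   is screened out.
#' @param keep_null retain the resampled null scores in the result.
#' @return Object of class `cooccur_test` with elements `method`,
#'   `factors`, `observed`, `iterations`, `exceed`, `p_value`, `seed`,
#'   `n_pool`, `n_a`, `n_b`, `screened` and (optionally) `null_sample`.
#' @examples
#' pair <- make_simple_model(m = 10)
#' cooccur_test(pair, "A", "B", method = "hybrid",
#'              iterations = 2000, seed = 1)
#' @export
cooccur_test <- function(x, a, b,
                         method = c("hybrid", "permutation",
                                    "independent", "fl"),
                         iterations = 5000, seed = NULL,
                         policy = c("binary", "bases"),
                         survey_iterations = 0, survey_cutoff = 0.1,
                         keep_null = FALSE) {
  method <- match.arg(method)
  policy <- match.arg(policy)
  stopifnot(iterations >= 1, survey_iterations >= 0,
            survey_cutoff > 0, survey_cutoff <= 1)
  cm <- if (inherits(x, "cooccur_matrix")) x
        else build_cooccurrence(x, policy)
  for (f in c(a, b))
    if (!f %in% names(cm$sizes)) stop("unknown factor: ", f)
  if (a == b) stop("the two tested factors must differ")
  if (method != "fl" && !setequal(names(cm$sizes), c(a, b)))
    cm <- subset_cooccurrence(cm, c(a, b))
  n_a <- sum(cm$origin == a)
  n_b <- sum(cm$origin == b)
  if (method != "fl" && n_a + n_b == 0L)
    stop("empty joint pool: neither factor has any location")
  observed <- observed_statistic(cm, a, b)
  draw <- switch(method,
    permutation = draw_permutation(cm, n_a),
    independent = draw_independent(cm, n_a, n_b),
    hybrid = draw_hybrid(cm, n_a, n_b, partition_pool(cm, a, b)),
    fl = draw_fl(cm, n_a, n_b))
  with_local_seed(seed, {
    if (survey_iterations > 0) {
      sv <- run_engine(draw, observed, survey_iterations, keep_null)
      if (sv$exceed / survey_iterations > survey_cutoff)
        return(mc_result(method, c(a, b), observed, sv$exceed,
                         survey_iterations, seed, cm$n, n_a, n_b,
                         screened = TRUE, null_sample = sv$null_sample))
    }
    full <- run_engine(draw, observed, iterations, keep_null)
    mc_result(method, c(a, b), observed, full$exceed, iterations, seed,
              cm$n, n_a, n_b, null_sample = full$null_sample)
  })
}

#' Format a Monte-Carlo p-value estimate
#'
#' Zero exceedances are reported as a bound, e.g. `"< 2e-04"` at 5000
#' iterations, since the estimate is then only resolved to the Monte-Carlo
#' floor `1/iterations`.
#'
#' @param p numeric p-value estimate(s).
#' @param iterations iteration count(s) behind the estimate.
#' @return Character vector.
#' @export
format_pvalue <- function(p, iterations) {
  ifelse(p == 0, paste0("< ", format(1 / iterations)),
         format(signif(p, 3)))
}

#' @export
print.cooccur_test <- function(x, ...) {
  cat("\n\tCo-occurrence resampling test (", x$method, ")\n\n", sep = "")
  cat("factors: ", x$factors[1L], " vs ", x$factors[2L],
      "  (n_A = ", x$n_a, ", n_B = ", x$n_b,
      ", pool = ", x$n_pool, ")\n", sep = "")
  cat("observed statistic = ", x$observed, "\n", sep = "")
  cat("p-value = ", format_pvalue(x$p_value, x$iterations),
      "  (", x$exceed, " of ", x$iterations, " resamples >= observed)\n",
      sep = "")
  if (x$screened)
    cat("screened out at the survey stage\n")
  invisible(x)
}

#' Merge independent runs of the same resampling test
#'
#' Iterations are mutually independent, so an iteration budget may be split
#' across runs (e.g. across workers) with seeds derived per partition and
#' the exceedance counts summed; the merged estimate is distributed as a
#' single run of the combined length would be.
#'
#' @param ... `cooccur_test` objects sharing method, factors and observed
#'   statistic.
#' @return A merged `cooccur_test`.
#' @export
merge_cooccur_tests <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "cooccur_test"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, TRUE, "cooccur_test")))
  first <- parts[[1L]]
  for (p in parts[-1L])
    if (p$method != first$method || p$observed != first$observed ||
        !identical(p$factors, first$factors))
      stop("cannot merge results from different tests")
  exceed <- sum(vapply(parts, `[[`, 0L, "exceed"))
  iters <- sum(vapply(parts, `[[`, 0, "iterations"))
  null_sample <- if (all(!vapply(lapply(parts, `[[`, "null_sample"),
                                 is.null, TRUE)))
    unlist(lapply(parts, `[[`, "null_sample"))
  mc_result(first$method, first$factors, first$observed, exceed, iters,
            first$seed, first$n_pool, first$n_a, first$n_b,
            null_sample = null_sample)
}
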