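#' Closed-form results for the simple paired co-occurrence model
#'
#' The simple model has `m` overlapped pairs (2m locations, one of each
#' factor per pair) plus `n_a - m` and `n_b - m` singleton locations for
#' factors A and B.  Its observed statistic under the binary policy equals
#' `m`, the maximum attainable under whole-pool permutation, which makes the
#' permutation-test p-value analytically tractable: it is the product of
#' the probability that exactly `m` of each factor's labels land on the
#' overlapped locations ([perm_assign_prob()]) and the probability that
#' those labels form a perfect cross-factor pairing ([pairing_prob()]).
#'
#' All combinatorial terms are evaluated in log space, so the functions are
#' stable for pool sizes in the tens of thousands.
#'
#' @param m number of overlapped pairs.
#' @param n_a,n_b total locations bound by factors A and B (each `>= m`).
#' @return A probability.
#' @name simple-model-closed-forms
#' @examples
#' perm_assign_prob(10, 20, 20)    # 0.2476
#' perm_assign_prob(10, 1000, 1000)  # 0.1771
#' pairing_prob(10)                # 0.00554
#' perm_pvalue_simple(10, 1000, 1000)  # 0.00098
NULL

check_simple_params <- function(m, n_a, n_b) {
  stopifnot(length(m) == 1L, length(n_a) == 1L, length(n_b) == 1L,
            m >= 0, n_a >= 0, n_b >= 0,
            m == round(m), n_a == round(n_a), n_b == round(n_b))
  if (m > min(n_a, n_b))
    stop("'m' cannot exceed min(n_a, n_b)")
}

#' @describeIn simple-model-closed-forms Hypergeometric probability that a
#'   random permutation assigns exactly `m` A-labels (and hence `m`
#'   B-labels) to the `2m` overlapped locations:
#'   \eqn{\binom{2m}{m}\binom{n_a+n_b-2m}{n_a-m} / \binom{n_a+n_b}{n_a}}.
#' @export
perm_assign_prob <- function(m, n_a, n_b) {
  check_simple_params(m, n_a, n_b)
  if (m == 0) return(1)
  stats::dhyper(m, 2 * m, n_a + n_b - 2 * m, n_a)
}

#' @describeIn simple-model-closed-forms Probability that `m` A-labels and
#'   `m` B-labels placed on the `2m` overlapped locations form a perfect
#'   cross-factor pairing: \eqn{2^m (m!)^2 / (2m)!}.  Independent of the
#'   total profile sizes, hence the ceiling of the permutation p-value.
#' @export
pairing_prob <- function(m) {
  stopifnot(length(m) >= 1L, all(m >= 0), all(m == round(m)))
  exp(m * log(2) + 2 * lgamma(m + 1) - lgamma(2 * m + 1))
}

#' @describeIn simple-model-closed-forms Exact permutation-test p-value for
#'   the simple model: `perm_assign_prob(m, n_a, n_b) * pairing_prob(m)`.
#'   Valid because the observed statistic `m` is maximal, so the only
#'   permutations reaching it are those reconstructing a perfect pairing.
#' @export
perm_pvalue_simple <- function(m, n_a, n_b) {
  perm_assign_prob(m, n_a, n_b) * pairing_prob(m)
}

#' Limiting null pmf of the hybrid statistic with no overlapped locations
#'
#' When every location in the joint pool is a singleton, the hybrid scheme
#' reduces to two independent without-replacement draws (sizes `n_a` and
#' `n_b`) from the `n_a + n_b` locations, and the statistic is the number
#' of locations drawn by both factors.  Its pmf is hypergeometric:
#' \deqn{P(S = k) = \binom{n_a}{k}\binom{n_b}{n_b-k} / \binom{n_a+n_b}{n_b}}
#' for `0 <= k <= min(n_a, n_b)` (zero outside that range), with mean
#' `n_a * n_b / (n_a + n_b)`.
#'
#' @param k number of dually-assigned locations (vectorised).
#' @param n_a,n_b profile sizes.
#' @return Probability of observing exactly `k` co-occurrences.
#' @examples
#' hybrid_limit_pmf(0:1, 1, 1)  # 1/2, 1/2
#' @export
hybrid_limit_pmf <- function(k, n_a, n_b) {
  stopifnot(n_a >= 0, n_b >= 0, n_a == round(n_a), n_b == round(n_b))
  stats::dhyper(k, n_a, n_b, n_b)
}
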