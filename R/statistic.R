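#' Co-occurrence statistic for an assignment of locations to two factors
#'
#' The statistic is the sum of matrix weights over every pairwise
#' combination of an A-assigned and a B-assigned record,
#' \eqn{\sum_{i \in A}\sum_{j \in B} c_{ij}}.  The double sum includes the
#' diagonal term (a record assigned to both factors overlaps itself) and
#' counts \eqn{c_{ij}} and \eqn{c_{ji}} separately when both records are in
#' both sets, so under the binary policy a fully dually-assigned overlapped
#' pair scores 4.
#'
#' Within a set each index may appear once (assignment within a factor is
#' without replacement); `setA` and `setB` may intersect under sampling
#' schemes that permit dual assignment.
#'
#' @param cm a `cooccur_matrix` from [build_cooccurrence()].
#' @param setA,setB integer vectors of joint-pool record indices (1-based),
#'   without duplicates.
#' @return The non-negative statistic score.
#' @export
cooccur_statistic <- function(cm, setA, setB) {
  stopifnot(inherits(cm, "cooccur_matrix"))
  setA <- as.integer(setA)
  setB <- as.integer(setB)
  if (anyDuplicated(setA) || anyDuplicated(setB))
    stop("an index may be assigned to a factor at most once")
  if (length(setA) && (min(setA) < 1L || max(setA) > cm$n) ||
      length(setB) && (min(setB) < 1L || max(setB) > cm$n))
    stop("indices out of range")
  inA <- inB <- logical(cm$n)
  inA[setA] <- TRUE
  inB[setB] <- TRUE
  score_assignment(cm, inA, inB)
}

# Hot path shared with the resampling engines: logical membership vectors in.
score_assignment <- function(cm, inA, inB) {
  s <- sum(cm$diag[inA & inB])
  if (length(cm$w))
    s <- s + sum(cm$w * ((inA[cm$ei] & inB[cm$ej]) +
                         (inA[cm$ej] & inB[cm$ei])))
  s
}

#' Observed co-occurrence statistic of two factors
#'
#' Evaluates [cooccur_statistic()] at the identity assignment: every record
#' is assigned to the factor whose profile it came from.  This is the
#' observed value against which the resampled null distributions are
#' compared.
#'
#' @param cm a `cooccur_matrix`.
#' @param a,b factor names present in the matrix.
#' @return The observed statistic score.
#' @export
observed_statistic <- function(cm, a, b) {
  stopifnot(inherits(cm, "cooccur_matrix"))
  for (f in c(a, b))
    if (!f %in% names(cm$sizes)) stop("unknown factor: ", f)
  score_assignment(cm, cm$origin == a, cm$origin == b)
}

#' Partition the joint pool into overlapped and singleton locations
#'
#' The hybrid resampling scheme splits the joint pool of the two tested
#' factors into two pools: the heterogeneously *overlapped* set (records
#' involved in at least one observed cross-factor overlap) and the
#' *singleton* set (everything else).  Overlaps between records of the same
#' factor do not count: only co-occurrence between the two tested factors
#' defines the first pool.
#'
#' @param cm a `cooccur_matrix`.
#' @param a,b the tested factor names.
#' @return List with integer index vectors `overlapped` and `singleton`
#'   (disjoint, jointly covering the pool).
#' @export
partition_pool <- function(cm, a, b) {
  stopifnot(inherits(cm, "cooccur_matrix"))
  for (f in c(a, b))
    if (!f %in% names(cm$sizes)) stop("unknown factor: ", f)
  het <- (cm$origin[cm$ei] == a & cm$origin[cm$ej] == b) |
         (cm$origin[cm$ei] == b & cm$origin[cm$ej] == a)
  ov <- sort(unique(c(cm$ei[het], cm$ej[het])))
  list(overlapped = ov,
       singleton = setdiff(seq_len(cm$n), ov))
}
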