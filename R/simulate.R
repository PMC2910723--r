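#' Generate the simple paired co-occurrence model
#'
#' Lays out `m` overlapped pairs — one interval of each factor per pair,
#' overlapping by `overlap_shift` bases — followed by `singletons_a` and
#' `singletons_b` isolated intervals that overlap nothing.  Clusters are
#' spaced `spacing` bases apart, so under the binary policy the observed
#' statistic of the generated pair is exactly `m`, the overlapped pool has
#' `2m` records and the singleton pool `singletons_a + singletons_b`.
#'
#' The layout is deterministic: under the binary scoring policy only the
#' overlap topology matters, so randomising the geometry could not change
#' any statistic.  A `seed` argument is accepted for interface uniformity
#' with the resampling functions.
#'
#' @param m number of overlapped pairs.
#' @param singletons_a,singletons_b isolated locations per factor.
#' @param interval_length length of every interval, bases.
#' @param overlap_shift bases by which the two intervals of a pair overlap
#'   (must be in `[1, interval_length)`).
#' @param spacing distance between consecutive clusters, bases; must exceed
#'   `2 * interval_length` so clusters stay disjoint.
#' @param contig contig name for all intervals.
#' @param factors names of the two generated factors.
#' @param seed unused; the layout is deterministic.
#' @return Named list of two [binding_profile()] objects with sizes
#'   `m + singletons_a` and `m + singletons_b`.
#' @examples
#' pair <- make_simple_model(m = 10, singletons_a = 5, singletons_b = 5)
#' sapply(pair, profile_size)
#' @export
make_simple_model <- function(m, singletons_a = 0, singletons_b = 0,
                              interval_length = 100, overlap_shift = 50,
                              spacing = 1000, contig = "chr1",
                              factors = c("A", "B"), seed = NULL) {
  stopifnot(m >= 0, singletons_a >= 0, singletons_b >= 0,
            overlap_shift >= 1, overlap_shift < interval_length,
            spacing > 2 * interval_length, length(factors) == 2L,
            factors[1L] != factors[2L])
  len <- as.integer(interval_length)
  cluster_at <- function(k) as.integer((k - 1L) * spacing)
  iv <- function(start) data.frame(contig = contig,
                                   start = as.integer(start),
                                   end = as.integer(start) + len,
                                   stringsAsFactors = FALSE)
  pair_starts_a <- if (m) cluster_at(seq_len(m)) else integer(0)
  pair_starts_b <- pair_starts_a + (len - as.integer(overlap_shift))
  off_a <- cluster_at(m + seq_len(singletons_a) + 1L)
  off_b <- cluster_at(m + singletons_a + seq_len(singletons_b) + 1L)
  a <- binding_profile(iv(c(pair_starts_a, off_a)), factors[1L])
  b <- binding_profile(iv(c(pair_starts_b, off_b)), factors[2L])
  stats::setNames(list(a, b), factors)
}

#' Generate a multi-factor scenario for the pooled (FL) null
#'
#' Builds a dataset around a tested pair of factors that co-occur as
#' `base_pairs` overlapped pairs, optionally adding `replicates` further
#' factor pairs binding the *identical* coordinates (emulating datasets in
#' which several factors share a binding pattern) and one extra factor with
#' `disjoint_sites` novel locations overlapping nothing.
#'
#' The tested pair is named `A`/`B`; replicate pairs `R1A`/`R1B`, ...; the
#' disjoint factor `DIS`.  Because the pooled null draws from the records
#' of every factor, replicate pairs dilute the significance of the tested
#' pair while a disjoint factor concentrates it — the scheme's sensitivity
#' to dataset composition.
#'
#' @param base_pairs overlapped pairs for the tested factors.
#' @param replicates additional factor pairs at the same coordinates.
#' @param disjoint_sites locations of the extra non-overlapping factor
#'   (0 = no such factor).
#' @param interval_length,overlap_shift,spacing,contig geometry, as in
#'   [make_simple_model()].
#' @param seed unused; the layout is deterministic.
#' @return Named list of `2 + 2*replicates + (disjoint_sites > 0)`
#'   [binding_profile()] objects, the tested pair first.
#' @examples
#' length(make_fl_scenario(40, replicates = 3))  # 8 profiles
#' @export
make_fl_scenario <- function(base_pairs = 40, replicates = 0,
                             disjoint_sites = 0, interval_length = 100,
                             overlap_shift = 50, spacing = 1000,
                             contig = "chr1", seed = NULL) {
  stopifnot(base_pairs >= 1, replicates >= 0, disjoint_sites >= 0)
  base <- make_simple_model(base_pairs, interval_length = interval_length,
                            overlap_shift = overlap_shift, spacing = spacing,
                            contig = contig)
  profs <- base
  for (r in seq_len(replicates)) {
    nm <- paste0("R", r, c("A", "B"))
    profs[[nm[1L]]] <- binding_profile(base$A$intervals, nm[1L])
    profs[[nm[2L]]] <- binding_profile(base$B$intervals, nm[2L])
  }
  if (disjoint_sites > 0) {
    far <- as.integer((base_pairs + 2L) * spacing) +
      as.integer(spacing) * seq_len(disjoint_sites)
    profs$DIS <- binding_profile(
      data.frame(contig = contig, start = far,
                 end = far + as.integer(interval_length),
                 stringsAsFactors = FALSE), "DIS")
  }
  profs
}
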