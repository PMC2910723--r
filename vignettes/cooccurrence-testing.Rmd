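---
title: "Assessing binding-site co-occurrence by resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing binding-site co-occurrence by resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccurbind)
```

## The problem

Most DNA-binding proteins act on chromatin as members of multi-protein
complexes, and genome-wide assays (ChIP-chip, ChIP-seq, DamID) reveal such
complexes as clusters of overlapping binding sites for the individual
components.  Given the binding profile of each factor — its list of bound
genomic intervals — the question is whether two factors overlap each other
more often than "by chance".  Because binding is strongly non-uniform along
the genome, parametric nulls are unreliable; resampling the observed
locations themselves is the natural alternative, and the entire difficulty
lies in *how* the locations are resampled.  This package implements one
statistic and four resampling nulls for it, together with closed-form
results for a tractable special case that anchor the Monte-Carlo machinery.

## The co-occurrence matrix and statistic

Profiles of the two tested factors A and B (sizes $n_A$ and $n_B$) are
concatenated into a joint pool of *location records*; a physical site bound
by $k$ factors contributes $k$ records.  A symmetric matrix $C = (c_{ij})$
scores every unordered pair of records: under the `binary` policy
$c_{ij} = 1$ when records $i$ and $j$ overlap by at least one base on the
same contig, and $c_{ii} = 1$ (a record overlaps itself); under the `bases`
policy the score is the number of shared bases.  For an assignment of
records to the factors ($L_A$, $L_B$) the statistic is

$$ S \;=\; \sum_{i \in L_A}\;\sum_{j \in L_B} c_{ij}. $$

The double sum runs over ordered pairs, so when both records of an
overlapped pair are assigned to both factors the pair contributes
$c_{ij} + c_{ji} + c_{ii} + c_{jj} = 4$; a dually-assigned singleton
contributes $c_{ii} = 1$.  Only *heterogeneous* overlaps (one A record, one
B record) can contribute to the observed statistic; overlaps between two
records of the same factor sit in the matrix but never meet the double sum
at the identity assignment.

The matrix abstracts away coordinates and the scoring policy: resampling
needs nothing but $C$.  Since records on different contigs can never
overlap, the matrix is assembled one contig at a time (interval overlap
queries are delegated to the IRanges machinery), which is exactly
equivalent to a whole-genome all-pairs scan and is asserted against one in
the test suite.

Coordinates are BED-style 0-based half-open; abutting intervals
(`end == start`) do not overlap, strand is ignored, and duplicated
coordinates are independent records that overlap each other fully.  All of
the package's validated results use the binary policy; the `bases` policy
is provided as an alternative weighting but has no external reference
values.

## The four null distributions

Each scheme redraws an assignment $(L_A^*, L_B^*)$ of sizes
$(n_A, n_B)$ and scores it with $S$; the estimated p-value is the fraction
of resamples with $S^* \ge S_{obs}$ (ties count as exceedances).

**Permutation** — the joint pool of the two profiles is split
exhaustively: $n_A$ records drawn without replacement for A, the rest to
B.  No record is unassigned or dually assigned, so overlaps can only recur
where they were observed.

**Independent resampling** — $L_A^*$ and $L_B^*$ are two independent
without-replacement draws from the pool; dual assignment is allowed and a
fully dual pair scores 4.

**Hybrid** — the pool is partitioned into the heterogeneously
*overlapped* records $O$ and the *singletons* $s$.  Records in $O$ may
be assigned to at most one factor; singletons to either or both.  The
implementation draws $L_A^*$ from $O \cup s$ without replacement, then
$L_B^*$ from $(O \setminus L_A^*) \cup s$.  The formal definition of the
draw order is an implementation choice; this one is pinned down by its two
limiting cases, which it provably reaches: with no singletons the scheme
*is* the permutation test, and with no overlapped records it is two
independent draws whose statistic — the number of dually drawn singletons —
has the hypergeometric pmf

$$ P(S = k) \;=\;
   \binom{n_A}{k}\binom{n_B}{n_B - k} \Big/ \binom{n_A + n_B}{n_B},
   \qquad 0 \le k \le \min(n_A, n_B), $$

with mean $n_A n_B / (n_A + n_B)$ (`hybrid_limit_pmf()`).  Both limits are
asserted by the tests (KS agreement with the permutation null; chi-squared
agreement with the pmf).  Note the B draw is always feasible: at most
$n_A$ records of $O$ are blocked, so at least $n_A + n_B - n_A$ remain.

**Pooled multi-factor null (FL)** — the null pool contains the records of
*every* factor in the dataset, not just the tested pair: $n_A$ records are
drawn for A, then $n_B$ from the remainder for B, and scored against the
whole-dataset matrix.  With a two-factor dataset the scheme collapses to
the permutation test (with a shared seed the implementation produces
bit-identical draws).  Its distinguishing property — and liability — is
that the p-value of a pair depends on which other factors are in the
dataset.  The variant that holds one profile fixed while permuting the
other is deliberately not implemented: it treats the two factors
asymmetrically and is excluded from scope.

## The simple paired model and its closed forms

The analytically tractable case has $m$ overlapped pairs plus
$n_A - m$ and $n_B - m$ singletons.  Its observed binary statistic is $m$ —
the permutation maximum, since singletons can never meet.  The permutation
p-value is then exactly the probability of re-creating a perfect pairing:

$$ p \;=\; P_m \cdot P_{pair}, \qquad
   P_m = \frac{\binom{2m}{m}\binom{n_A+n_B-2m}{n_A-m}}
              {\binom{n_A+n_B}{n_A}}, \qquad
   P_{pair} = \frac{2^m\,(m!)^2}{(2m)!}. $$

$P_m$ (the probability that exactly $m$ of each factor's labels land on
the $2m$ overlapped locations) hardly moves with the total number of
sites — it is 0.2476 at $n_A = n_B = 20$ and 0.1771 at $n_A = n_B = 1000$,
converging to the central term $\binom{2m}{m}/2^{2m}$ — so the p-value is
dominated by $P_{pair}$, which depends only on the *count* of overlaps
(0.0055 at $m = 10$, $7.6\times10^{-6}$ at $m = 20$).  A permutation test
therefore declares almost any recurring overlap count significant no
matter how small a fraction of the profiles it represents; this
insensitivity to the overlapped *proportion* is the motivation for the
hybrid scheme, whose p-value rises from ~0.005 to ~0.12 when five
singletons per factor are added to a ten-pair model.  All binomial
coefficients are evaluated through `lgamma`/`dhyper` in log space, so the
closed forms are stable at pool sizes of $10^4$ and beyond.

`perm_pvalue_simple()` is validated against exhaustive enumeration of all
$\binom{n_A+n_B}{n_A}$ splits on small models, and the Monte-Carlo
engines are validated against it and against each other (see
`tests/testthat/`).

## The co-localization index

An earlier permutation-based approach ranked factor pairs by the
co-localization index $CI = N/R$ (or $\log N/R$), the ratio of the
observed co-occurrence count to the count after one permutation.
`ci_distribution()` simulates the permutation distribution of $CI$ for the
simple model; running it at a fixed number of overlapped pairs with
singleton loads differing 100-fold produces nearly indistinguishable
distributions, illustrating that $CI$, like the permutation p-value, is
blind to the overlapped fraction.  Resamples in which the permuted count
is zero leave the ratio undefined; they are dropped from the index sample
and reported in `n_zero`.

## Synthetic data generators

`make_simple_model()` and `make_fl_scenario()` produce the study
conditions used throughout the tests: intervals of 100 bases, paired
intervals overlapping by 50, clusters spaced 1000 bases apart on one
contig, singletons placed beyond the paired region.  The geometry is
deterministic and arbitrary by design — under the binary policy only the
overlap topology can influence any statistic, a property the suite asserts
by rescaling the geometry and comparing seeded runs bit-for-bit.  The FL
scenarios add replicate factor pairs at coordinates identical to the
tested pair's and, optionally, one factor whose sites overlap nothing.

What the generators emulate is the *combinatorial* structure of binding
data: counts of overlapped and isolated sites.  They do not emulate peak
width variation, partial or chained overlaps (site A–B–C), clustering of
sites along the chromosome, or contig structure — so passing tests
demonstrate correctness of the statistics and samplers under known
topology, not robustness to the messiness of real peak calls.  For real
data those features enter through the co-occurrence matrix, which the
resampling layer consumes unchanged.

## Numerical and design choices

* **Exceedance and estimator.** `p = exceed / iterations` with `>=`; no
  `+1` continuity correction is applied, keeping the estimator the plain
  null exceedance proportion.  When `exceed` is zero the result is
  reported as `< 1/iterations` — at $10^5$ iterations, `< 1e-05`.
* **Seeding.** Every stochastic entry point takes an integer `seed`;
  identical inputs give bit-identical results, and the caller's RNG stream
  is saved and restored.  Iterations are independent, so an iteration
  budget may be split into seeded parts and pooled with
  `merge_cooccur_tests()` (exceedances and iterations add).  The all-pairs
  screen derives per-pair seeds from the factor *names*, so a pair's
  pair-pool p-values do not change when unrelated factors enter or leave
  the dataset.
* **Survey-then-full.** Screening first spends a 100-iteration survey per
  pair and abandons those with estimated p above 0.1, then runs the full
  budget (default 5000) afresh for the survivors — the standard two-stage
  economy for all-pairs scans.  Both stages honour the single seed.
* **Degenerate inputs.** Empty profiles give an empty joint pool, which
  the pair tests reject; an observed statistic of zero yields p = 1 under
  every scheme; `m = 0` closed forms return 1.
* **Problem sizes.** The validation suite uses the scenarios the closed
  forms and reference synthetic values anchor: models up to $m = 40$
  pairs, pools up to 2000 records, $5\times10^4$–$2\times10^6$ iterations
  in the heaviest checks, and exhaustive enumeration oracles on pools of
  up to ~10 records.

## Limitations

* P-values are reported raw, matching the screening use case; the
  `cooccur_screen` table carries everything needed to apply
  `p.adjust()` downstream if a corrected column is wanted.
* The resolution of any Monte-Carlo p-value is bounded by `1/iterations`;
  very small p-values are bounds, not estimates.
* The statistic is the pairwise sum only — no higher-order (3+ factor)
  co-occurrence statistic is attempted.
* The method assumes profiles are *observed* chromatin state; it is not
  suitable for motif-hit co-occurrence, where the sequence composition
  must enter the null.

## A worked example

```{r example}
pair <- make_simple_model(m = 10, singletons_a = 5, singletons_b = 5)
cooccur_test(pair, "A", "B", method = "hybrid",
             iterations = 20000, seed = 1)
```

```{r screen-example}
profs <- make_fl_scenario(10, replicates = 1)
screen_pairs(profs, methods = c("hybrid", "fl"), iterations = 1000,
             seed = 1)
```
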