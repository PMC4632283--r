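---
title: "Methods: aberration calling, clonality testing, subtype scoring and promoter methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aberration calling, clonality testing, subtype scoring and promoter methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccstats)
```

`hccstats` packages five statistical stages that recur in hepatocellular
carcinoma (HCC) genomics: copy-number aberration calling from aCGH log2
ratios, a permutation test for the clonality of paired tumor/metastasis
aberration profiles, marker-panel clustering of expression cohorts with
signal-to-noise-ratio (SNR) scoring, Kolmogorov–Smirnov (KS) differential
expression with Pearson gene–gene correlation, and promoter methylation
averaging. This vignette explains each model, its assumptions, the tunable
parameters, and the design choices made where the methods are conventionally
underspecified. All empirical statements below are the ones the package's
own test suite and `scripts/acceptance.R` compute.

## Aberration calling

An aCGH probe profile is a table of ordered genomic probes with a log2 ratio
of tumor versus reference copy number. `call_aberrations()` labels each probe

* **gain** if `log2ratio > t`,
* **loss** if `log2ratio < -t`,
* **neutral** otherwise,

with `t = 0.25` by default, the standard log-ratio calling threshold for this
platform class. Two conventions are fixed deliberately:

* **Boundary probes are neutral.** A magnitude exactly equal to `t` does not
  call an aberration; strict inequalities make noiseless fixtures
  unambiguous.
* **Per-probe calling, no segmentation.** The threshold is applied to each
  probe's ratio directly. Segmentation-based callers (circular binary
  segmentation and mixture calling) are a different method family and are
  intentionally out of scope here; the rest of the pipeline only requires
  ternary per-probe states.

Calling is monotone in the threshold and equivariant under negating the
ratios (gains and losses swap); both are asserted as property tests.
`aberration_frequencies()` aggregates calls from samples on an identical
probe grid into the classic per-probe fraction-gained/fraction-lost track.
Grid identity is checked on the probe-identifier sequence, not coordinates:
downstream matching assumes positionally comparable samples.

## Clonality permutation test

The clonality question: do a primary tumor and a metastasis share more
positionally matching aberrations than two unrelated profiles with the same
aberration burdens would? The statistic is the observed match count `o`. By
default matching is **sign-specific** — a gain matches a gain, a loss a loss
— because matching a gain to a loss is not evidence of shared clonal origin;
`mode = "any_aberration"` relaxes this.

The null is built by redrawing the aberration positions of the sample that
carries **fewer** aberrant probes uniformly without replacement over the
whole probe grid, keeping its gain and loss counts and leaving the other
sample fixed. Each of `n` replicates yields a match count `ri`, and

\[
r = \#\{\,ri > o\,\}, \qquad \hat P = r/n ,
\]

with strict exceedance. When `r = 0` the test reports the upper bound
`P < 1/n` (at the default `n = 100\,000`, `P < 10^{-5}`) rather than zero;
the raw counts are kept in the result. Redraws are genome-wide — a single
position pool — not per-chromosome. An alternative reading of "reordering
against the other sample's aberration positions" restricts the redraw pool
to the fixed sample's aberrant probes; it is available as
`redraw_pool = "other_aberrant"` for sensitivity analysis but is not the
default, since the genome-wide pool preserves both samples' burdens and
yields a well-defined null for any pair.

`exact_clonality_test()` enumerates every redraw configuration (position
subsets, with gain/loss assignments exactly as the Monte-Carlo scheme draws
them) and returns the exact exceedance probability. It is the testing oracle
for the Monte-Carlo path and refuses instances above a configurable
configuration cap (default $10^6$). The exact P is symmetric in the two
samples — with both position sets exchangeable, conditioning on either side
gives the same law of the match count — and the suite asserts this.

### Calibration and the discreteness of the match count

The match count is integer-valued, so the strict-exceedance estimate `r/n`
is not uniformly distributed under the null: large probability atoms sit on
few support points, and `r/n` (which estimates `P(R > o)` without the tie
mass) is anti-conservative at those atoms. Calibration is therefore assessed
with **randomized p-values**

\[
p = \bigl(\#\{ri > o\} + U \cdot \#\{ri = o\}\bigr)/n, \qquad U \sim
\mathrm{Unif}(0,1),
\]

the standard construction for discrete tests: these are exactly uniform when
the test is calibrated. `clonality_test()` returns both `r` and the tie
count `r_eq` so any estimator — strict (the default, reported), inclusive
`(r + r_{eq})/n`, add-one `(r+1)/(n+1)`, or randomized — can be formed
without re-running permutations. The calibration suite runs 500 unrelated
pairs (100 probes, 10 aberrations each, 2000 replicates per test) and
requires the Kolmogorov distance of the randomized p-values from uniform to
stay below the $\alpha = 0.01$ critical value.

## Synthetic cohorts with planted truth

Every stage is exercised on generated data whose ground truth is known
exactly:

* `simulate_acgh_pair()` plants shared gains/losses (same sign, same
  positions in both samples) and private aberrations (aberrant in exactly
  one sample) on an abstract probe grid, then adds i.i.d. Gaussian probe
  noise on the log2 scale. All planted position sets are disjoint, so the
  planted state table is unambiguous. Defaults — aberration levels
  $\pm 0.6$, noise SD $0.1$ — put planted aberrations comfortably beyond the
  $0.25$ threshold (the single-probe miscall rate is
  $\Phi((0.25-0.6)/0.1) \approx 2\times10^{-4}$), realistic for averaged
  array ratios while leaving the calling step something to do.
* `simulate_null_pair()` draws two samples' aberrant positions independently
  and uniformly, signs by fair coin — the null of the permutation test. For
  two samples with $k_A, k_B$ aberrations on $g$ probes the expected
  sign-specific match count is $k_A (k_B/g) \tfrac12$, which the suite
  verifies against the generator.
* `simulate_expression_cohort()` builds a gene × sample log2 matrix with
  gene baselines $\sim N(7, 1)$ (the scale of RMA-normalized intensities),
  planted sample classes, and marker genes shifted by `effect_size` only in
  their own class. Defaults (60 samples, 2 classes, 20 markers/class, shift
  3, residual SD 1) describe a strongly subtyped cohort, the regime in which
  marker-panel clustering is meaningful.
* `simulate_methylation_cohort()` places `probes_per_promoter` probes within
  ±2000 bp of each gene's strand-aware TSS plus one **decoy probe outside
  the window** per gene — the decoys exist purely to exercise the window
  filter — and plants a tumor-vs-normal beta shift on a designated gene
  subset. Betas are truncated Gaussians (clipped to $[0,1]$) around
  baselines drawn from $[0.35, 0.65]$, leaving headroom for the default
  $\Delta\beta = -0.3$ hypomethylation.

Chromosome structure is cosmetic (a single linear coordinate): the
permutation test operates on probe positions, not genomic distances. The
generators emulate planted mean structure with homoscedastic noise; they do
not model probe-specific biases, GC waves, correlated noise along the
genome, mixed tumor purity, or platform batch effects. Passing tests
therefore demonstrate correctness of the statistics on their idealized
sampling models, not robustness to every artifact of real arrays.

## Subtype clustering and SNR attribution

`cluster_subtypes()` clusters samples on the panel-gene submatrix with
**complete-linkage** hierarchical clustering. Conventions the method family
leaves open are fixed as:

* **Distance**: 1 − Pearson correlation between sample profiles over panel
  genes, the convention for expression subtyping (robust to row scaling);
  Euclidean by flag.
* **Standardization**: gene-wise zero mean/unit variance before clustering,
  on by default, so high-variance genes do not dominate.
* **`k`**: the caller's choice, defaulting to 2; in liver cohorts the
  Hoshida S1–S3 panel conventionally yields 2 major classes and the Chiang
  panel 3.
* Classes are renumbered by decreasing size, so "class 1" is always the
  largest.

`snr_scores()` implements the Golub-style signal-to-noise ratio
$\mathrm{SNR} = (\mu_1 - \mu_0)/(\sigma_1 + \sigma_0)$ with **population**
(divide-by-n) standard deviations and a per-class floor
$\sigma \leftarrow \max(\sigma,\, 0.01\,|\mu|,\, 0.01)$. The floor constants
are artifact choices (configurable) in the Golub tradition of guarding the
denominator; with them SNR remains shift- and scale-invariant per gene to
well beyond the precision of any decision made with it, and exactly
antisymmetric under swapping the class designation.

`marker_class_composition()` attributes each panel gene to the discovered
class maximizing its SNR (that class versus the rest) and reports, per panel
subclass, the fraction of its genes landing in each class — the computation
behind statements like "84% of S1 marker genes were found in class 1". SNR
ties are broken toward the larger class and reported; with continuous
expression values they occur with probability zero.

## KS differential expression and correlation

`ks_differential_expression()` runs a per-gene two-sample, two-sided KS test
between two groups. The exact small-sample null is used when both groups
have ≤ 25 samples, the asymptotic distribution otherwise — exactness where
it is cheap. Raw p-values are reported (no correction is applied to the
primary column, matching how such screens are conventionally read), with a
Benjamini–Hochberg column alongside. One subtlety the suite makes explicit:
the KS statistic for groups of sizes $m, n$ lives on a lattice, so its
p-values are only near-uniform under the null when $m, n$ are coprime (fine
lattice) and the exact null is used; the uniformity property test uses a
29-vs-31 split for that reason.

`gene_correlation()` is the sample Pearson coefficient across samples with
$R^2 = r^2$ and the usual $t_{n-2}$ p-value. $R^2$ is reported because
correlations between oncogene pairs are conventionally quoted that way.

## Promoter methylation

`map_probes_to_promoters()` assigns a probe to a gene iff its position is
within 2000 bp of the gene's TSS — a **closed** interval (a probe at exactly
±2000 bp is included), symmetric around the TSS. Strand determines where
the TSS sits on the BED interval (start for `+`, end for `-`) but does not
skew the window; asymmetric upstream-weighted windows are a reasonable
alternative the interface could grow, but the plain symmetric reading is
the default. Probe coordinates follow the 1-based platform-manifest
convention, BED inputs the 0-based half-open convention; conversion happens
at I/O.

`promoter_methylation_means()` averages the mapped probes' betas per gene
and sample — regions covered by multiple probes are summarized by their
arithmetic mean — and `compare_promoter_methylation()` tests tumor versus
normal per gene (KS by default for consistency with the expression module;
Wilcoxon rank-sum by flag), reporting the direction of the tumor shift
(hypo/hyper). Filtering strictly precedes averaging, so decoy probes
outside the window can never leak into a promoter mean; the suite asserts
this, plus the boundary behavior at ±2000/±2001 bp, against the generator's
placements.

## Problem sizes and numerical choices

The test and acceptance workloads use: a 2000-probe clonal pair at
`n = 100 000` permutations for the headline bound; 50 random ≤ 12-probe
instances against the exact enumeration oracle (tolerance 3 binomial
standard errors of the exact P); 500 null pairs × 2000 permutations for
calibration; 50 seeds × 1000 probes for calling recovery; a 200 × 60 cohort
for subtype recovery (adjusted Rand index against planted labels, computed
with `mclust::adjustedRandIndex` as an independent oracle); and a 25-gene
methylation cohort. These sizes make every planted effect decisively
detectable under the generators' default noise levels while keeping the full
suite comfortably reproducible on a single CPU.

Other numerical conventions: permutation replicates draw positions with
`sample.int` (no replacement) and assign the first $g$ drawn positions as
gains, which is equivalent to a uniformly random state assignment because
the draw order is exchangeable; the exact enumerator iterates gain-position
subsets and then loss-position subsets of the remainder, mirroring that
scheme; all parsers reject rather than coerce malformed input; and every
stochastic entry point takes an explicit integer seed, making each result
replayable from its recorded parameters.

## Known limitations

* Per-probe thresholding ignores spatial correlation along the genome; it
  is the intended method here, not a general-purpose CNA caller.
* The clonality null treats probes as exchangeable positions; chromosome
  boundaries and local dependence are ignored by design (single position
  pool).
* SNR-based attribution assumes classes differ in mean; purely
  variance-driven subtypes would not be attributed sensibly.
* The generators' noise models are homoscedastic Gaussians; conclusions
  about real-array robustness require real arrays.
* Cohort-specific results from published liver datasets (specific class
  compositions, specific gene correlations) depend on those cohorts and are
  not reproduced by synthetic data; the package reproduces the methods, and
  its acceptance workload checks them against planted truth and exact
  oracles instead.
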