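---
title: "Differential SEC co-fractionation profiling with secshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential SEC co-fractionation profiling with secshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secshift)
library(dplyr)
```

## The problem

Size-exclusion chromatography coupled to data-independent-acquisition mass
spectrometry (SEC-SWATH-MS) separates native protein complexes by
hydrodynamic size and quantifies the proteins of every fraction. A protein
engaged in a complex elutes earlier (at larger apparent molecular weight)
than its monomer; when two biological states are profiled, a protein whose
complex engagement changes shows a shift of signal between elution
positions even when its total abundance is constant. `secshift` turns
peptide-level fractionation intensity tables from two conditions into
statistically scored, SEC-localized differential association calls, and
aggregates them into complex-level remodeling inferences.

The pipeline has three stages, each exposed as ordinary tibble-in,
tibble-out functions:

1. **Preprocessing** — spike-in normalization, spline smoothing of
   per-fraction totals, interpolation of internal detection gaps,
   removal of short identification stretches, sibling-peptide-correlation
   filtering with target-decoy calibration, and top-2 protein
   quantification.
2. **Feature detection** — protein elution peaks ("features") found from
   co-peaking sibling peptides on an integrated master map, with decoy-based
   q-values and assembled/monomeric annotation from a log-linear MW
   calibration.
3. **Differential testing** — paired peptide-level t-tests on
   feature-summed intensities, order-statistic aggregation to
   protein-feature p-values, Benjamini-Hochberg correction, change
   classification, and complex remodeling calls against priors.

## The statistical model

### Peptide-level tests

For each detected feature of a protein, every sibling peptide's intensity
is summed over the feature's fraction range `[left, right]` (inclusive) in
each run. With `n` paired replicates per condition the log2 intensities are
compared by a two-sided paired t-test; the peptide's log2 fold change is
the mean paired difference (second condition over first). Testing operates
on minimally processed values — normalized only — so that the raw replicate
variability enters the test rather than being absorbed by smoothing or
imputation. Zero cells are first replaced by draws from `Uniform(0, Q)`
with `Q` the 5th percentile of all nonzero feature-summed values; the pool
is dataset-wide because per-feature pools would be unstable for small
features.

### Protein-level aggregation

The `k`-th smallest of `n` independent uniform p-values follows a
`Beta(k, n - k + 1)` law. With `k = ceiling(n / 2)`, evaluating that beta
CDF at the observed `k`-th order statistic of the peptide p-values yields a
protein-level p-value that tolerates a minority of discordant peptides.
Two schemes are implemented:

* **plain** (default): the two-sided peptide p-values are aggregated
  directly. Under the null this statistic is *exactly* uniform for every
  `n`, which we verified by simulation and rely on for calibrated type-I
  error control.
* **adjusted**: each peptide p is first converted to a one-sided p toward
  the protein's median fold-change direction (`p/2` when concordant,
  `1 - p/2` otherwise), aggregated, and re-two-sided as `2 min(B, 1 - B)`.
  This rewards directional concordance. It is exactly calibrated for odd
  `n`; for even `n` the two directional aggregates are not complementary,
  which leaves a small conservative point mass at p = 1. Its rejection
  rates at 0.05 and 0.01 remain correct, but its null distribution is not
  exactly uniform, which is why it is not the default.

A related numerical point: the beta law describes an *order statistic*, not
the interpolated midpoint median. For an even number of peptides we
therefore aggregate the `k`-th order statistic itself (`k = n/2`), not the
mean of the two central values; using the midpoint-mean with the same beta
parameters is badly conservative (empirical type-I error of roughly 0.004
at a nominal 0.05 in our simulations). The midpoint median is still used to
summarize fold changes, where no distributional claim is attached.

BH adjustment runs over the full family of (protein, feature) tests of an
experiment, matching per-feature reporting. A call is significant at
`pBHadj <= 0.01` and `|median log2 FC| >= log2(1.5)` by default. The
feature with the lowest `pBHadj` (ties: larger |fold change|, then earlier
apex) represents the protein in single-score summaries, and the
total-abundance test applies the identical machinery to across-all-fraction
sums, so that mass redistribution between elution states (feature-level
significant, total-level flat) is separable from abundance change.

### Feature detection and error control

Per protein, peptide traces are smoothed with a centered moving average
(window 3, a minimal smoother that cannot displace an apex by more than one
fraction) and summed into a consensus trace. Local maxima of the consensus
above a noise floor of 1% of the consensus maximum are candidate apexes,
bounded by the flanking local minima; candidates whose ranges overlap by
more than half the smaller width are merged toward fewer, wider features. A
peptide participates in a feature if one of its own local maxima falls
inside the boundaries; the co-elution score is the mean pairwise Pearson
correlation of participating peptides across the feature range, weighted by
the participating fraction of the protein's peptides. Decoy proteins built
by randomly reassigning peptides to pseudo-proteins (preserving the
peptide-count distribution, seeded) provide the null score distribution,
and q-values are the monotonized decoy/target tail ratio. Features need at
least two participating peptides; reported features pass `q <= 0.05`.

All constants — window, noise floor, merge threshold, q cutoff — are
exposed as arguments. They are our own re-specification of the co-elution
peak-picking idea: sensible, minimal defaults rather than values
transcribed from any particular dataset.

### Calibration and assembly state

Apparent MW decays log-linearly with fraction on a SEC column:
`MW(f) = exp(a + b f)` with `b < 0`, fit by OLS of `ln MW` on the apex
fractions of standards (natural log internally; the base is immaterial to
the fitted map). A feature is *assembled* when its apparent MW is at least
twice the sequence-predicted monomer MW (boundary inclusive), else
*monomeric*. Extrapolation beyond the calibrated range is permitted —
columns behave log-linearly somewhat beyond the standards — but worth
checking when standards span a narrow range.

### Classification and complex remodeling

Significant proteins with one significant feature are class 1 (assembled)
or class 2 (monomeric). With two or more significant features, `deltaFC`
is the ratio of the largest to the smallest linear fold change among them;
`log10(deltaFC) <= 1` is class 3 (similar), `> 1` class 4 (dissimilar).
Whether fold-change *signs* should enter separately from magnitudes is
genuinely open; we adopt the magnitude-ratio reading — the simplest measure
that is invariant under swapping condition labels — and expose the cutoff.

A prior complex is called *remodeling* when at least two subunits have a
significant assembled-range feature. Monomer-range changes never count:
they say nothing about the complex-bound pool. Complexes with fewer than
two detected subunits are reported as not covered rather than called.
Overlapping complexes are scored independently, with no merging.

## The synthetic-data generator

`simulate_sec_experiment()` emulates the data-generating process the
pipeline assumes: 65 fractions; per protein 1–5 Gaussian elution peaks
(width 1–2 fractions, apexes at least 6 fractions apart) and 2–40 sibling
peptides; lognormal peptide response factors (sdlog 1) fixed across runs,
because ionization efficiency is a property of the peptide; multiplicative
lognormal measurement noise (CV 0.2); 2 conditions x 3 replicates with
per-run lognormal scale distortions (sdlog 0.2) that normalization must
remove; flat spike-in standard peptides; decoy proteins assembled from
reshuffled peptide sets; and a detection-limit floor (default 1e4 against
a median protein amount of 1e6) that produces the preferential dropout of
weak signals seen in real data, plus an optional
missing-completely-at-random component. Protein amounts are lognormal
(sdlog 1), spanning the orders of magnitude typical of cellular proteomes.
Calibration standards are emitted exactly on the generating log-linear MW
grid so that fit recovery is exact by construction.

Condition effects act on peak amplitudes only: uniform abundance change
(default 4-fold), redistribution of mass from the first to the last peak
with conserved totals, or a peak gained in the second condition. Ground
truth records every planted peak, amplitude, effect and the class the
four-category rules would assign to the planted fold changes.

What the generator does *not* emulate: chromatographic tailing and
fraction-boundary effects, retention drift between runs, correlated
(structured) noise across peptides of a fraction, interference between
co-eluting peptides, and peptide-specific missingness beyond the intensity
floor. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artifact of real
chromatography.

## Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to give stable Monte-Carlo
estimates while staying comfortably interactive: null calibration on
10,000 simulated proteins; the order-statistic oracle on 100 random
instances with 4,000 Monte-Carlo draws each; planted-peak recovery on 500
proteins (3–12 peptides, peaks at least 6 fractions apart, CV 0.2); and an
end-to-end screen of 1,000 proteins with 20% planted 4-fold changes plus
5% redistribution cases. On these conditions the screen reaches sensitivity
above 0.99 at an observed false discovery proportion of 0, recovers more
than 99% of planted peaks with every matched apex within one fraction, and
flags redistribution cases by feature tests while the total-abundance test
stays silent — the behaviour that motivates SEC-localized testing in the
first place.

## Numerical choices and degenerate inputs

* Natural cubic interpolating splines fill internal detection gaps (only
  gaps flanked by at least two consecutive identifications on both sides);
  a cubic smoothing spline with GCV-selected smoothness rescales
  per-fraction totals. These are the simplest members of the spline family;
  imputed values are floored at 0 and observed values are never modified.
* Zero-variance paired differences make the t-statistic undefined; such
  peptides get the smallest positive double as p-value and a `degenerate`
  flag rather than silently dropping out.
* Pearson correlations of constant traces are undefined; they contribute 0
  to sibling and co-elution scores.
* Ties in top-2 peptide selection break lexicographically by peptide id;
  ties in representative-feature selection break by larger |fold change|,
  then earlier apex; rank-sum ties break by lower `pBHadj`. All are
  deterministic.
* Imputation draws are sub-seeded per cell from a rolling hash of the cell
  identity, so results do not depend on row order.
* Cross-run fraction alignment is assumed exact (fraction collection is
  hardware-synchronized in the targeted workflow) and not implemented.

## Known limitations

Protein inference is out of scope: input peptides must be proteotypic and
pre-mapped. Precursor-level error control belongs to the upstream targeted
extraction. The t-tests are unmoderated (no empirical-Bayes variance
shrinkage); with three replicates the heavy-tailed df = 2 null is the price
of keeping the raw replicate variability, and statistical power for
proteins with very few peptides is correspondingly limited. Subunit
stoichiometry and co-elution against complex hypotheses are not estimated.
The windowed co-elution search nominates candidates by local correlation
only; co-elution of physically independent complexes of similar size is an
unavoidable confounder that the window-summed intensity column can help
screen, not resolve.
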