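---
title: "Dose-responsive promoter discovery from DNase accessibility profiles"
author: "DoseDHS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-responsive promoter discovery from DNase accessibility profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DoseDHS)
```

## The problem

During early T cell development, hematopoietic progenitors (LSK cells)
progress through the double-negative stages DN1 → DN2a → DN2b, with the
DN2b transition marking T-lineage commitment. This progression depends on
the *dose* of Notch signaling: low dose carries cells to DN1, and only high
dose (as in the thymus) drives them to DN2b. A chromatin-level explanation
is that promoters of commitment genes are DNA-inaccessible in the ground
state and carry low CpG content, so they require a high Notch dose to open,
while low-dose-responsive promoters open already at the DN1 transition.

Testing this requires four computational pieces, which this package
implements as one chain: a spatial differential-accessibility test on
DNase-seq cut-count profiles over fixed DHS windows; expression
fold-change gates; a rule-based dose-response classification; and a
promoter CpG observed/expected comparison. A synthetic-data generator with
planted ground truth makes every piece testable at desk scale.

## The differential-accessibility model

The unit of analysis is a fixed 4-kb DHS window divided into 20-bp bins.
For each sample, the data are integer cut counts per bin, normalized to
reads per million (RPM). For stages $A$ and $B$ with $n_A, n_B \ge 2$
replicates, let $\bar y_A(b)$, $s_A^2(b)$ denote the per-bin replicate mean
and variance. The unsmoothed score is

$$\mathrm{TS}_{\mathrm{dnun}} = \frac{1}{B}\sum_{b=1}^{B}
  \frac{(\bar y_A(b) - \bar y_B(b))^2}
       {s_A^2(b)/n_A + s_B^2(b)/n_B + \varepsilon},$$

a Welch-standardized integrated squared difference. Because each bin is
standardized by its own Welch variance, the score tolerates
heteroscedastic error variance across samples and stages. The smoothed
variant $\mathrm{TS}_{\mathrm{kn}}$ applies a Nadaraya–Watson Gaussian
kernel (SD 150 bp on the bp scale, echoing the 150-bp display-window
convention for these data) to the condition-mean curves and to the Welch
variance term before forming the same quadratic form. Both scores are
non-negative, zero iff the (smoothed) condition means coincide, invariant
to swapping the two conditions, and respond to all three alternative
shapes of interest: a peak present in one stage only, a height change, and
a positional shift (the smoothed score is the natural detector for
shifts; both detect them in practice).

**Variance floor.** With 2–3 replicates, many background bins have zero
replicate variance, and the raw ratio would blow up. We floor the
denominator with $\varepsilon = 0.5 \cdot \mathrm{median}_b(s_A^2(b)/n_A +
s_B^2(b)/n_B) + 10^{-12}$: half the typical Welch variance in that region.
The absolute $10^{-12}$ term keeps the score finite in the degenerate
all-variances-zero case (where the score is then dominated by any mean
difference, which is the desired behavior).

## Null calibration: permutations and the pooled Gamma tail

The null distribution is built by permuting condition labels across the
pooled replicates, which is exactly valid under exchangeability and makes
no distributional assumption. With $n_A = n_B = 3$ there are
$\binom{6}{3} = 20$ distinct assignments; `permutationPvalue()` enumerates
them and reports $p = \#\{\mathrm{stat} \ge \mathrm{observed}\}/20$ with
ties counted conservatively. Two facts about this empirical p matter:

* both scores are invariant under swapping the groups, so the complement
  of the identity assignment always ties with it and the smallest
  attainable p is $2/20 = 0.1$;
* Bonferroni control over hundreds of regions needs p-values several
  orders of magnitude smaller than that.

No per-region enumeration at realistic replicate counts can deliver such
resolution, so `diffAccessTest()` additionally computes a continuous tail
p-value: the permutation statistics of *all* regions in the run are pooled
(excluding each region's identity and complement assignments, which by
construction equal the observed score and would contaminate the null under
alternatives), a Gamma distribution is moment-matched to the pool, and the
p-value is its upper tail at the observed score. The standardized form of
the score is what makes it comparable across regions and the pooling
legitimate. This pooled-tail p is the default evidence used downstream;
the coarse empirical p is always reported alongside. Under label-swapped
alternatives the remaining mixed assignments are mildly inflated relative
to a pure null, which biases the fitted null upward and makes the tail p
conservative — an acceptable direction.

In simulation at the default conditions (1000 null regions, 3v3, Poisson
background 0.5 cuts/bin) the tail p rejects at a rate close to the nominal
$\alpha = 0.05$; the test suite and `scripts/acceptance.R` recompute this.

## Multiple testing: effective number of tests

DHS windows from merged stage-wise peak lists can overlap, and overlapping
windows test nearly the same signal. `adjustEffectiveBonferroni()` merges
overlapping regions into single-linkage clusters, takes the minimum p per
cluster, multiplies by the number of clusters (the effective number of
tests), and assigns the result back to every member region. With disjoint
regions this is plain Bonferroni. The cluster count is recorded in the
result's metadata. Significance downstream is `p_adjusted < 0.05`.

## Accessibility calls, gates, classification

Accessibility per (region, stage) either comes from externally supplied
hotspot BEDs (midpoint membership) or from a threshold rule: mean RPM per
bin over the central 1 kb at least $3\times$ a background estimate, taken
as the 25th percentile of per-bin stage-mean RPM across regions. The 25th
percentile is a robust background proxy because peaks occupy a minority of
region-bins; the factor 3 separates the planted 10×-background apexes from
background fluctuations by a wide margin in both directions.

Expression gates use CPM (counts × 10^6 / column sum; no between-sample
normalization factors, the simplest defensible choice, recorded in the
config echo). Genes need ≥ 1 CPM in ≥ 2 samples to survive filtering —
the edgeR-style reading, with 2 the size of the smallest group. Group-mean
CPM receives a 0.5 pseudocount before the log-ratio; without it,
high-dose genes silent in control would produce infinite fold-changes.
Gates are inclusive at the threshold (log2FC ≥ 2).

Classification evaluates, in order, **high** (LSK and DN1 closed, DN2b
open, adjusted DN1~DN2b p < α, high gate), **low_I** (LSK closed, DN1
open, adjusted LSK~DN1 p < α, low gate), **low_II** (LSK open, adjusted
LSK~DN1 p < α with positive DN1 − LSK mean-RPM effect, low gate). The
classes are mutually exclusive on the accessibility flags; the fixed order
is a safety convention. "Increased in DN1" is operationalized as
significance *plus* a positive signed effect, since direction is otherwise
stated only verbally. DN2a evidence is carried but unused: the high-dose
definition names DN2b specifically. A comparison against the no-Notch
control can be added by the caller but is not part of the default
predicates.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with one promoter DHS per gene:

* **Profiles.** Per bin, counts are Poisson with rate
  background + amplitude × Gaussian bump, scaled by library size.
  Defaults: background 0.5 cuts/bin, amplitude 5 (10× background) at the
  window center, bump SD 200 bp, 3 replicates per stage, equal 10^6
  libraries. Planted classes set per-stage amplitudes: `low_I` 0 → 5 at
  DN1; `low_II` 5 → 10 at DN1 (height-change classes double from the
  accessible baseline, the same 2× condition exercised by the power
  checks); `high` 5 in DN2b only; `shift_only` moves the center by 300 bp;
  `null` is background everywhere.
* **Expression.** Negative-binomial counts (dispersion 0.1) with planted
  log2 fold-changes of 3 on the gate-relevant pairs, plus 5000 stage-flat
  background genes with log-normally spread means. The background
  transcriptome is not cosmetic: real stage transcriptomes have ~10k
  expressed genes, and without them the planted 8-fold effects would
  inflate library totals and shrink CPM fold-changes well below the
  planted value.
* **Promoters.** 2-kb sequences from a first-order Markov chain whose
  stationary base composition matches the GC target and whose stationary
  CpG observed/expected ratio matches the class target (defaults 0.43 for
  high-dose, 0.60 for low-dose genes — the magnitudes reported for real
  high- versus low-dose promoter sets — and 0.90, a typical
  high-CpG-promoter value, elsewhere). Within the validated parameter
  ranges this chain family always exists; the infeasibility guard only
  fires for out-of-range targets.

One master seed drives deterministic child streams per module, so fixtures
are byte-identical across runs. Replicate counts default to 3 for both
assays (within the 2–4 range typical of such designs).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level artifacts (mappability, adapter and
duplication structure), fragment-size effects, correlated biological
replicate variability beyond Poisson/NB noise, multi-promoter genes and
overlapping DHS windows (exercised separately in the interval tests), and
real promoter sequence context (CpG islands, repeats). The acceptance
quantities are properties of the method under this generative model, not
re-estimates of any genome-wide numbers.

## Numerical and design choices

* Coordinates are BED-style 0-based half-open on disk and 1-based closed
  in `GRanges` in memory; the DHS midpoint is `floor((start + end)/2)` of
  the BED interval, and promoter windows `[TSS − 1 kb, TSS + 1 kb)` are
  half-open at the right edge and strand-independent.
* Multi-TSS genes collapse to the 5′-most TSS of their transcripts — a
  stated convention, one of several defensible ones.
* Overlapping bedGraph lines are rejected, not summed: in binned fixture
  data, overlap is more likely a bug than a dialect.
* Permutation ties count as ≥ (conservative); exhaustive enumeration is
  used whenever the assignment count is within `max_perms`, Monte-Carlo
  with the add-one estimator otherwise.
* Undefined CpG ratios (no C or no G) are excluded from means and tests
  with a warning rather than coerced to 0, which would bias group means
  downward. `N` bases count toward sequence length but break
  dinucleotides. The Mann–Whitney test is two-sided by default (the
  conservative choice); exact when both groups total ≤ 16 without ties.
* The pipeline's default score for p-values is the unsmoothed, more
  robust `dnun`; `kn` is computed and reported for every region either
  way.

## Problem sizes and runtime

The shipped checks use 1000 null regions for type-I calibration, 500
regions per alternative for power, and a 500-region / 20-genes-per-class
fixture for end-to-end recovery — sizes at which the Monte-Carlo error of
the measured rates is a few percent and a full run takes well under a
minute on one core. These are the package's chosen study sizes for
reproducible desk-scale verification; the method itself is linear in
regions × assignments × bins.

## Known limitations

* The two scores are a stated reconstruction of this family of
  kernel-based two-sample profile tests; bit-compatibility with any
  particular implementation is a non-goal — the contract is qualitative
  behavior (sensitivity to peak/no-peak, height, shift;
  heteroscedasticity robustness; calibrated type-I error).
* The pooled Gamma tail extrapolates beyond the permutation support;
  its far-tail accuracy is unverifiable by construction at these
  replicate counts and is validated only through the calibration and
  recovery simulations above.
* Power against *height-only* changes at desk-scale sequencing depth is
  the weakest link: a 2× height change at 10× background is detected
  essentially always at α = 0.05 but only ~70–100% of the time at the
  Bonferroni-adjusted threshold over 500 regions, so `low_II` recall
  fluctuates accordingly. At real library depths (tens of millions of
  reads) the same relative change is overwhelming.
* Genome-scale performance (170k+ regions) and peak calling are out of
  scope; regions are taken as given.
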