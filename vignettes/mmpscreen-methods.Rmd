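---
title: "Methods: barcode screen deconvolution and MMP analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode screen deconvolution and MMP analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpscreen)
```

## Setting

Budding yeast mother cells lose mitochondrial membrane potential (MMP) as
they age. A common experimental design for finding genes that modulate this
decline is a pooled screen over the barcoded deletion collection: every
nonessential-gene deletion strain carries a unique 20-nt DNA barcode between
constant priming sequences, the pooled, aged population is FACS-sorted on a
two-channel MMP reporter ratio into low/medium/high thirds, and the barcode
composition of each sorted bin is read out by paired-end amplicon
sequencing. Around that screen sit several companion assays: single-cell
MMP-ratio trajectories from microfluidic lifespan microscopy, repeated-pass
flow cytometry of a potentiometric dye whose signal decays during
measurement, ratiometric plate-reader measurements of isolated mitochondria,
and elemental potassium measurements of aged cultures whose size
distributions mix old mothers with contaminating daughters.

`mmpscreen` implements the computational spine of this design: barcode
detection and catalog assignment, sorted-bin enrichment statistics,
trajectory summaries, the bulk-assay signal corrections, and the
Gaussian-mixture deconvolution of aged-culture potassium. Every input has a
seeded synthetic generator, so the full pipeline runs and is tested without
any external data.

## Barcode detection

Each read pair covers one amplicon: constant flank, variable barcode,
constant flank. Detection proceeds in three stages.

**Flank location.** Both flanks are located by a sliding-window Hamming
scan, allowing up to `max_mismatch = 2` mismatches on either side of the
barcode. The budget is per flank, `N` bases count as mismatches, and indels
are not modeled at this stage (they are absorbed by the similarity matching
below). Among admissible placements the pair with the fewest total
mismatches wins; ties resolve leftmost. Antisense mates are
reverse-complemented (qualities reversed) before the scan so both mates are
processed in sense orientation. The scan is implemented in C++ because it
is the per-read hot loop.

**Pair reconciliation.** If both mates yield the same barcode, or only one
yields a barcode, that sequence is used. If both yield barcodes of equal
length that differ, the per-position base with the higher Phred score is
taken; a Phred tie keeps the sense base (deterministic). Unequal-length
conflicts have no per-base merge, so the mate with fewer total flank
mismatches wins, with mean barcode quality as the tiebreak.

**Cosine assignment.** The reconciled barcode and each catalog barcode are
embedded as k-mer count vectors and compared by cosine similarity
$\cos(b, c) = \langle b, c\rangle / (\lVert b\rVert\,\lVert c\rVert)$.
The highest-scoring catalog entry is the match and the score doubles as the
confidence; calls below `min_score = 0.8` or with tied maxima (within
1e-12) are rejected. The feature space is a package choice: the default is
k = 3 counts because a single substitution in a 20-mer disturbs at most
three of its eighteen 3-mers, leaving a score of 15/18 ≈ 0.833 — above the
0.8 threshold, so the threshold is conservative for single errors. At k = 4
the same single error would drop the score to ≈ 0.765 and be rejected.
`k` is exposed as a parameter. Matching needs no fixed edit-distance budget
and tolerates errors in the catalog itself.

## Sorted-bin enrichment

Counts are tabulated one increment per passing, unambiguous call, rows
zero-filled over the catalog. Technical replicates are pooled by summation.
Per strain, with pooled counts $c_{hi}, c_{lo}$, library sizes
$N_{hi}, N_{lo}$ and $S$ strains:

* log2 fold change
  $\log_2\frac{c_{hi}+p}{N_{hi}+Sp} - \log_2\frac{c_{lo}+p}{N_{lo}+Sp}$
  with pseudocount $p = 0.5$ (standard half-integer correction; keeps
  zero-count fold changes finite);
* a conditional exact two-sided binomial test of $c_{hi}$ out of
  $c_{hi}+c_{lo}$ against $p_0 = N_{hi}/(N_{hi}+N_{lo})$, two-sided by the
  minimal-likelihood rule (outcomes no more probable than the observed one);
* Benjamini–Hochberg adjustment.

The exact test is a deliberate, documented substitution for a
negative-binomial shrinkage fit: the screen usage here needs a ranking with
calibrated type-I error, and a self-contained exact test provides that
without dispersion modeling. It is *not* equivalent to a shrinkage model:
it ignores between-replicate overdispersion (replicates are summed), so on
real data with strong replicate effects its p-values would be optimistic.
It is also conservative at finite counts, as all exact tests are: at the
default simulated depth (~850 pooled counts per strain) its attained size
at the 0.05 level is ≈ 0.046 rather than 0.050.

Ranking is by ascending q, then descending log2FC, then strain id — a total
order, so selections are reproducible under permutation.

**Deming regression.** Cross-experiment concordance of per-strain
enrichments compares two quantities that both carry error, so ordinary
least squares (which attributes all error to y) would attenuate the slope.
The errors-in-variables fit minimizes weighted perpendicular residuals with
variance ratio $\lambda$ (default 1) and has the closed form
$\hat\beta = \frac{s_{yy} - \lambda s_{xx} + \sqrt{(s_{yy}-\lambda
s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}}$. At $\lambda = 1$ the fit is
axis-symmetric (swapping axes inverts the slope); as $\lambda \to \infty$
it approaches OLS. Degenerate inputs (zero covariance with balanced or
y-dominant variances) fail explicitly rather than returning an arbitrary
orientation.

## Trajectory analytics

Trajectories are tidy tables: one row per fluorescence sample per mother
cell, with time (h), cumulative division count, the MMP-sensitive and
MMP-insensitive signals, and death/censor status. Filtering retains cells
that start at time 0, stop before the 300th sample on the acquisition grid
(late event calls are unreliable), and keep both signals strictly above 50
arbitrary units throughout; removal counts per criterion are reported. The
"timepoint 300" rule is a bound on the number of grid samples, exposed as a
parameter because the grid spacing is configuration-dependent.

The MMP ratio is the elementwise quotient of the two channels; mean
trajectories are computed on per-cell mean-centered ratios (each series
divided by its own mean, so the centered mean is exactly 1), binned along
time or divisions with two-SEM bands computed across cells (cells are
averaged within a bin first).

The early-life mean is the raw ratio averaged over samples at 0–5 divisions
inclusive. Raw, not centered: centering by the lifetime mean would leak
lifespan information into the predictor. Its Pearson correlation with
divisions at death (dead cells only) is the screen's headline single-cell
statistic. The windowed summary (default 21.5–26.5 h, the window for
"24-h-old" cells) reports the group mean of log10 ratio with a
nonparametric bootstrap CI over cells (1,000 resamples, seeded); the
bootstrap substitutes for mixed-effects genotype contrasts, which are out
of scope here.

## Bulk signal corrections

**Decay correction.** Repeated flow passes over the same stained samples
decay exponentially (dye export), so `fit_decay()` fits
$\log(\text{signal}) \sim t$ by least squares — a closed-form, deterministic
estimator of the rate constant — and reports the corrected signal as the
fitted value at $t = 0$. Pooled mode shares one rate within a
strain-by-experiment group with per-sample intercepts, matching the
sets-of-samples design. Exactly exponential input is recovered to machine
precision; at 1% multiplicative noise and 5 passes the rate is recovered
within 2% on average.

**Plate ratio.** For paired signal/background wells read at two
excitations: per-wavelength background means are subtracted, the 572/546
ratio is formed per timepoint, and timepoints are averaged. Timepoints with
non-positive denominators are flagged and excluded, never silently used.

**Mass adjustment.** The MMP-insensitive channel tracks mitochondrial mass.
A mutant's fractional change $d = \text{MMP}_i^{mut}/\text{MMP}_i^{wt} - 1$
rescales its MMP-sensitive estimate. The printed source formula multiplies
by $-(1+d)$; a negative multiplier would flip the sign of a fluorescence
quantity, so this package treats the minus sign as a typographical slip and
multiplies by $(1+d)$ by default. Because "normalized to mass" could also
be read as division, `direction = "divide"` is provided; the choice is an
explicit argument, never silent.

**Mitochondrial OCR** is the difference of phase means before and after
antimycin A.

## Potassium deconvolution

Aged cultures mix old mothers with newly budded daughters. The diameter
distribution is modeled as a three-component Gaussian mixture fit by EM
(univariate, weighted means/variances in the M step), with:

* k-means++-style seeded initialization and 10 random restarts, best
  log-likelihood kept;
* convergence at a relative log-likelihood change below 1e-8, cap 1,000
  iterations;
* a variance floor of 1e-4 µm², applied and flagged rather than allowed to
  collapse a component onto a point;
* components relabeled by ascending mean, so results are invariant to
  initialization order; the smallest-mean component is the daughter class.

The per-iteration log-likelihood trace is retained; EM guarantees it is
non-decreasing and the tests assert that. All EM settings are exposed
because no canonical values exist for this assay; an off-the-shelf mixture
implementation (mclust) is used in the test suite as an independent
cross-check of the fitted solution, never as the implementation. Whether to
fit diameters or volumes is an open choice; diameters are used, matching
the instrument's native output.

Counts are apportioned to classes by fitted weights (per-class counts are
not observed). Class mean volumes use the sphere of the component's mean
diameter, $\pi/6\,\bar d^3$, matching the young-cell convention; this
underestimates $E[\pi/6\,d^3]$ by the Jensen gap ($3\bar d\sigma^2\pi/6$
for Gaussian diameters, ~1–3% at the default parameters), and a
moment-correct mode is available. Old-cell potassium is bounded two ways
from the blank-subtracted total $K$:

* point estimate, daughters assumed at the young-culture concentration
  $c_y$: $(K - n_d \bar V_d c_y) / (n_o \bar V_o)$;
* maximum upper bound, daughters assumed empty: $K / (n_o \bar V_o)$.

A negative point estimate (assumed $c_y$ overexplains the measured total)
is reported with a warning, never clipped — the sign is diagnostic.

## What the generators emulate — and what they do not

* **Screen** (`make_catalog()`, `simulate_screen()`): barcodes drawn
  uniformly with a minimum pairwise Hamming distance of 5 (bounded
  rejection sampling); strain abundances log-normal (sd 0.5) to emulate
  pool skew; per-strain log MMP ratio Gaussian with unit sd, hit strains
  shifted by `hit_effect` sd; cells sorted at the tertiles of the pooled
  mixture distribution (the cutpoints are roots of the mixture CDF); bin
  counts multinomial at `read_depth = 1e6` per bin per replicate — the
  depth and abundance model are stand-ins, since no values are published
  for this design; reads carry per-base substitution errors, occasional
  2-substitution flank corruptions, and appended uniform-random junk pairs.
  Not modeled: indel sequencing errors, platform quality profiles, PCR
  chimeras. Perfect recovery on error-free reads therefore shows the
  algorithm's correctness, not its robustness to indels.
* **Trajectories** (`simulate_trajectories()`): division count advances
  deterministically (one division per 1.5 h) on a 2-h sampling grid —
  timing realism is irrelevant to the in-scope statistics, which depend
  only on counts. MMP_s declines multiplicatively per division
  (5%/division), MMP_i is constant, both with log-normal measurement noise
  (sd 0.1). Lifespans are Gaussian (mean 25, sd 8 divisions, floored at 6)
  with a latent score mixing the cell's realized early-life mean ratio and
  independent noise, so the planted early-MMP/lifespan correlation (default
  0.55) is exact in the latent scale and attenuated only negligibly by
  rounding to whole divisions.
* **Decay** (`simulate_decay()`): exact exponential decay with
  multiplicative mean-zero noise of a given CV.
* **Sizes** (`simulate_sizes()`): three Gaussian diameter classes (defaults
  3 / 5 / 6.5 µm, sd 0.3, weights 0.5 / 0.3 / 0.2 — heavy daughter
  contamination); negative draws rejected and counted; potassium 200 mM in
  daughters, 150 mM in old cells. Real Coulter output is binned and the
  real classes are not exactly Gaussian; passing recovery tests shows the
  estimator inverts its own model, not that three Gaussians are the right
  model for any particular culture.

Every generator is a pure function of its config, including the seed, and
always emits its truth table; recovery tests compare against the emitted
truth, never against re-derived values.

## Problem sizes and numerical conventions

The test-suite and acceptance-script runs use: 51k read pairs for the
end-to-end screen check; 14,100 strain-draws (3 × 4,700) for null
calibration; 10,000 cells for the correlation recovery; 100 seeds for decay
recovery; 50,000 diameters for mixture recovery. These sizes give
Monte-Carlo error comfortably inside each stated tolerance while keeping a
full run in tens of seconds.

Conventions: Phred+33 qualities; 0-based half-open barcode intervals;
1 µm³ = 1 fL; concentrations in mM (1 mM ≡ 1e-18 mol/fL); ties broken
deterministically everywhere (leftmost window, sense base, strain id).

## Known limitations

* The exact enrichment test ignores replicate overdispersion; on real data
  prefer it for ranking, not for literal error rates.
* Cosine k-mer matching is orientation- and composition-based; two
  barcodes with identical k-mer multisets are indistinguishable (tied calls
  are dropped as ambiguous rather than guessed).
* The mixture deconvolution assumes exactly three classes and apportions
  counts by fitted weights; gross departures (e.g. bimodal old-mother
  sizes) bias both potassium bounds.
* Censored trajectories are excluded from the lifespan correlation rather
  than modeled; survival-model integration is deliberately out of scope.
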