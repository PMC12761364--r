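---
title: "Image-based QSAR for congeneric inhibitor series: models, validation and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based QSAR for congeneric inhibitor series: models, validation and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miaqsar)
```

## The method

Multivariate image analysis QSAR (MIA-QSAR) builds regression descriptors
from *drawings*: every compound of a congeneric series is sketched on a
shared 2D template so that the common core occupies identical coordinates,
the sketch is rasterised into a fixed-size pixel image, and the unfolded
pixel intensities become the descriptor block **X**. Because the core pixels
are identical across compounds, all descriptor variance comes from the
substituents — the chemistry that actually changes along the series. The
response block **y** holds inhibitory activities as pKi = −log10(Ki in
mol/L).

In the augmented ("property-weighted") variant implemented here, the atom
disks are not binary: each atom is painted as a filled disk of radius
proportional to its van der Waals radius, with a fill intensity encoding an
atomic property. Three property channels are modelled in parallel —
Pauling electronegativity, Bondi van der Waals radius, and their ratio
r_vdW/ε — yielding three parallel models whose predictions are averaged
when candidates are scored, with the spread across channels as an error
bar.

The regression engine is centred single-response PLS fitted by NIPALS.
Latent variables are extracted with initial weight `X'y`, so the algorithm
is deterministic; the number of components A is chosen as the minimiser of
the leave-one-out RMSECV, with ties broken toward smaller A.

## Canvas, intensity mapping and rasterisation choices

* **Canvas**: 432 × 300 pixels, intensities on the summed-RGB scale 0–765,
  background 765 (white). These are the conventional descriptor-image
  dimensions for this method; the canvas is a `canvas_spec` object and all
  sketches of one dataset must share one spec.
* **Geometry**: default 8 px per template unit with the template origin at
  canvas position (200, 150). The bundled scaffold plus the largest
  substituents then occupy roughly columns 150–270 and rows 100–200,
  comfortably inside the canvas; an atom whose disk would cross the border
  is a hard error, never clipped.
* **Intensity mapping**: the literature does not disclose a unique mapping
  from atomic property to pixel value, and any strictly monotone injective
  mapping carries the same information into a PLS model. We use
  `value = 765·(1 − prop/prop_max)` with `prop_max` the channel maximum of
  the element table, so heavier/more electronegative atoms paint darker
  disks; `prop_max` is an argument for users who prefer another anchor.
* **Disk radius** is `scale · r_vdW` for every channel — the channel
  affects only intensity, so the three channels share pixel geometry and
  their kept-pixel sets are directly comparable.
* **Determinism**: no anti-aliasing; pixel membership is exact integer
  Euclidean distance, bonds are 1-px lines, and overlaps resolve by
  painter's order (bonds first, then atoms in file order). Images are
  bit-reproducible, which the pruning step exploits: a pixel is dropped
  only when it is *exactly* constant across all samples.
* **Element properties**: Pauling electronegativities and Bondi radii for
  H, C, N, O, F, P, S, Cl, Br ship as a CSV; the compilation used by the
  original descriptor software is not documented, so the table is
  user-replaceable (`load_property_table(path)`), and an element missing
  from the table is an error rather than a silent default.

## The validation battery

`validate_channel()` reproduces the full statistic set that this family of
QSAR studies reports, with the cutoffs evaluated on the cross-channel
average (`channel_summary()`): r² ≥ 0.6, c-r²p ≥ 0.5, q² ≥ 0.5,
r²pred ≥ 0.5, average r²m ≥ 0.5, Δr²m < 0.2, CCC ≥ 0.8.

* **Calibration**: r² = 1 − SSres/SStot and RMSEC = √(SSres/n).
* **Leave-one-out**: every sample predicted by a model refitted without it
  at the same A; q² = 1 − PRESS/SStot.
* **Y-randomization** (default 50 permutations, seeded): the response is
  permuted and the model refitted; the penalty statistic is
  c-r²p = r·√(r² − mean r²rand). The permutation count is a default of this
  package — source studies rarely state theirs.
* **Bootstrap external validation**: `floor(0.25·n)` samples held out in
  each of 10 cycles, component count re-selected on the calibration
  remainder, then RMSEP, r²pred, Roy's metrics and Lin's CCC computed on
  the holdout. Two conventions are worth making explicit because the
  literature often leaves them implicit: the r²pred denominator uses the
  *training-set* mean (the Golbraikh–Tropsha convention for external
  sets), and r₀² inside Roy's r²m comes from the through-origin fit of
  observed on predicted. CCC uses population (1/n) moments, Pearson r the
  sample convention. The "best" cycle is defined as the one passing the
  most cutoffs, ties broken by the higher mean of r²pred, avg r²m and CCC —
  published studies describe this selection only loosely ("highest average
  values above 0.5"), so the rule is stated here and kept configurable.
* **Williams plot**: leverage in score space,
  h = 1/n + t'(T'T)⁻¹t (Σh = A + 1), against studentized residuals
  e/(RMSE·√(1−h)). The residual threshold is 2.5 — reports of this method
  phrase the threshold ambiguously, and we read it as a cutoff on the
  absolute studentized residual. The leverage warning limit is the
  customary 3(A+1)/n. Flagged samples are *reported, never auto-removed*:
  outlier removal in the source literature is a judgement call made after
  inspecting the plot, so refitting without flagged samples is left to the
  user.
* **Fractional component counts**: the battery reports `pls_comp` as the
  mean of the per-cycle re-selected A over bootstrap cycles, which is why a
  published value like 6.60 can be fractional while every per-fit A is an
  integer.

All resampling refits run in Gram-matrix space: with n samples and tens of
thousands of pixel descriptors, n ≪ p, and single-response NIPALS touches
X only through XX′ and X′y. Train/holdout predictions are therefore exact
functions of the n × n Gram matrix; the test suite enforces equality with
explicit feature-space refits to 1e-8. This makes the full battery
(LOO scan, 50 permutations, 10 bootstrap cycles with internal LOO
re-selection) run in well under a second per channel at n = 59.

## Candidate design and docking arithmetic

Interpretation maps — VIP and regression-coefficient vectors refolded onto
the canvas — show *where* activity-relevant variance lives; reading
substituent preferences off them mixes statistical evidence with chemical
reasoning, so the shortlist of favoured substituents per position is user
input, not automated. `enumerate_candidates()` expands the shortlists into
a deduplicated Cartesian product on the training template (the descriptors
are alignment-sensitive by construction, so candidates are stamped on the
same grid), `predict_candidates()` scores them per channel and aggregates
mean ± sd, and `rank_vs_reference()` orders them against a reference
inhibitor such as mesotrione (pKi 7.699).

The docking-evaluation stage implements the arithmetic only (no docking
engine is run):

* **Docking Accuracy**: DA = f_l + 0.5·(f_h − f_l) with f_l, f_h the
  cumulative fractions of redocked poses within l = 2 Å and h = 3 Å
  (closed intervals — a pose at exactly 2 Å counts in full). Published
  typesettings of this equation are sometimes garbled; this form is the
  one consistent with DA ∈ [0, 1] and with the standard worked example
  (83 poses ≤ 2 Å and 17 in (2, 3] of 100 giving DA = 0.915).
* **Energy decomposition totals**: ΔG_bind = electrostatic + vdW +
  torsional, excluding the ligand internal term; recomputed totals are
  checked against reported ones at 0.015 kcal/mol, i.e. just beyond the
  rounding radius of values printed to two decimals.
* **Activity–energy regression**: OLS of the three per-channel predicted
  activities on binding energy, with a replicate-based lack-of-fit F test
  (pure error from the three replicates at each energy) and studentized
  residuals from the two-parameter line.

## The synthetic generator

No public dataset accompanies this class of study — the sketches are
hand-drawn and the descriptor software's intensity mapping is undisclosed —
so absolute published statistics are not desk-reproducible. The package
therefore ships a generator whose output exercises every pipeline stage
with *known* ground truth, and the package's quantitative claims are made
on that surface.

`generator_config()` defaults define the study conditions: 59 compounds on
a triketone-like scaffold; four ring positions each drawing uniformly from
a four-substituent pool (H, methyl, ethyl, methoxy, halogens); additive
planted effects in [−0.75, +0.8] pKi units with the strongest spread at R3
(methoxy +0.8, chloro +0.55), deleterious alkyls at R1, moderate halogens
at R2 and methyl at R4; baseline pKi 7.0 so activities land in the 6–8
range typical for such series; Gaussian noise of 0.2 pKi units. The
additive-effects model is deliberate: pixel descriptors are themselves
additive indicators of substituent presence, so the planted truth is
exactly representable and recovery is a meaningful test of the estimator
rather than of model misspecification.

What the generator does *not* emulate: correlated substituent usage across
positions (real series are designed, not sampled uniformly), non-additive
substituent interactions, activity cliffs, measurement-protocol shifts
between merged datasets, and drawing noise (jitter is available but
defaults to 0). Passing the recovery surface therefore demonstrates that
the estimator and battery work as specified — not that any real series
satisfies the additivity assumption.

Two constructed fixtures support specific checks. The response-outlier
scenario plants a 5σ shift on one compound over a clean background whose
noise is drawn from a ±2σ truncated normal (`noise_cap_sd = 2`), and the
realisation is additionally required to keep every clean studentized
residual at or below 2 — the scenario is defined that way, as "one gross
outlier over an unremarkable background" — before asserting that the
Williams analysis flags exactly the planted sample at threshold 2.5.
Pose-RMSD and energy-decomposition fixtures plant exact band counts and
recorded total perturbations.

## Numerical choices and degenerate inputs

* NIPALS tolerance 1e-10, inner-loop cap 500 (single-y NIPALS converges in
  one pass per component; the cap guards degenerate input). Requesting
  more components than the deflated X supports raises an error naming the
  attainable maximum.
* y centred, X centred but not autoscaled (pixels share one physical
  scale); autoscaling is available as a flag.
* Zero-variance pruning is exact (bitwise constant columns), so adding a
  constant column never changes a fit.
* Constant response → calibration error (SStot = 0); leverage 1 → Williams
  error (exact interpolation); both zero-variance inputs → CCC error; zero
  pure error with nonzero lack-of-fit → F = ∞ with a warning.
* Alignment tolerance defaults to 1e-3 template units: sketches are copies
  of a template, so deviations indicate a data error, not noise to be
  absorbed.
* All randomness (generator, permutations, holdouts) flows from explicit
  integer seeds; pipeline stage seeds are fixed offsets of the master
  seed, and a rerun of `run_pipeline()` with the same config is
  bit-identical.

## Problem sizes

The shipped tests and the quantitative recovery checks run the full
battery (LOO component scan, 50-permutation Y-randomization, 10-cycle
bootstrap with internal re-selection) on 59-compound datasets across 10
seeds and three channels, plus brute-force oracle refits on small dense
instances (n ≤ 24). These sizes match the study conditions the package
models and keep a complete run in the low minutes on a single core.

## Known limitations

* The intensity mapping and radius convention are *a* faithful member of
  the family of augmented-MIA mappings, not a reverse-engineered copy of
  any proprietary implementation; absolute statistics from studies using
  other mappings will differ even on identical sketches.
* Pose RMSD assumes matched atom order and no symmetry correction
  (automorphism-aware matching is out of scope).
* Aromaticity is represented only through bond orders in the file formats;
  no perception is attempted.
* The design stage enumerates and scores; it does not judge
  synthesizability or ADMET behaviour.
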