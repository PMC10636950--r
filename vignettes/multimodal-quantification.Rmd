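---
title: "Methods: multimodal quantification of tumor response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal quantification of tumor response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpq)
```

This vignette documents the models, conventions and numerical choices behind
`mpq`, and what the synthetic-data layer does and does not establish about
real data.

## The measurement models

### DCE-MRI enhancement kinetics

Contrast-enhanced breast MRI samples the T1-weighted signal before contrast
(S0) and at early (S1, ~2 min) and delayed (S2, ~8 min) phases. Two
voxel-wise semi-quantitative measures summarize the uptake curve:

* **Percent enhancement** $PE = (S_1 - S_0)/S_0$ — early uptake amplitude,
  a surrogate of lesion vascularity. Voxels with $S_0 \le 0$ have no valid
  normalization and are masked (`NaN`), never errors.
* **Signal enhancement ratio** $SER = (S_1 - S_0)/(S_2 - S_0)$ — the shape
  of the curve: $SER > 1$ means washout between the early and delayed
  phase, typical of malignant kinetics. The ratio is undefined where the
  delayed enhancement vanishes; voxels with
  $|S_2 - S_0| \le \varepsilon \cdot \max(S_0, 1)$ are masked, with
  $\varepsilon = 10^{-6}$ (a relative guard chosen well below any
  physiological enhancement, so it only catches genuine degeneracy).

Tumors are segmented in 3D by thresholding PE at 0.50, labeling
26-connected components, and keeping either the component containing a
user-supplied seed point or, by default, the largest component. Manual
lesion identification cannot be reproduced in software; the seed-point /
largest-component rule is its deterministic surrogate.

Per-lesion summary metrics:

* **Hotspot peaks** of PE and SER: the highest mean over a 3 × 3 voxel
  in-plane window lying entirely inside the tumor (and, for SER, entirely
  on SER-valid voxels). The window is in-plane — not 3 × 3 × 3 — because
  axial clinical acquisitions have anisotropic slice thickness, so an
  in-plane neighborhood is the only isotropic-ish "subregion" available.
  Windows straddling the boundary are excluded ("tumor subregion" means
  tumor voxels only); lesions too small for any full window fall back to
  the single-voxel maximum with a logged warning.
* **Functional tumor volume (FTV)**: voxel count with $PE \ge 0.50$ times
  the voxel volume, in cc.
* **Washout volume**: tumor-mask voxels with $SER \ge 1.1$, in cc. The
  threshold is evaluated *within* the segmented mask: this avoids counting
  vascular or background voxels and yields the testable invariant
  washout volume $\le$ FTV.
* **Longest dimension**: maximum pairwise physical distance between
  mask-voxel centers (computed on the mask's 6-connected boundary, which
  provably contains the diametral pair).

No inter-phase registration or smoothing is applied; the phases are assumed
voxel-aligned, and thresholds act on raw voxel values.

### DW-MRI: apparent diffusion coefficient

The diffusion signal is fit voxel-wise to the monoexponential model
$S(b) = S(0)\,e^{-b\,\mathrm{ADC}}$ at $b = 0, 100, 800$ s/mm². The default
fit is ordinary least squares on $\ln S$ — the conventional reading of a
"monoexponential fit", deterministic, and exactly invertible (it reduces to
the closed-form two-point solution when only two b-values are given, and
recovers a noiseless phantom to float precision). All three b-values enter
the fit by default; restricting to the 0/800 pair is a configuration
choice. A per-voxel nonlinear refinement exists behind
`method = "nonlinear"` for users who prefer amplitude-domain residuals.
Voxels with any non-positive signal are flagged invalid and excluded from
ROI means, with the exclusion count reported — never silently zeroed.

### Dynamic FDG-PET

SUV images are built from the dynamic series by duration-weighted averaging
of frames inside the 30–60 min window and normalizing by injected dose per
body weight, with tissue density taken as 1 g/mL; SUVmax is the hottest
voxel inside a ~1 cc spherical VOI. Tumor time-activity curves (TACs) are
per-frame VOI means at frame midtimes.

Kinetics use the irreversible two-tissue compartment model ($k_4 = 0$,
standard for FDG over 60 min):

$$C_T(t) = \frac{K_1\left(k_3 + k_2\,e^{-(k_2+k_3)t}\right)}{k_2+k_3}
  \circledast C_p(t) \;+\; v_b\,C_p(t)$$

with blood input $C_p$ from a left-ventricle VOI. The metabolic flux is the
macro-parameter $K_i = K_1 k_3/(k_2+k_3)$ (always recomputed from the
rates, so $K_i \le K_1$ holds by construction), and
$\mathrm{MRFDG} = K_i \cdot [\mathrm{Glucose}]$ with no lumped-constant
correction. Glucose units (mmol/L or mg/dL) are declared metadata; MRFDG is
reported in matching units and a unit mismatch is an error, never a silent
conversion. The blood-volume fraction $v_b$ defaults to 0 — the three-rate
model matches the printed parameter set — with fitting it available as an
option.

**Numerics.** The convolution is evaluated on a uniform fine grid (0.05 min)
using the exact solution for a piecewise-linear $C_p$ convolved with an
exponential (a linear recurrence, evaluated in C via `stats::filter`), then
averaged over each acquisition frame with trapezoidal weights. Against an
independent 10×-finer direct numerical convolution the frame-averaged curve
agrees to better than 0.1% (the test asserts 0.5%).

**Fitting.** Weighted nonlinear least squares with box constraints
($0 \le K_1 \le 2$ mL/min/g, $0 \le k_2 \le 5$, $0 \le k_3 \le 2$ min⁻¹),
weights `frame duration / max(activity, 5% of peak)` approximating count
statistics. Optimization runs 8 deterministic multistarts from a fixed
lattice of plausible rate values (`nlminb`, tight tolerances); the best
weighted residual sum wins, ties broken by the first start — no randomness
anywhere in fitting. A TAC that is identically zero returns a flagged
degenerate fit with $K_1 = 0$; failure of every start returns a flagged
non-convergence, never an exception. `nlminb`'s convergence codes are noisy
on noiseless data at tight tolerances, so a finite best objective counts as
converged. On noiseless curves the fit recovers $K_i$ to within $10^{-4}$
relative across a 27-point rate grid; under noise, $K_i$ and $K_1$ are
substantially better identified than $k_2$ and $k_3$ individually, which
trade off along the likelihood ridge.

## The statistics layer

Percent change from baseline, $100\,(x_t - x_0)/x_0$, is undefined (missing)
when the baseline is missing or zero; missingness propagates so that each
metric's analysis N follows from the data, with no imputation. The five
metabolism/perfusion ratios (MRFDG/peak PE, MRFDG/peak SER, MRFDG/K1,
SUVmax/peak PE, SUVmax/peak SER) go missing only where their own numerator
or denominator does.

The cohort grid mirrors the serial-biomarker design: baseline Spearman
correlations (average ranks on ties, two-sided t-approximate p); Wilcoxon
rank-sum comparisons of percent change between pathological responders
(residual cancer burden class 0/I) and non-responders (II/III, including
patients with metastases before surgery); univariate Cox proportional
hazards of RFS on percent change scaled to 5%-change units (Efron tie
handling — the modern default, and continuous RFS times make ties rare),
with Wald tests; and Kaplan–Meier curves split at the third quartile of
percent change compared by log-rank.

Design choices where the convention was genuinely open:

* **Multiplicity families.** Benjamini–Hochberg adjustment is applied
  within each (analysis type × timepoint) family — e.g. all 14 metrics'
  mid-treatment Wilcoxon p-values form one family. Pooling across
  timepoints or across test types are defensible alternatives; families
  are kept separate so that an informative timepoint is not penalized by
  an uninformative one, and the family id is recorded in every result row.
* **Quartile convention.** Q3 is computed by linear interpolation of order
  statistics (quantile type 7, the common statistical-software default).
* **Direction of the Q3 split.** Treatment changes are mostly negative, so
  patients with change $\le Q3$ are labelled the "larger decrease" group
  (75% of the cohort) and change $> Q3$ "smaller decrease"; both group
  labels are explicit in the output rather than an unlabeled dichotomy.
* **Degenerate inputs** (constant covariates, event-free cohorts, all-equal
  splits, monotone partial likelihood under perfect separation) yield
  flagged result rows, not exceptions, so one pathological metric cannot
  abort a cohort run.

All tests are two-sided at $\alpha = 0.05$. Wilcoxon p-values are exact for
combined $n \le 20$ without ties, otherwise normal-approximate with
continuity and tie correction.

## The synthetic-data layer

### Digital phantoms

`phantom_spec()` describes a spherical "tumor" in a uniform background on a
regular grid; membership is by physical distance ≤ radius, so the default
1 mm isotropic grid with a 5 mm radius gives the canonical 515-voxel digital
sphere. DCE phantoms are built by *inverting* the PE/SER definitions
($S_1 = S_0(1+PE)$, $S_2 = S_0 + (S_1-S_0)/SER$), DWI phantoms by evaluating
the monoexponential decay, and PET phantoms by evaluating the compartment
forward model per region — so noiseless phantoms are exact fixed points of
the corresponding estimators, which is the package's core correctness
property. Defaults (tumor PE 0.8 vs background 0.1, SER 1.3 vs 0.5, ADC
1.0 vs 2.0 × 10⁻³ mm²/s, K1/k2/k3 = 0.10/0.20/0.05 tumor vs
0.02/0.30/0.005 background) are typical breast-cancer versus fibroglandular
values from the FDG and breast-MRI literature — stand-ins, since per-patient
kinetic values are not published at the individual level.

The blood input function is a tri-exponential Feng-type curve,
$C_p(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
A_3 e^{-\lambda_3 t}$ past a 0.25 min arrival delay — smooth, non-negative,
peaking within the first two minutes, and analytically convenient for
oracle checks. Its coefficients are generator defaults, not claims about
any patient. Default dynamic framing is 17 frames over 60 min (4 × 0.5,
4 × 1, 2 × 2, 4 × 5, 3 × 10 min).

Two noise models are deliberately distinct:

* **Image-domain PET noise** (`make_pet_phantom`): Gaussian with variance
  proportional to activity / frame duration — a standard
  reconstruction-domain approximation of count statistics.
* **Curve-level noise for recovery studies** (`noisy_tac`): Gaussian with
  per-frame-relative SD ("5% noise" = each frame measured with 5% error),
  the conventional model for kinetic parameter-recovery simulations and the
  one under which $K_1$ and $K_i$ are recoverable to better than 5% median
  relative error. Peak-anchored or count-based scalings of the same nominal
  level put ~2.6× more noise on the early frames and push median $K_1$
  error to 7–9% regardless of weighting — an identifiability limit of the
  early transient, documented here so users scaling noise levels know the
  convention matters.

DWI noise is Gaussian or Rician (magnitude-image model
$\sqrt{(S+n_1)^2+n_2^2}$). All phantom randomness is fixed by the spec's
seed.

### Cohort simulation

`make_cohort()` draws the statistics layer's inputs directly rather than
through simulated images, so the two layers are unit-testable
independently. Group sizes default to 11 responders vs 24 non-responders —
the clinical study conditions. The responder flag is assigned first and
percent changes are drawn conditional on it, from group-specific normal
distributions whose means and SDs default to the published per-metric
values (`reference_change_effects()`). Baseline metric levels are log-normal with a
Gaussian copula imposing the observed modest correlations (ρ = 0.35 between
K1 and peak PE, ρ = 0.38 between MRFDG and ADC); follow-up raw values are
reconstructed from baseline and change so that `percent_change()` recovers
the drawn change exactly. RFS is exponential proportional-hazards with log
hazard linear in (percent change)/5 of one linked metric (default: MRFDG at
mid-treatment, log HR = log 1.04 per 5%, matching the published hazard
scale in `reference_hazard_ratios()`), centered at the cohort-mean change, with a
0.04/year baseline hazard and uniform 1–10 year administrative censoring —
roughly 20% events over a median 8-year follow-up, the clinical study's
event rate.

What the generator does **not** emulate: realistic anatomy and texture,
partial-volume and scanner physics, motion, registration error between
modalities, non-normal change distributions, informative censoring, or any
dependence structure among the 14 metrics' changes beyond group membership.
Passing tests therefore establish that the estimators and tests are correct
and calibrated *under the stated models* — not that the clinical effect
sizes themselves generalize.

## Problem sizes used in the validation suite

The shipped tests use deliberately small, fixed-seed problems chosen to make
every check sharp: 32 × 32 × 16 (1 mm) DCE/DWI phantoms and 12 × 12 × 9
(2 mm) PET phantoms; a 27-point noiseless rate grid and 50 noisy replicates
for kinetic recovery; 1000 voxels at SNR 50 for ADC bias; 1000 null cohorts
of n = 50 for type-I error and FDR calibration; 500 cohorts of n = 400 for
detection power and 150 cohorts of n = 300 for hazard-ratio recovery; and a
six-patient, three-timepoint end-to-end study whose outputs are checked to
be bit-identical across reruns (all numeric CSV output uses a pinned
`%.10g` format).

## Known limitations

* No pharmacokinetic (Tofts-type) DCE modeling: three-phase clinical
  sampling cannot support it, and the semi-quantitative PE/SER measures are
  the appropriate summary.
* No spatial registration between PET and MRI (supine vs prone positioning
  in practice); metrics are compared per lesion, not per voxel.
* Segmentation reproduces a thresholding rule, not expert judgment; in
  noisy backgrounds the largest-component default can latch onto spurious
  clusters, which the seed-point option avoids.
* $k_2$ and $k_3$ are reported but individually unstable under realistic
  noise; inference should rest on $K_1$ and $K_i$.
* Univariate survival modeling only — small event counts preclude
  multivariate adjustment, and the package deliberately does not offer it.
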