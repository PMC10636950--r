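# mpq — multimodal PET/MRI quantification of chemotherapy response

`mpq` is an R package for quantifying breast tumor biology from serial
multimodal imaging during neoadjuvant chemotherapy (NAC), and for the
longitudinal statistics that link imaging change to pathological response
and recurrence-free survival (RFS). It is aimed at quantitative-imaging
researchers who need a reproducible, testable implementation of the standard
serial-biomarker analysis: voxel-wise maps, per-lesion metrics, percent
changes, and a cohort-level statistical grid — plus a synthetic phantom and
cohort generator so every stage can be validated without clinical data.

## What it computes

**DCE-MRI enhancement kinetics.** From pre-contrast (S0), early
post-contrast (S1, 2 min) and delayed (S2, 8 min) T1-weighted volumes:

- percent enhancement `PE = (S1 − S0) / S0` and signal enhancement ratio
  `SER = (S1 − S0) / (S2 − S0)`, voxel-wise;
- 3D tumor segmentation at `PE ≥ 0.50`, with 26-connected component
  selection;
- hotspot peaks: the highest mean over an in-plane 3 × 3 voxel tumor
  subregion, for PE and SER;
- functional tumor volume (FTV, cc): total volume with `PE ≥ 0.50`;
  washout volume (cc): tumor volume with `SER ≥ 1.1`; longest dimension
  (mm).

**DW-MRI.** Voxel-wise monoexponential fit `S(b) = S(0)·exp(−b·ADC)` at
b = 0, 100, 800 s/mm² (log-linear least squares), and lesion ROI mean ADC.

**Dynamic FDG-PET.** Summed SUV images over 30–60 min post injection
(`SUV = C·weight/dose`, 1 g/mL tissue density), SUVmax within a ~1 cc
lesion VOI, and irreversible two-tissue-compartment kinetic modeling of the
tumor time-activity curve against a blood (left-ventricle) input function:
K1 (delivery, mL/min/g), k2 (efflux, 1/min), k3 (trapping, 1/min), the
metabolic flux

    Ki = (K1 · k3) / (k2 + k3),      MRFDG = Ki · [Glucose]

**Metabolism/perfusion mismatch.** The five ratios MRFDG/peak PE,
MRFDG/peak SER, MRFDG/K1, SUVmax/peak PE, SUVmax/peak SER.

**Cohort statistics.** Percent change from baseline at mid- and
post-treatment; Spearman correlations between baseline measures; Wilcoxon
rank-sum comparisons of RCB 0/I vs II/III responders; univariate Cox
proportional hazards on RFS (hazard ratio per 5% change, Wald tests);
Benjamini–Hochberg adjustment within each analysis-by-timepoint family;
Kaplan–Meier curves dichotomized at the third quartile of percent change
with log-rank tests.

## Worked example

Quantify a noisy digital phantom and fit its PET kinetics:

```r
library(mpq)

spec <- phantom_spec(noise_sd = 0.02, seed = 11)   # 5 mm tumor, 2% noise
ph   <- make_dce_phantom(spec)
pe   <- compute_pe_map(ph$s0, ph$s1)
ser  <- compute_ser_map(ph$s0, ph$s1, ph$s2)
mask <- segment_tumor(pe, threshold = 0.50)
mask
#> <tumor_mask> 515 voxels (0.515 cc), 1 component(s) found
hotspot_peak(pe, mask)                  # 0.845  (true tumor PE: 0.8)
hotspot_peak(ser, mask)                 # 1.353  (true tumor SER: 1.3)
functional_tumor_volume(pe, mask)       # 0.515 cc
washout_volume(ser, mask)               # 0.515 cc (all tumor SER > 1.1)
longest_dimension(mask)                 # 10 mm (5 mm radius sphere)

cp    <- simulate_input_function(input_function_spec())
ft    <- default_frame_timing()
truth <- two_tissue_params(0.1, 0.2, 0.05)          # Ki = 0.02
curve <- noisy_tac(simulate_tumor_tac(truth, cp, ft$start, ft$end),
                   0.05, seed = 2)
fit <- fit_two_tissue(curve, cp)
summary(fit)
#> Two-tissue compartment fit (irreversible, k4 = 0)
#>       k1       k2       k3       vb       ki
#> 0.100190 0.188040 0.044850 0.000000 0.019294
#> frames: 17, weighted RSS: 29.77, relative RMSE: 0.0369
phys <- patient_physiology(370, 70, plasma_glucose = 5.0)
metabolic_rate_fdg(fit, phys)           # 0.0965 (true MRFDG: 0.1)
```

The fitted K1 is within 0.2% of truth and Ki within 4% despite 5% frame
noise — the macro-parameter Ki is far better identified than k2 and k3
individually.

Simulate a 35-patient cohort with the reference effect sizes and run the
full analysis grid:

```r
co  <- make_cohort(cohort_effect_spec(), seed = 1)  # 11 vs 24 patients
run_full_analysis(co)
#> Multimodal response analysis: 35 patients
#>   metrics: k1, mrfdg, suvmax, adc, peak_pe, peak_ser, ftv, ...
#>   wilcoxon_mid: 2/14 p < 0.05 (k1, ftv)
#>   wilcoxon_post: 5/14 p < 0.05 (adc, peak_ser, longest_dimension,
#>     mrfdg_peak_ser, suvmax_peak_pe); BH-significant: peak_ser
#>   cox_mid: 0/14 p < 0.05 (none)
#>   cox_post: 0/14 p < 0.05 (none)
#>   log-rank (Q3 split, mid): k1 p=0.220; mrfdg p=0.270; ...
```

At n = 35 with 14 metrics, single-seed significance patterns vary
substantially — exactly the small-sample behavior the simulation layer is
meant to expose. End-to-end runs from images to report go through
`quantify_patient()` and `run_study()`.

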