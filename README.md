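# mbDWI

Multi-b-value diffusion-weighted MRI (DWI) model fitting and diagnostic
statistics, built for the problem of separating **tumour progression** from
**pseudoprogression** in glioblastoma follow-up imaging. After
chemoradiation, both present as enlarging enhancing lesions on conventional
MRI; quantitative diffusion parameters can tell them apart because
progressing tumour is densely cellular (restricted, heterogeneous diffusion,
rich microvasculature) while pseudoprogression is dominated by treatment
necrosis and oedema.

The package is aimed at imaging scientists who want the whole chain —
voxel-wise model inversion, ROI measurement protocol, and the diagnostic
statistics — as tested, scriptable code, together with a digital phantom
cohort so every stage runs and is verifiable without patient data.

## Models

For signal `S(b)` at diffusion weighting `b` (s/mm²), normalised by `S(0)`:

- **Monoexponential**: `S(b)/S(0) = exp(−b·ADC)`, with the conventional
  two-point ADC from b = 0 and 1000 s/mm².
- **Biexponential (IVIM)**:
  `S(b)/S(0) = (1−f)·exp(−b·D) + f·exp(−b·(D* + D))`, separating tissue
  diffusion `D` from capillary pseudodiffusion `D*` with perfusion
  fraction `f`. Fitted by segmented estimation (high-b log-linear fit for
  `D` and `f`, bounded 1-D search for `D*`) followed by bounded
  Levenberg–Marquardt refinement.
- **Stretched-exponential**: `S(b)/S(0) = exp(−(b·DDC)^α)`, with
  distributed diffusion coefficient `DDC` and heterogeneity index
  `α ∈ (0, 1]` (α = 1 recovers monoexponential decay).

Default acquisition is the 12-point scheme
0, 10, 20, 40, 60, 70, 80, 100, 200, 400, 800, 1000 s/mm². Diffusion
coefficients are stored in mm²/s and displayed ×10⁻³.

The statistics layer reproduces the full clinical analysis per parameter:
Lilliefors normality screening, pooled independent-samples t test, ICC(2,1)
and Bland–Altman interobserver agreement, empirical ROC with
Youden-optimal cutoff, DeLong 95% CIs and pairwise DeLong AUC comparisons.

## Worked example

```r
library(mbDWI)

# simulate the two-group phantom cohort (22 progression / 18
# pseudoprogression lesions, SNR 50), fit all models at every lesion
# voxel, apply the ROI protocol with two readers, run the statistics
run <- runPipeline(seed = 7)
run$report
```

```
DiagnosticReport: progression (n = 22 ) vs pseudoprogression (n = 18 )

Group comparison (diffusion coefficients x10^-3 mm^2/s):
  parameter mean_pos  sd_pos mean_neg  sd_neg    t        p   icc
1       adc    1.241  0.1897    1.744  0.2006 8.14 7.54e-10 0.999
2         d    0.988  0.1850    1.536  0.2039 8.91 7.71e-11 0.999
3    d_star   44.543 16.0156   30.621 21.0939 2.37 2.28e-02 0.902
4         f    0.244  0.0539    0.193  0.0346 3.44 1.41e-03 0.996
5       ddc    1.427  0.4135    2.043  0.2677 5.45 3.25e-06 1.000
6     alpha    0.520  0.0819    0.737  0.0694 8.94 7.03e-11 0.999

Diagnostic performance:
  parameter   auc ci_low ci_high cutoff youden sensitivity specificity
1       adc 0.982  0.952   1.000  1.482  0.909       0.909       1.000
2         d 0.992  0.977   1.000  1.259  0.909       0.909       1.000
3    d_star 0.790  0.641   0.940 28.817  0.530       0.864       0.667
4         f 0.785  0.640   0.931  0.218  0.505       0.727       0.778
5       ddc 0.902  0.799   1.000  1.721  0.763       0.818       0.944
6     alpha 0.972  0.917   1.000  0.634  0.955       0.955       1.000
```

Reading this: progression lesions show *lower* ADC, D, DDC and α (denser,
more heterogeneous tissue) and *higher* D* and f (more microvascular flow)
than pseudoprogression; every parameter separates the groups (p < 0.05),
and α and the ADC/D pair are the strongest discriminators — the same
ordering the clinical literature reports. `cutoff` is the Youden-optimal
threshold in display units; `direction` (in `performanceTable()`) records
whether high or low values call progression.

Lower-level entry points: `fitADC()`, `fitBiexp()`, `fitStretched()` for
single curves, `fitVolume()` for 4D NIfTI volumes, `measureLesion()` /
`buildLesionTable()` for the ROI protocol, `buildReport()` for the
statistics, and `summaryTTest()` for group comparison straight from
published n/mean/SD summaries. A command-line front end
(`inst/scripts/mbdwi`) wraps the disk-backed stages
(`simulate` / `fit` / `roi` / `report` / `run-all`).

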