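# renogram

Split renal function and drainage-curve analysis for comparative dynamic
renography.

In children with obstructive congenital anomalies of the kidney and
urinary tract (CAKUT), two questions drive surgical decisions: how is
function split between the two kidneys (split renal function, SRF), and
does each collecting system drain? Diuretic renal scintigraphy (DRS) is
the gold standard for both; functional MR urography (fMRU) answers them
without ionizing radiation and adds high-resolution anatomy. `renogram`
implements the full analysis chain needed to compare the two modalities —
and a paired digital phantom with known ground truth to validate it —
for methodologists and imaging scientists working on renography pipelines.

## What it computes

**Split renal function.** From background-corrected time–activity curves
over an uptake window preceding collecting-system outflow:

- *AUC method*: SRF_L = 100·A_L/(A_L + A_R) from trapezoid integrals of
  the two renal curves.
- *Rutland–Patlak method*: ordinary least squares on the linearized
  irreversible-uptake model
  Q(t)/P(t) = K·(∫₀ᵗP dτ)/P(t) + V₀,
  where P is the aortic (fMRU) or cardiac (DRS) input curve; the uptake
  constant K gives SRF_L = 100·K_L/(K_L + K_R).
- *Volumetric SRF*: per-unit-volume indices k weighted by segmented
  parenchymal volumes, vSRF_L = 100·V_L k_L/(V_L k_L + V_R k_R).

**Drainage.** Whole kidney-plus-pelvis curves are classified into the
three canonical patterns — *normal* (post-peak decline), *borderline*
(post-peak plateau), *accumulation* (ever-increasing) — and quantified by
Tmax, NORA (late activity / 1–2-min activity) and renal output efficiency
(ROE, the percentage of modelled input that has drained by study end).

**Method agreement.** Bland–Altman limits of agreement
(mean ± 1.96·SD with confidence intervals), Cohen's kappa with the
standard interpretation bands, contingency-table diagnostic effectiveness
and misclassification, and Spearman correlation.

**Digital phantom.** `simulate_study()` generates paired studies of the
same virtual patient: a 4D fMRU series (ellipsoidal kidneys, pelvic
reservoirs and an aortic tube on a labelled voxel grid, dual 5 s/30 s
frame rate, Gaussian noise) and a 2D posterior-projection DRS series
(Poisson counts, cardiac blood-pool ROI, C-shaped perirenal background),
both driven by a gamma-variate aortic bolus and a two-compartment
parenchyma/pelvis model with pattern-specific outflow.

## Worked example

```r
library(renogram)

spec <- spec_for_srf(65, volume_left = 100, volume_right = 130,
                     drainage_pattern_left = "accumulation",
                     drainage_pattern_right = "normal", seed = 7)
mru <- analyze_mru_study(simulate_study(spec, "mru"))
drs <- analyze_drs_study(simulate_study(spec, "drs"))
round(rbind(fMRU_volumetric   = mru$srf$volumetric,
            fMRU_pixel_patlak = mru$srf$patlak,
            DRS_patlak        = drs$srf$patlak,
            DRS_auc           = drs$srf$auc), 1)
#>                   left right
#> fMRU_volumetric   65.0  35.0
#> fMRU_pixel_patlak 70.7  29.3
#> DRS_patlak        65.5  34.5
#> DRS_auc           64.0  36.0
```

The ground truth is a 65/35 split. The fMRU volumetric SRF (Patlak slope
density × segmented volume) and both DRS estimates recover it to within
~1.5 points at default noise. The pixel-based fMRU split (70.7/29.3) is
intentionally different: it is the per-unit-volume uptake ratio before
volume weighting — here the left kidney is smaller but takes up more per
millilitre.

```r
mru$drainage$left
#> <drainage_result> accumulation: Tmax 585 s, NORA 2.53, ROE 3.4%, end/peak 0.98
drs$drainage$right
#> <drainage_result> normal: Tmax 175 s, NORA 0.65, ROE 83.9%, end/peak 0.57
```

The obstructed (accumulation) side never peaks, retains 2.5× its early
activity and has near-zero output efficiency; the normal side peaks at
~3 min and drains 84% of its modelled input.

The agreement layer works directly on published reading tables:

```r
tab <- read_contingency_table(system.file("extdata",
    "drainage_concordance_counts.csv", package = "renogram"))
cohens_kappa(tab)
#> <kappa_result> Po = 0.716, Pe = 0.350, kappa = 0.563 (95% CI 0.418-0.708), moderate
```

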