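---
title: "Methods: phantom design, SRF estimation and drainage classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom design, SRF estimation and drainage classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renogram)
```

This vignette documents the models behind `renogram`, the parameters that
matter, and the design choices that were genuinely open — in enough
detail that a reader can judge what a passing test suite does and does
not establish about real patient data.

## The kinetic model

Both imaging paths share one forward model. The arterial input is a
gamma-variate first pass,

$$P_1(t) = A\left(\frac{t-t_0}{\alpha\beta}\right)^{\alpha}
           e^{\,\alpha-(t-t_0)/\beta}, \qquad t > t_0,$$

normalized so its continuous maximum is $A$ at $t_0 + \alpha\beta$, plus
a recirculation plateau at a fixed fraction of that peak, approached with
an exponential tail. The gamma-variate is the standard empirical bolus
form in tracer kinetics; a micro-bolus injection justifies treating MR
signal as proportional to concentration, so no relaxivity nonlinearity is
modelled.

Each kidney follows irreversible-uptake (Rutland–Patlak) kinetics with a
collecting-system compartment. Per unit parenchymal volume,

$$\mathrm{parenchyma}(t) = K\!\left[\mathrm{cum}P(t)-\mathrm{cum}P(t-T_t)\right]
  + V_b P(t), \qquad
  \mathrm{pelvis}'(t) = K\,P(t-T_t) - k_{out}\,\mathrm{pelvis}(t),$$

where $\mathrm{cum}P$ is the running input integral, $T_t$ the
parenchymal transit time, $V_b$ the blood-volume fraction, and $k_{out}$
the pelvic outflow rate. With $k_{out}=0$ the whole-ROI curve reduces
exactly to $K\,\mathrm{cum}P(t) + V_b P(t)$ (conservation; the test suite
checks this to 0.5% at 5-s sampling). The three drainage regimes are
realized purely through $k_{out}$:

| pattern | $k_{out}$ | behaviour |
|---|---|---|
| normal | 0.02 s$^{-1}$ | clear post-peak decline |
| borderline | solved per curve | post-peak plateau |
| accumulation | 0 | ever-increasing |

The borderline rate has no closed form: it must balance late pelvic
inflow against outflow for the specific input and schedule in use. It is
solved by root-finding (on $\log_{10} k_{out}$, tolerance $10^{-4}$) so
that the mean of the final minute sits at 95% of the curve maximum —
inside the plateau band of the classifier but clearly away from both the
normal and the accumulation boundary. Because every compartment term is
proportional to $K$ except the small $V_b P$ term, the solved rate is
nearly independent of kidney function.

## Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| $\alpha$, $\beta$ | 3, 6 | –, s | sharp paediatric micro-bolus, ~36 s first pass |
| peak time | 40 | s | aortic arrival in a dynamic renographic sequence |
| recirculation fraction | 0.05 | – | small steady-state blood pool after a micro-bolus |
| $K$ | 0.01 | s$^{-1}$ | makes the parenchymal phase dominate the vascular spike, as in real renograms (peak-to-vascular ratio ≈ 2–3) |
| $V_b$ | 0.1 | – | typical renal blood-volume fraction |
| $T_t$ | 150 | s | physiological parenchymal transit (2–3 min); also keeps the default fit window inside the pure-uptake phase |
| volumes | 60–150 | mL | paediatric-to-adolescent parenchymal range |
| fMRU noise SD | 1% of parenchymal peak | a.u. | high-SNR dynamic gradient-echo series |
| DRS count scale | 10 000 | counts/frame at peak | MAG3 posterior-projection statistics |
| background level | 0.3 | of peak pixel rate | perirenal soft-tissue activity |

The fMRU schedule is fixed by the acquisition protocol being emulated:
5-s frames for the first 5 minutes, then 30-s frames for 5 more. The DRS
schedule (10 s × 120 frames, 20 min) is a conventional diuretic-renography
duration; the emulated study did not publish its frame timing, so this is
a stated convention, not a reproduced fact.

An important interaction: with a low $K$ the whole-ROI maximum is the
*vascular* spike $V_b P$, not the filtration peak, and plateau curves
become inseparable from rising ones. The default $K = 0.01$ was chosen so
the parenchymal hump dominates; users lowering $K$ below ~0.005 with
$V_b = 0.1$ should expect the borderline regime to degrade, which mirrors
the clinical situation (poorly functioning kidneys have uninterpretable
drainage curves).

## Study geometry

The fMRU phantom is a labelled voxel grid (default 2 × 2 × 4 mm, matching
a 4-mm slice thickness) holding two axis-aligned ellipsoidal kidneys with
2:1 axis ratio and the specified parenchymal volumes, a small pelvic
reservoir medial-inferior to each, and a vertical aortic cylinder.
Parenchymal voxels carry the intensive model signal; pelvic voxels carry
the pelvic amount divided by the discretized pelvic volume, so ROI means
remain exactly proportional to the compartment sums and the drainage ROI
(parenchyma + pelvis) reproduces the model curve shape. A separate
structural volume (parenchyma-bright, used for segmentation) emulates the
volumetric sequence. The DRS phantom is a posterior-projection pixel grid
with projected kidney + pelvis regions, a cardiac blood-pool disc as
input-function ROI, soft-tissue background proportional to the blood
curve everywhere, and C-shaped perirenal background ROIs open toward the
midline. Counts are Poisson; fMRU noise is additive Gaussian — the two
modality-appropriate noise models.

There is no respiratory motion, no partial-volume blurring, no
attenuation or scatter, no furosemide pharmacokinetics (the diuretic
timing protocols differ between modalities in practice and are treated as
labels, not models), and the segmentation stand-in is simple thresholding
plus 26-connected components rather than a dedicated parenchymal
segmentation algorithm. Passing tests therefore demonstrate the internal
consistency of the estimators under the stated statistical structure, not
robustness to the full physics of either modality.

## Estimation choices

**Analysis window.** Both SRF methods require pure uptake: the default
window runs from 20 s to 120 s after the smoothed input-curve peak. With
$T_t = 150$ s, filtered tracer cannot have reached the pelvis (let alone
left the ROI) before the window closes, so whole-kidney DRS slopes are
unbiased; the window is fully configurable.

**Background correction.** DRS count curves are corrected by the
kidney-to-background ROI size ratio (counts are extensive); fMRU signal
means subtract the background mean unscaled (signal is intensive).
Whether the emulated DRS software size-scaled or fitted its background is
unpublished; the size-ratio rule is the stated convention. Negative
corrected values are clipped to zero and counted in the QC flags.

**Patlak fit.** Plain OLS on the linearized model, cumulative input by
trapezoid from $t=0$ (the signal is assumed zero before the first frame —
true pre-bolus). Frames with non-positive input are dropped with a
warning; fewer than three usable frames is an error. Negative fitted
slopes are floored at zero (non-physical) with a warning before forming
ratios. The fit is checked against a direct normal-equations solve to
$10^{-9}$ in the test suite.

**Volumetric combination.** The published plug-in's exact combination
formula is not printed; this package uses volume-weighted per-unit-volume
slopes, $vSRF_L = 100\,V_L k_L/(V_L k_L+V_R k_R)$, and accepts AUC-based
per-volume indices through the same interface. For fMRU the ROI-mean
Patlak slope is already per unit volume; for DRS the whole-kidney count
slope is volume-integrated, so its ratio is directly the volumetric
split — which is why the two pipelines are expected to agree.

**Drainage classification.** The published definition of the three
patterns is visual. The operational rule here: accumulation if the
smoothed global maximum falls in the final `end_window` (60 s); otherwise
normal if the final-window mean has declined at least `decline_threshold`
(10%) below the peak; otherwise borderline. Both constants are arguments.
An inter-reader kappa near 0.56 for this reading in practice indicates
genuine boundary ambiguity; no threshold choice can remove it, only state
it.

**NORA and ROE.** NORA is late activity (20 min, or study end if
shorter) over the 1–2-min mean — the conventional nuclear-medicine
constants; the emulated study names the metrics without constants. ROE
uses the Patlak-modelled expected input $U(t) = K\int_0^t P\,ds$ (the
residual the kidney would hold had nothing drained), giving
$ROE = 100\,(1 - R(t)/U(t))$, clipped at 100; negative values (vascular
signal on top of full retention) are flagged rather than hidden.

**Ties and degenerate inputs.** Peak ties break toward the earliest
frame; flat curves classify as borderline with a flag; all-zero curves
are an error, as are non-functioning kidney *pairs* in any SRF ratio
(an undefined split should fail loudly, not return NaN downstream).

## Agreement layer

Bland–Altman uses the sample SD (n−1); limits are mean ± 1.96 SD, the CI
of the mean uses SE = SD/√n and of each limit SD·√(3/n) — the standard
large-sample construction. Cohen's kappa is unweighted by default (the
three patterns are treated as nominal); a linear-weighted option exists
but is not used for any comparison here. The kappa CI uses the simple
large-sample standard error $\sqrt{P_o(1-P_o)/(N(1-P_e)^2)}$; published
CIs computed with other formulas will differ slightly, so only $P_o$ and
$\kappa$ themselves should be compared across software.

When reconstructing limits of agreement from a *printed* mean/SD table,
only limit cells consistent with two-decimal rounding of the inputs are
comparable; cells computed by the original authors from unrounded means
can differ in the last digit, and the test suite documents exactly which
cells are excluded for that reason.

## Problem sizes

The shipped tests and the acceptance script run 20 paired phantom
simulations (one fMRU grid of roughly 90 × 40 × 30 voxels × 70 frames and
one 50 × 60 × 120 DRS pixel series each), 100-replicate noise Monte
Carlos per drainage pattern, and a 10 000-pair Bland–Altman coverage
check — sizes chosen so the whole suite completes in about a minute on a
laptop while keeping Monte-Carlo standard errors well below the asserted
margins.

## Interfaces

The package is driven from R: generators, analysis functions and
CSV/NIfTI/JSON readers and writers form the public surface, and
`scripts/acceptance.R` is the reproducibility entry point. No separate
shell CLI is shipped; the exported functions are the supported interface
for scripted use.

## Known limitations

- The phantom's background and recirculation share the blood-curve
  shape; real soft-tissue washout is slower and can bias DRS background
  correction in ways the phantom cannot reveal.
- Volumetric SRF accuracy is bounded by the threshold segmentation
  (~1–2% volume error on the default grid); a real parenchymal
  segmentation has different, anatomy-dependent errors.
- Patient-level reading variability (intra-/inter-reader) is outside the
  phantom's scope: it models acquisitions, not readers.
- The borderline pattern is defined relative to the classifier's own
  plateau band; other operationalizations of "plateau" will draw the
  normal/borderline boundary elsewhere.
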