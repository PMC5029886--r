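---
title: "Calibrated dual-echo ASL BOLD analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated dual-echo ASL BOLD analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calbold)
```

## The measurement problem

Resting cerebral metabolic rate of oxygen (CMRO2) can be mapped with MRI by
calibrating the BOLD signal against two respiratory challenges: hypercapnia
(HC, raised inspired CO2, which increases cerebral blood flow with little
change in metabolism) and hyperoxia (HO, raised inspired O2, which increases
arterial O2 content with little change in flow). A dual-echo
pseudo-continuous arterial spin labeling (pCASL) sequence measures CBF and
the transverse relaxation rate R2* simultaneously; end-tidal gas monitoring
supplies the arterial O2 levels. The generalized calibration model (GCM)
turns the per-gas responses into two curves in the (OEF, M) plane whose
intersection yields, per voxel, the BOLD calibration parameter M and the
resting oxygen extraction fraction OEF. O2 delivery (CBF0 times arterial O2
content) and CMRO2 (OEF times delivery) follow directly.

`calbold` implements this chain end to end, together with a synthetic-data
generator that exercises every stage, the test-retest statistics used to
characterize reproducibility, and the sensitivity machinery for systematic
and random errors.

## The calibration model

For one gas challenge with fractional CBF change $f$, fractional CMRO2
change $r$ (1 = isometabolism) and arterial O2 contents $C_{a,0}$ (baseline)
and $C_{a}$ (during gas), the venous deoxyhemoglobin ratio is

$$d(E) = \frac{\phi\,[\mathrm{Hb}] - C_a + (r/f)\,E\,C_{a,0}}
              {\phi\,[\mathrm{Hb}] - C_{a,0} + E\,C_{a,0}},$$

with $E$ the resting OEF, $\phi = 1.34$ mL O2/g Hb the carrying capacity and
$[\mathrm{Hb}] = 15$ g/dL by default. Venous dissolved O2 is neglected. The
fractional BOLD change implied by a measured R2* change is
$b = e^{-TE_{\mathrm{ref}}\,\Delta R2^*} - 1$ at the reference echo time
$TE_{\mathrm{ref}} = 30$ ms, and the per-gas curve is

$$M(E) = \frac{b}{1 - f^{\alpha} d(E)^{\beta}},$$

with $\alpha = 0.18$ (flow-volume coupling) and $\beta = 1.5$ (dHb
nonlinearity). The HC and HO curves are intersected per voxel by a
sign-change scan on a uniform OEF grid (step $10^{-3}$) refined by bisection
to $|\Delta E| < 10^{-7}$; roots must satisfy $M > 0$ and
$E \in (0.01, 0.99)$. Voxels without a sign change are flagged unsolved and
excluded from all downstream averages; with multiple roots the smallest OEF
is reported and the root count recorded (the model treats the solution as
unique; no principled tie-break exists, so the choice is conservative
toward physiological OEF values). The forward map
(`forwardDeltaR2star()`) is the exact algebraic inverse, which gives the
simulator and the solver a shared round-trip identity checked to $10^{-4}$.

Arterial saturation uses the Severinghaus empirical dissociation curve
$S_aO_2 = (23400/(P^3 + 150P) + 1)^{-1}$, with end-tidal O2 standing in for
arterial PaO2 (no alveolar-arterial gradient). O2 content is
$C_a = \phi [\mathrm{Hb}] S_aO_2 + 0.003\,P$ (mL O2/dL), and delivery is
converted to micromoles with $u = 44.6$ µmol/mL O2 (ideal gas at STPD).
All of these constants are exposed as configurable parameters
(`bloodParams()`, `modelParams()`), because published variants of the
content model differ in conventions.

## Signal model and estimation

The acquisition is an 18-minute dual-echo pCASL run (TR 4.12 s, TE 8.4/30
ms, 21 slices): two 2-min HC blocks and two 3-min HO blocks separated by
rest, 262 TRs, two echo frames per TR, label and control alternating per TR.
Gas responses are modeled with a single-gamma kernel with 20-s time-to-peak
and 40-s FWHM (shape and scale solved numerically from that pair), which
yields near-exponential transitions of end-tidal and tissue signals toward
each plateau.

The voxelwise GLM has one row per frame and 15 columns: four
channel-baseline indicators (echo 1/2 x label/control), eight response
regressors (channel indicator times the HRF-convolved block regressor of
each condition, normalized to unit plateau), and three shared zero-mean
polynomial drift terms (degrees 1-3). A degree-3 polynomial *with* an
offset would be exactly collinear with the channel baselines (they sum to
the constant), so the offset lives in the baseline columns; this keeps the
design full rank while retaining cubic drift flexibility. Estimation is
ordinary least squares; no autocorrelation model is applied.

Per condition and label state, S0 and R2* come from the exact two-point
exponential fit $R2^* = \ln(S_1/S_2)/(TE_2 - TE_1)$. The BOLD R2* of a
condition is the control/label mean; the ASL signal is control-minus-label
S0. State maps are 3D-median-filtered (3x3x3, edge-truncated) before
differencing to suppress isolated non-parenchymal voxels. Voxels with
baseline T2* below 30 ms, or positive R2* responses to either gas, are
excluded; voxels below 50% GM probability stay out of ROI statistics.

CBF quantification uses the single-compartment consensus model with
slice-dependent post-labeling delay, linear from 900 ms (slice 1) to 1986 ms
(slice 21), brain average 1443 ms. (A published variant states the upper
end as 1960 ms; both endpoints are arguments of `acquisitionGeometry()`.
The 900/1986/1443 triple is used because it is internally consistent.)
During hyperoxia, dissolved O2 shortens arterial blood T1 as
$1/T1 = 1/T1_0 + \kappa \Delta PaO2$ with $T1_0 = 1.65$ s and
$\kappa = 1.38\times10^{-4}$ s$^{-1}$/mmHg, chosen to reproduce a hyperoxic
blood T1 of about 1.558 s at a typical +259 mmHg end-tidal excursion; the
hyperoxic CBF response is re-quantified with the shortened T1, and — because
the hyperoxic ASL response has low contrast-to-noise — the GM-weighted mean
of the corrected percent change replaces the voxelwise value as a single
per-subject estimate.

## Respiratory chain

End-tidal (ET) and fixed-inspired (FI) points are extracted per breath from
the continuous O2/CO2 traces: breath cycles are delimited by upward
zero-crossings of the trace minus its one-breath moving average, and the
two extrema of each cycle are classified. When the programmed FI schedule
is known, the FI point is the extremum nearest the expected FI — this stays
correct while end-tidal O2 exceeds inspired O2 during the washout after a
hyperoxic block, where a fixed min/max convention inverts. Breaths
straddling or adjacent to a programmed gas switch are dropped as ambiguous.

The sampling-line filter attenuates the waveform's peak-to-peak amplitude
symmetrically about the breath midline, so each ET point is corrected by
the observed-minus-expected FI error of its two adjacent same-gas-segment
FI points, combined by linear interpolation in time (this reduces to the
plain two-point mean for a breath midway between them, and removes a
~0.6 mmHg bias during fast plateau transitions). ET pressures are then
rescaled by $(P_B - 47)/P_B$ for water vapor (barometric pressure
configurable, default 760 mmHg).

Baseline and gas-induced ET changes come from least squares against a
third-degree polynomial (offset included; polynomial terms orthogonalized
to zero mean so the offset is the drift-free baseline) plus four
HRF-convolved block regressors evaluated at the irregular breath times.
The per-gas ET change is the mean of the two block effect sizes.

## What the synthetic-data generator emulates

`simulateStudy()` draws voxelwise truth maps (CBF0 U[40,60] mL/100 g/min,
baseline T2* U[40,60] ms with a 5% fraction lowered to U[20,28] ms to
exercise the exclusion rules, M U[0.03,0.08], OEF U[0.25,0.55], GM
probability U[0,1], hypercapnic flow ratio U[1.3,1.7], hyperoxic flow ratio
1.0), generates a breath-by-breath respiratory trace whose vapor-corrected
plateaus are ETO2 111/370/118 and ETCO2 40/39/50 mmHg
(baseline/HO/HC), and synthesizes the annotated dual-echo series: per
condition, the endpoint signal of each echo/label state is
$S = S_0 e^{-TE\,R2^*}$ with the label S0 depressed by the ASL difference
implied by that condition's CBF (the hyperoxic difference uses the
shortened blood T1), and the R2* changes generated through the calibration
forward model. Each frame mixes the endpoint levels linearly along the
HRF-convolved block regressors, then adds polynomial drift and white
Gaussian noise (optionally AR(1)).

Mixing *signal states* linearly along the regressors makes the GLM the
exact inverse of the generator on noiseless data — by design, so that
noiseless recovery failures always indicate an estimation defect rather
than model mismatch. Real data differ in ways the generator does not
attempt: transitions blend physiology nonlinearly, noise is physiological
and serially correlated rather than white, motion and distortion are
absent, and truth maps are spatially unstructured. Passing recovery tests
therefore validate the estimation chain's correctness, not the acquisition
model's realism.

The noise SD default is 0.5 signal units (0.5% of the normalized brain
mean), a plausible post-smoothing temporal noise level at 3 T. The breath
period is 4 s (15 breaths/min) sampled at 10 Hz.

## Numerical choices and degenerate inputs

* HRF shape/scale are solved by `uniroot` from (mode 20 s, FWHM 40 s);
  the kernel and all regressors are evaluated on a 0.1-s grid and shared
  (by construction) between simulator and analysis.
* The OEF grid step ($10^{-3}$), bisection tolerance ($10^{-7}$) and search
  bounds (0.01, 0.99) are `modelParams()` arguments. Roots landing exactly
  on grid points are captured separately from sign changes.
* Non-physical deoxyhemoglobin ratios (non-positive numerator or
  denominator) and near-zero curve denominators ($<10^{-9}$) mark curve
  points invalid; all-invalid curves yield an unsolved voxel, never an
  error.
* Non-positive echo signals make a voxel NA through `estimateR2star()`;
  NAs propagate to the exclusion mask rather than stopping the pipeline.
* Gaussian smoothing uses a separable truncated kernel renormalized at
  volume edges (constants are preserved exactly); `fwhm = 0` and
  `medianRadius = 0` are exact identities, used by the noiseless
  verification experiments where any spatial mixing would break the
  voxelwise identity being tested.
* A constant respiratory trace has no zero-crossings and raises
  "no breaths detected"; a zero-variance paired difference raises an error
  in the paired t-test rather than returning p = NaN.

## Sensitivity analyses

`sweepSystematic()` re-solves a GM-like fixture voxel (CBF0 50, f_HC 1.5,
responses forward-generated from M = 0.05, OEF = 0.39 at end-tidal O2
111/118/370 mmHg) across the assumed-parameter ranges $\alpha$ [0.15,
0.45], $\beta$ [1.0, 1.5], [Hb] [11, 17] g/dL, CMRO2 ratios 0.90-1.10 (HC)
and 0.93-1.07 (HO), and hyperoxic flow ratio 0.90-1.00. Varying the
assumed [Hb] recomputes the arterial O2 contents from the stored end-tidal
pressures — content is derived from [Hb], and holding it fixed would be
internally inconsistent. On this fixture, $\beta$ and the hypercapnic
CMRO2 assumption dominate M (tens of percent), while [Hb] and the
hyperoxic assumptions move M by only about 1-2%.

`propagateRandomError()` scales one measured input — the hypercapnic
percent flow change or either R2* response — by $1+e$ over $e \in
[-0.33, 0.33]$, re-solves, and reports the CV between the perturbed and
unperturbed solutions. The closed form for a pure input pair is
$CV = 100\,|e| / (\sqrt 2\,(1 + e/2))$: 20% at $e = +33$%, 28% at
$e = -33$%. Because resting CBF and O2 content are unvaried, the OEF and
CMRO2 CV curves coincide.

## Test-retest statistics

For each metric-by-ROI cell with paired sessions A/B: dSD is the SD of the
differences, wsSD $=$ dSD$/\sqrt 2$, the repeatability coefficient is
CR $= 1.96\,$dSD, and the within-subject CV is the root-mean-square of
per-subject (wsSD/mean) ratios. Whether the cell is analyzed on the
original or log10 scale follows a decision tree: Shapiro-Wilk on the
differences and Kendall's $\tau$ between $|B-A|$ and $(A+B)/2$, both at
$\alpha = 0.05$; failure of either triggers a retry on log10 data, which
are used when they pass (wsCV then $= 100(10^{\mathrm{wsSD}}-1)$) and
annotated as failed otherwise. The order-effect test is a two-tailed
paired t; ROI pairs are compared with Welch tests under Bonferroni
correction (Holm available) and binned at 0.05/0.005/0.0005. The
multiple-comparison method and the ROI test are design choices — the
originating analyses name neither.

## Problem sizes and known limitations

The shipped verification experiments use a 12x12x4 grid with 262 TRs
(desk-scale but structurally complete: all four channels, all slices, both
gas conditions), 1000-voxel solver round trips against a brute-force
exhaustive OEF grid at step $10^{-5}$, and $10^4$-replicate calibration
checks for the statistics; a full run takes on the order of a minute.

Known limitations: the solver's voxelwise estimates become visibly biased
at high noise (the intersection is a nonlinear function of the inputs and
unsolved voxels are a selected subset) — the stochastic recovery test
therefore runs in the moderate-noise regime; motion estimation, tissue
segmentation, distortion correction and atlas registration are out of
scope (`applySharedTransforms()` enforces the shared echo-transform
contract for externally supplied motion parameters); and arterial transit
time, partial volume and background suppression are not modeled.
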