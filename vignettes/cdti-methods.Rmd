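---
title: "Methods: ex vivo cardiac DTI analysis with cdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ex vivo cardiac DTI analysis with cdti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdti)
```

## Scope

`cdti` implements the analysis chain of an ex vivo cardiac diffusion tensor
imaging (cDTI) study: log-linear tensor estimation from diffusion-weighted
volumes, fractional anisotropy (FA) and apparent diffusion coefficient
(ADC) maps, helix-angle (HA) and secondary eigenvector angle (E2A) mapping
in a local cardiac frame, AHA 17-segment regional statistics with
transmural profiles and gradients, multiple-acquisition SNR estimation with
parallel-imaging normalization, and supporting T1/T2* relaxometry.  Because
no scanner data ships with the package, a synthetic left-ventricle phantom
generator provides controlled inputs for every stage; it is first-class,
tested code, not a fixture.

## Signal model and tensor estimation

The diffusion-weighted signal of a Stejskal–Tanner preparation is

$$S_k = S_0 \, e^{-b \, g_k^{\mathsf T} D \, g_k},$$

with $b = \gamma^2\delta^2G^2(\Delta - \delta/3)$ for rectangular gradient
lobes (`compute_bvalue()`).  Because $D$ is symmetric it is estimated as the
6-vector $\bar D = (D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz})$; each
unit direction $g$ contributes the design row
$\bar g = (g_x^2, g_y^2, g_z^2, 2g_xg_y, 2g_xg_z, 2g_yg_z)$ so that
$g^{\mathsf T} D g = \bar g \cdot \bar D$.  With $S_0$ the arithmetic mean
of the $b=0$ reference volumes (multiple references are acquired; the mean
is the obvious combination and the one used here), the fit solves

$$A \bar D = B, \qquad B_k = \frac{\ln(S_0 / S_k)}{b_k}, \qquad
  \bar D = (A^{\mathsf T} A)^{-1} A^{\mathsf T} B .$$

A sign convention note: the log-linearized system is sometimes written with
$\ln(S_k/S_0)$ on the right-hand side.  Since the signal decays, that form
pairs with a negated quadratic form; `fit_tensor()` uses $\ln(S_0/S_k)$,
the sign under which the noiseless simulate→fit roundtrip returns the input
tensor exactly — a property the test suite asserts at relative error
$10^{-9}$ and which holds to machine precision in practice.

Numerical choices:

* **Non-positive signals.**  Any voxel with $S_k \le 0$ or $S_0 \le 0$ is
  flagged invalid and excluded, never clamped: clamping would silently bias
  the logarithm, whereas flags keep the exclusions auditable.
* **Negative fitted eigenvalues** (possible under noise) keep their
  decomposition but are flagged; FA/ADC are reported only on voxels with
  all eigenvalues positive.
* **Ordinary least squares**, no weighting and no Rician-bias correction:
  the estimator is the plain pseudo-inverse, and its noise behaviour is
  characterized by simulation rather than corrected.
* **Eigenvector sign**: the first component exceeding $10^{-12}$ in
  magnitude is made non-negative.  Physically the sign is arbitrary; fixing
  it makes maps reproducible.  Eigenvalues are sorted descending, the
  ordering `eigen(symmetric = TRUE)` already guarantees.

From the sorted eigenvalues,
$\mathrm{FA} = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\bar\lambda)^2} \big/
\sqrt{\sum_i \lambda_i^2}$ and $\mathrm{ADC} = \bar\lambda$; both are
rotation invariant, which the suite checks under random rotations.

## Local cardiac frame, helix angle, E2A

`build_local_frames()` sets, at every myocardial voxel: the longitudinal
axis $e_l$ (the long axis, oriented apex→base), the radial axis $e_r$
(in-slice unit vector from the cavity center, orthogonalized against
$e_l$), and the circumferential axis $e_c = e_l \times e_r$.  This
chirality is chosen so that right-handed endocardial helices get positive
helix angles; data following another convention can be flipped in
configuration.  For real data the long axis would be estimated as the
principal axis of the mask and cavity centers as per-slice cavity
centroids; the phantom supplies both exactly.

**Helix angle.**  $E_1$ is projected onto the $e_c$–$e_l$ plane and
$\mathrm{HA} = \operatorname{atan2}(E_1\cdot e_l,\ E_1\cdot e_c)$, after
flipping $E_1$ to a non-negative circumferential component (eigenvectors
are axes, not arrows).  HA therefore lies in $(-90°, 90°]$.

**E2A.**  The cross-myocyte direction is constructed as the unit vector
perpendicular to (the wall-tangent projection of) $E_1$ within the
wall-tangent plane, $\hat x = e_r \times E_1 / |e_r \times E_1|$, and the
in-plane radial direction as $\hat r = E_1 \times \hat x$.  $E_2$ is
projected onto their span and
$\mathrm{E2A} = \operatorname{atan2}(E_2\cdot\hat r,\ E_2\cdot\hat x)$,
folded into $[-90°, 90°]$; statistics use $|\mathrm{E2A}|$.  The
cross-myocyte direction has no universal constructive definition in the
applied literature; the construction above is the standard one and is a
convention of this package, recorded in output sidecars.  Voxels where
$E_1$ is parallel to $e_r$ (degenerate tangent projection) are flagged.

## Regional analysis

`aha_segment()` splits the cavity-bearing slices into equal basal /
mid-cavity / apical thirds (remainder slices assigned base-first — an
algorithmic stand-in for the manual slice grouping used on scanner data),
sectors the basal and mid rings into six 60° wedges and the apical ring
into four 90° wedges from a configurable angular origin, and labels the
closed cap beyond the cavity as the apex (segment 17).

Transmural depth is 0 at the endocardium and 1 at the epicardium along the
center-to-epicardium ray; `transmural_depth()` re-derives it from the mask
alone by angular-bin profile rays.  Profiles bin voxels into five
equal-depth layers (endocardial, sub-endocardial, mid-wall, sub-epicardial,
epicardial — named layers without published boundaries; equal quintiles are
the neutral choice) and report the layer mean ± SD of HA per region.  Note
that with a linear transmural rule the *within-layer* SD is dominated by
the rule's own spread across a 20 %-depth bin (~7° for a 120° span), not by
noise; layer means, not SDs, are the recovery target.  Gradients are
adjacent-layer differences of layer means over the 20 % midpoint spacing,
in °/% depth, plus a total endo→epi gradient.  The apex is excluded from
profiles (no ring geometry) but included in segment medians.

`segment_statistics()` reports per-segment medians (midpoint convention for
even counts) of ADC, FA, |E2A| and $E_1$ components over valid voxels,
with region aggregates taken as the mean of constituent segment medians
(a voxel-pooled median is available by pooling upstream).  An FA ≥ 0.1 mask
(`fa_mask()`) excludes isotropic/noise-dominated voxels first.

`compare_to_reference()` implements the validation procedure for comparing
one protocol against a reference: a two-sided paired Wilcoxon signed-rank
test on per-heart regional values (exact null distribution for ≤ 25
non-zero pairs, zero differences dropped per Wilcoxon's original rule, no
multiple-testing correction — each comparison is reported at its own
$P<0.05$), and a per-segment percent-deviation "bias range" of across-heart
segment medians relative to the reference, reported as a min–max pair over
the 17 segments for ADC and FA.

## SNR and relaxometry

`snr_map()` uses the multiple-acquisition estimator: replicate $b=0$
images form a pseudo-time series and per voxel
$\mathrm{SNR} = \bar x_t / \sigma_t$ with the $n-1$ SD denominator and no
small-sample correction.  At 30 replicates the estimator reads about 2.5 %
high (ratio-estimator bias), within its 5 % calibration band; for true SNR
below ~3 the Rician noise floor inflates the temporal mean and the
estimator overestimates substantially — demonstrated by simulation in the
suite and documented here as a calibration note, not corrected.

`normalize_snr()` compensates accelerated / high-bandwidth scans with the
two factors $\sqrt{N_{PE}(\mathrm{ref})/N_{PE}(\mathrm{test})}$ and
$\sqrt{bw(\mathrm{test})/bw(\mathrm{ref})}$, applied multiplicatively to
the measured SNR (compensation upward for shorter echo trains and higher
bandwidth).  Whether such factors should multiply or divide is ambiguous in
parts of the literature; the package applies the literal upward reading and
logs both factors in the result so the direction is always auditable.

Relaxometry: `fit_t2star()` is the log-linear mono-exponential fit
(log-slopes above $-10^{-10}$ /ms are flagged as carrying no decay);
`fit_despot1()` the standard DESPOT1 linearization $S/\sin\alpha$ against
$S/\tan\alpha$ with slope $e^{-TR/T_1}$, flip angles scaled per voxel by a
B1 map, slopes outside $(0,1)$ flagged; `b1_double_angle()` the long-TR
double-angle method $\cos\alpha = S(2\alpha)/2S(\alpha)$.

## The phantom generator

`phantom_spec()` defaults describe the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| voxel size | 1.3 mm isotropic | acquisition resolution of the emulated protocol |
| wall radii | 12 / 20 mm | piglet-scale LV annulus |
| cavity slices | 30 | LV coverage of the SNR protocol |
| apical-cap slices | 4 | reported apical-cap extent |
| helix rule | linear, +60° → −60° | conventional transmural endpoints; configuration, not a claim |
| eigenvalues | (1.0, 0.45, 0.45)·10⁻³ mm²/s | gives FA ≈ 0.46, ADC ≈ 0.63·10⁻³ mm²/s, the unfixed-myocardium values |
| b-value / directions / b=0 | 700 s/mm² / 30 / 5 | emulated acquisition |
| noise | Rician, SNR 40 typical | magnitude MRI; SNR defined against the b=0 myocardial signal |

Two deliberate deviations from a naive reading of those conditions:

* The default eigenvalue triple has $\lambda_2 = \lambda_3$, which matches
  the target FA/ADC but makes $E_2$ directionally degenerate — E2A is then
  undefined in data simulated from it.  E2A-recovery experiments therefore
  use a sheetlet-resolving triple, (1.0, 0.6, 0.3)·10⁻³ mm²/s, as an
  explicit configuration.
* For relaxometry series the noise scale references each series' peak
  signal rather than $M_0$: the spoiled short-TR VFA signal is a few
  percent of $M_0$, and an $M_0$-referenced noise floor would bury it at
  any realistic target SNR.

Gradient tables come from iterative pairwise electrostatic repulsion on the
sphere with antipodal symmetry, initialized from a seeded, jittered
Fibonacci hemisphere.  The initialization matters: a raw random start can
leave a near-antipodal pair at an unstable equilibrium of the dynamics
(the antipodal repulsion force is purely radial there), which collapses the
minimum angular separation.  The displacement per iteration is capped at a
decaying angular step so the dynamics remain stable regardless of raw force
magnitudes.  At $n=6$ the scheme reaches the icosahedral optimum (63.4°
minimum separation) and the design matrix condition number is ~1.6.

What the phantom does *not* emulate: realistic anatomy (papillary muscles,
right ventricle), partial-volume effects at tissue boundaries, eddy-current
or susceptibility distortion (a simplified linear EPI shift model is
provided separately as `apply_epi_distortion()`), coil sensitivity and
g-factor noise amplification, and spatially correlated noise.  Passing
recovery tests on this phantom therefore demonstrates correctness of the
estimators and conventions, not robustness to everything real data does.

## Problem sizes and determinism

The default phantom grid is 40×40×36 voxels (~17 000 myocardial voxels),
which the full simulate–fit–angle–profile chain processes in seconds; the
test suite and the acceptance script use this size, with 1 000 random
tensors for the fit-oracle check and 1 000 Monte-Carlo replicates (11
paired hearts per arm, per-heart medians of 200-voxel samples from the
phantom FA distribution) for the Wilcoxon null calibration — the exact
test's attainable size at $n=11$ is 4.2 %, inside the 3.5–6.5 % band.
Every source of randomness takes an explicit integer seed; no function
reads or leaves global random state (`.Random.seed` is saved and
restored), so all outputs are reproducible from (config, seed).

## Known limitations

* The helix-angle layer means of the default phantom carry ~1.7–1.8° of
  discretization offset in the outermost layers (bin-mean depth is not the
  bin midpoint on a discrete annulus); this is geometry, not estimator
  error, and sits just inside the 2° recovery band.
* The Wilcoxon comparison assumes exchangeable paired hearts; no
  mixed-effects structure is modelled.
* Tensor fitting is strictly voxel-wise: no spatial regularization or
  denoising (deliberately — upstream denoising is out of scope).
* `run_pipeline()` reads NIfTI + FSL bval/bvec only; DICOM is out of scope.
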