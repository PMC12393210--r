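---
title: "Quantitative sodium MRI: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative sodium MRI: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sodium (^23^Na) MRI can quantify the tissue sodium concentration (TSC), a
volume-weighted average of intra- and extracellular sodium that changes
with cell vitality. Because the image intensity of a spin-density-weighted
sodium acquisition is only *proportional* to concentration, absolute
quantification calibrates the corrected image against external reference
vials of known concentration placed inside the field of view. What reaches
the image, however, is

$$ S(\mathbf r) \;\propto\; B_1^-(\mathbf r)\,
   \sin\!\big(\alpha(\mathbf r)\big)\,
   \frac{1-E_1}{1-E_1\cos\alpha(\mathbf r)}\;\rho(\mathbf r),
   \qquad E_1 = e^{-TR/T_1}, $$

so transmit-field inhomogeneity (through the local flip angle
$\alpha = \alpha_{nom} B_1^+$), receive-field inhomogeneity (linear in
$B_1^-$) and $T_1$ saturation all bias the apparent sodium concentration
(aSC; aTSC over tissue). `naquant` implements the full measurement *and*
correction chain as a simulation pipeline with known ground truth: digital
phantom, synthetic coil fields, density-adapted 3D radial (DA-3DPR)
acquisition, gridding reconstruction, dual-flip-angle $B_1^+$ mapping, the
$T_1/B_1^+/B_1^-$ correction chain, reference-vial regression calibration,
and an evaluation suite (VOI statistics, histogram FWHM, PSF / effective
resolution).

# The acquisition model

**Steady state.** Each voxel contributes a FLASH (spoiled gradient-echo)
steady-state amplitude, `flash_signal()`, with the local flip angle
$\alpha_{nom}\,tx(\mathbf r)$. The spoke-history Bloch simulation is
deliberately replaced by the analytic steady state: the corrections being
studied assume that steady state, and a UTE radial sequence with
$TR \gg T_1^\ast$ reaches it after a few spokes.

**Relaxation.** Readout decay is mono-exponential in $T_2^\ast$ and is
applied exactly: voxels are grouped by their (compartmental) $T_2^\ast$
value, each group is transformed separately, and the per-sample factor
$e^{-(TE+t)/T_2^\ast}$ multiplies that group's k-space contribution. The
sequence's ultrashort TE (1 ms) keeps these losses small, which is why the
quantification chain corrects only $T_1$. Bi-exponential relaxation is not
modelled (out of scope); the "apparent" in aSC flags exactly such
unmodelled losses.

**Sampling.** The DA-3DPR readout runs center-out along golden-angle
directions. Directions use the 3D golden means $m_1 = 1/\psi^2 = 0.4656$,
$m_2 = 1/\psi = 0.6823$ ($\psi^3 = \psi^2 + 1$): spoke $i$ has
$z = 2\,\mathrm{frac}(i m_1) - 1$ and azimuth $2\pi\,\mathrm{frac}(i m_2)$.
The pair is *jointly* 2D-equidistributed, which matters: means that are
affinely dependent modulo 1 (e.g. any pair with $m_1 + m_2 = 1$) collapse
the directions onto a one-dimensional spiral and produce coherent PSF
sidelobes an order of magnitude above the ideal ones.

Along each spoke, $k(t)$ rises linearly to $k_0$ during the gradient ramp
(fraction $u$ of the readout, default $u = 0.1$) and then grows as
$(k_0^3 + 3k_0^2 g_0 (t-t_0))^{1/3}$, so equal time steps sweep equal
k-space shell volumes; $k_0/k_{max} = (u/(3-2u))^{1/3}$ makes the curve end
exactly at $k_{max} = 1/(2\,\Delta x_{nom})$. The protocol does not print
its gradient timing, so $u$ is exposed as a parameter; the PSF width changes
by well under 0.15 nominal voxels over $u \in [0.05, 0.2]$ (tested).

**Density compensation.** Per-sample weights are spherical shell volumes
$k^2\,dk$ (central differences), with the k-space center regularized by
half of the innermost shell; the two stored center points of the protocol
(kept for future respiratory sorting, which is out of scope) share that
weight. Summed over all spokes the weights reproduce the k-space ball
volume to < 1%, and in the density-adapted portion they are constant by
construction.

# Reconstruction

The adjoint non-uniform Fourier transform of
`samples * dcf * window` is evaluated by Kaiser-Bessel gridding
(oversampling 2, kernel width 8, shape parameter from the standard
minimum-aliasing-error formula, exact sinh-form deapodization). Forward and
adjoint agree with brute-force direct Fourier sums to ~1e-7 relative error
(tested at 1e-5). Zerofilling evaluates the adjoint on the
`zerofill x nominal` matrix at unchanged FOV, which is algebraically the
same as zero-padding gridded k-space. The reconstruction is normalized by
the total density-compensation weight so uniform unit k-space data give a
unit central value; any residual global scale is irrelevant because the
calibration regression absorbs it.

Radial apodization: Hamming
($0.54 + 0.46\cos(\pi k/k_{max})$) for the quantitative image; Gaussian
($e^{-2\pi^2\sigma^2 k^2}$, $\sigma$ in image-space mm) for the $B_1^+$
map. Multi-channel images are combined voxelwise by sum of squares.

**PSF and effective resolution.** `simulate_psf()` reconstructs uniform
unit k-space data and reads the main-lobe FWHM along a grid axis (linear
interpolation at the half-maximum crossings, isotropy verified to 2%).
At full protocol scale this package obtains **1.58** nominal voxels
unfiltered and **1.99** with Hamming, in close agreement with the
continuous-theory values for an ideally density-compensated ball (1.59 /
1.99, obtained independently by radial quadrature of the ball transform).
The reference protocol quotes 1.7 and 2.1; those values are compatible
within the documented +-0.15 band and plausibly include kernel or
relaxation details of that implementation's own PSF simulation, which its
description does not specify. No parameter here was adjusted toward the
printed values.

# B1 mapping and the correction chain

The dual-flip-angle pair (nominal 45 and 90 degrees, alternating TR
106/168 ms, 20 mm nominal resolution, Gauss sigma = 20 mm, zerofill 8)
yields $\alpha_{45} = \arccos(S_{90}/2S_{45})$ per voxel and
$rel.B_1 = \alpha_{45}/45$. Voxels outside the arccos domain or below a
support threshold (5% of the 99th-percentile signal) are flagged `NA` and
propagate as undefined -- never imputed. Treating each acquisition as an
independent steady state at its own TR is accurate here because the
alternating TRs nearly cancel residual saturation in the ratio (bias
< 0.3% in $rel.B_1$ at $T_1 = 55$ ms); the optional exact correction was
therefore left out.

Corrections divide the image by
$\sin(\alpha_{nom}\,rel.B_1)\cdot B_1^-_{SOS,norm}\cdot f_{T_1}$.
Choices worth recording:

* the FLASH factor $f_{T_1} = (1-E_1)/(1-E_1\cos\alpha)$ uses the
  *nominal* flip angle with the declared per-compartment $T_1$ (55 ms
  NaCl, 34 ms tissue-like), matching the fixed per-compartment correction
  of the reference protocol; a flag allows the local flip angle instead;
* the receive field (sum of squares of the four channel sensitivities) is
  normalized to mean 1 over the union of the vial VOIs -- the protocol
  never states a normalization point because absolute scale cancels in
  calibration; fixing one makes intermediate images comparable;
* calibration regresses concentration on mean VOI signal with a *free
  intercept*, which absorbs the magnitude-image noise floor.

# The synthetic world

`generate_phantom()` builds the validation setup: a 35 mM NaCl canister
(cuboid 170 x 270 mm between two elliptical cylinders, height 160 mm),
four oval vials (stadium cross-section 60 x 38 mm, length 152 mm) at
20/30/40/50 mM (phantom session; 20/60/100/140 for the in-vivo-session
vial set), embedded in a 35 mM agarose bed inside a 52 mm-high drawer
below the body. The drawer hardware fixes the vial positions in reality
but publishes no coordinates, so this package fixes its own: vials side by
side along x at x = -105, -35, 35, 105 mm, axes along z, *centered* in the
bed's height (y = -114 mm). Centering matters at reduced test scales:
with the vials near the bed floor, air bleeds into the vial VOIs once the
effective resolution approaches the bed margin, and the calibration
degrades for a purely geometric reason.

Geometry is voxel-in/voxel-out at voxel centers (no partial-volume
antialiasing); the VOI erosion rules below handle edge effects, as in the
reference analysis. Compartment assignment is innermost-wins (vials within
bed within FOV).

Coil fields (`generate_coil_fields()`) are smooth stand-ins for the
measured/simulated ones: the transmit scale is a random quadratic
polynomial affinely mapped to exactly [1, 1 + `tx_variation`] over a fixed
support box covering phantom and drawer; receive channels are
Lorentzian-like complex sensitivities peaked near four loop positions
around the bore. They emulate the *smoothness and magnitude* of real 7 T
birdcage fields (40% peak-to-peak transmit variation by default), not
their electromagnetic structure -- so a green recovery test establishes
that the correction chain inverts fields of realistic scale and
smoothness, not that it reproduces any specific coil.

**VOI masks.** The protocol's reusable per-vial mask (5984 voxels =
93.5 mL at 2.5 mm) is reproduced by a deterministic rule: among voxels
with at least `erosion_mm` (default 5 mm) margin to the vial wall, keep
the `round(93500 / voxel^3)` most central ones (largest margin, array-order
tie-break) -- exactly 5984 at 2.5 mm, consistently scaled on test grids.
The whole-phantom VOI erodes the body by one effective-resolution width
(2.1 x nominal), the scaled analogue of "exclude the outermost pixels".

**Noise** is complex Gaussian per sample with SD equal to 2% of the RMS
noiseless sample magnitude. At the tiny fixture scale this puts the
thermal contribution to the whole-phantom CV near 0.02-0.04, comfortably
inside the regime of the reference phantom experiment (whose fully
corrected CV was ~0.11) while leaving the field-induced inhomogeneity
dominant -- the property the CV-ordering test is about.

**Fixtures.** `make_fixture("paper_replica")` is the full protocol
(Table-2 scale: 10000 x 256 at 5 mm, output 160^3 at 2.5 mm; B1 map
1020 x 256 at 20 mm). `make_fixture("tiny")` divides the nominal matrix
by 2.5 (32, i.e. 12.5 mm nominal, 64^3 output at 6.25 mm, 500 spokes) and
scales the B1 protocol likewise (50 mm nominal, zerofill 8, sigma =
50 mm = one B1 voxel). The tiny scale was chosen as the coarsest at which
reference-vial calibration remains well-posed: the effective resolution
(2.1 x 12.5 = 26 mm) must stay below the 38 mm vial diameter, otherwise
per-vial partial-volume weights differ between inner and outer vials and
the calibration line is structurally confounded (measured during
development; at 25 mm nominal the recovered mean is off by > 20 mM with
no noise at all).

# Numerical choices and degenerate inputs

* Gridding: oversampling 2, width 8; accuracy ~1e-7 versus direct sums.
* Trajectory center: two k = 0 points stored, weight split; dcf strictly
  positive.
* `dual_fa_map()`: arccos-domain and support filtering produce `NA`s, and
  downstream stages propagate them.
* `histogram_fwhm()`: Scott's-rule bins, Gaussian least squares fit
  initialized at the sample mean/SD with log-sigma parameterization (keeps
  sigma positive); constant data are an error, not a zero.
* Low-k quadrature: windows concentrated at low k (wide Gaussian blurs)
  need the protocol's dense radial sampling (256 samples); with very few
  ramp samples the regularized center weight becomes a visible DC
  pedestal. The fixtures keep the protocol's sampling ratios for exactly
  this reason.
* Ties in `which`-based peak finding and mask construction are broken in
  array order, making every artifact bit-reproducible for a fixed
  configuration (the manifest records md5 checksums to prove it).

# Limitations

* No B0/off-resonance effects, no bi-exponential T2* weighting, no
  partial-volume deconvolution, no motion -- all out of scope of the
  implemented chain (as in the reference analysis).
* The receive correction uses the generator's own B1- SOS field (the
  simulation stands in for the electromagnetic simulation of the real
  setup); with measured data a field map of the actual coil must be
  supplied.
* Proton-side imaging (anatomical reference, segmentation) is not part of
  this package; VOIs come from the known geometry instead.
* In-vivo CV values from the reference study depend on real coil fields
  and anatomy and are explicitly not reproduction targets; the synthetic
  ground-truth-recovery properties substitute for them.
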