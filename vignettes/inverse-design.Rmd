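---
title: "Differentiable wave optics and automated setup discovery with opticraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable wave optics and automated setup discovery with opticraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(opticraft)
```

## The problem

Super-resolution microscopy rests on a small number of hand-designed optical
tricks: a doughnut-shaped depletion beam that confines fluorescence to a
sub-diffraction region (STED), a radially polarized beam whose tight focus
produces a strong longitudinal field and an unusually sharp spot, and the
classic 4f relay that images with magnification $f_2/f_1$ and inversion. The
space of possible optical setups is combinatorially enormous -- ten elements
chosen from five component types already admit about $10^7$ discrete
arrangements, and each arrangement carries a high-dimensional continuous
parameter space on top. `opticraft` makes that space searchable: it couples a
vectorial wave-optics simulator, differentiable end to end, to a
gradient-based optimizer, so that both the *topology* of a setup and its
*continuous settings* (splitter ratios, distances, wave-plate angles, SLM
phase rasters) can be discovered by descent on an explicit design loss.

## Fields, units and conventions

Fields live on centered sampling lattices (`make_grid`): x rightward, y
upward, physical units micrometres, phases in radians wrapped to
$(-\pi, \pi]$. A `vector_field` carries complex component rasters
$E_x, E_y, E_z$ and its vacuum wavelength in nanometres; power is the
discrete surface integral $\sum |E|^2 \, \Delta x \Delta y$. Sources are
linearly polarized Gaussian beams normalized to unit power; when a
configuration does not state a waist we default to a quarter of the grid
half-width, which keeps the beam well contained for FFT propagation.

## Propagation

Free-space hops use the first Rayleigh--Sommerfeld (RS) solution. The
operator is evaluated in whichever domain samples it faithfully (the
standard dual-domain rule): below the critical distance
$z_c = P\,\Delta x^2/\lambda$ (with $P$ the zero-padded pixel count) the
angular-spectrum transfer $e^{i k_z z}$ is exact and unitary; beyond $z_c$
the spatial impulse response

$$h(x, y; z) = \frac{z}{2\pi}\, \frac{e^{ikr}}{r^2}\Big(\frac{1}{r} - ik\Big),
\qquad r = \sqrt{x^2+y^2+z^2},$$

is well resolved and used as an FFT convolution. Both branches share the
same padding (2x linear size, the containment contract) so the semigroup
property holds across the switch. Negative distances back-propagate with the
conjugate kernel; evanescent components are always attenuated, never
amplified.

The vectorial propagator (`propagate_vrs`) moves $E_x, E_y$ with the scalar
kernel and synthesizes $E_z$ through the transversality relation of the
angular spectrum, $\tilde E_z = -(k_x \tilde E_x + k_y \tilde E_y)/k_z$.
This is the frequency-domain statement of the x- and y-weighted kernel
derivatives of the spherical wave; we use it directly because the truncated
spatial derivative kernels decay only like $1/r^2$ and leave a percent-level
divergence residual at the grid sizes we use, whereas the spectral form is
divergence-free to machine precision. The $k_z$ denominator is clamped at
$10^{-3} k$ near the horizon ring.

`propagate_czt` evaluates the same diffraction integral on an arbitrary
output window via Bluestein's chirped z-transform: the final inverse
transform becomes a zoom transform whose output lattice is free in position,
extent and pixel count. On a window congruent with the input grid it
reproduces `propagate_rs` to floating-point accuracy, which is the
equivalence the test suite pins at $10^{-6}$.

High-NA focusing is the Richards--Wolf (Debye--Wolf) model of an aplanatic
objective: apodization $\sqrt{\cos\theta}$, rotation of the polarization
into the meridional frame, and a zoom transform onto the focal window. It
reproduces the classic results the package's design studies revolve around:
the on-axis longitudinal maximum of a tightly focused radially polarized
doughnut and the x-elongated spot of a linearly polarized pupil. We chose
Richards--Wolf over propagating through an explicit thick-lens phase because
it is the community-standard model of "a high-NA objective" and converges to
the scalar Airy pattern as NA goes to zero (checked at NA = 0.05 within 2%).

## Elements and imperfections

All elements are Jones-calculus operators applied pixel-wise:

* **SLM / super-SLM** -- `exp(1i * mask)` on the selected polarization
  component; the super-SLM addresses H and V with independent panels (2 SLM
  panels per sSLM in every audit).
* **Wave plate** -- $J = R(\theta)\,\mathrm{diag}(e^{-i\eta/2},
  e^{+i\eta/2})\,R(-\theta)$ with retardance $\eta$ and orientation
  $\theta$.
* **Tunable beam splitter** -- the symmetric lossless scattering
  $c = \sqrt{T}a + i\sqrt{R}b$, $d = i\sqrt{R}a + \sqrt{T}b$. The
  literature never fixes a phase convention; any lossless choice is
  observationally equivalent for detected intensities, and the $i$-on-
  reflection form keeps the matrix symmetric. A polarizing variant
  (H transmits, V reflects) is available behind a flag.
* **Radial polarization converter** -- an azimuthally varying half-wave
  plate whose fast axis sits at $(\varphi + \alpha)/2$; a linear input at
  angle $\alpha$ emerges radially polarized. The map is linear in the field
  (so it is differentiable inside optimized setups) and the undefined
  on-axis pixel is zeroed by convention.

The imperfection model (`noise_model`) applies per-pixel uniform phase noise
to SLMs (a scalar draw on wave plates, entering the retardance only unless
`perturb_theta` is set), band-limited transverse translation of masks by a
uniform misalignment draw, multiplicative perturbation of splitter ratios
renormalized to lossless, and optional 8-bit quantization of mask phases.
The "standard experimental conditions" envelope uses half-ranges 0.05 rad
and 0.05 mm with 1% splitter imperfection -- the midpoints of the
$\pm(0.01$--$0.1)$ device-quality band -- and the stress envelope uses the
midpoints 0.55 rad / 0.55 mm of $\pm(0.1$--$1)$. All draws derive from the
model's seed through a private RNG stream, so every element is
bit-reproducible and the global RNG is never disturbed.

## The grid ansatz

`ansatz_spec(rows, cols)` describes a lattice of tunable beam splitters in
which light flows up and to the right: node $(i,j)$ mixes its south and west
inputs into north and east outputs. Every internal edge *and* every external
stub hosts one building unit -- super-SLM, distance $z_1$, wave plate,
distance $z_2$, in that order. Sources feed the lower/left stubs and
detectors (high-NA objectives focusing onto camera windows) terminate the
upper/right stubs. This wiring is the unique assignment that reproduces the
canonical 3x3 audit: 9 splitters, 12 internal edges + 12 stubs = 24 units,
hence 24 super-SLMs (48 panels) and 24 wave plates, with 6 source and 6
detector ports. Because splitter ratios can reach $T = 1$ or $T = 0$,
continuous optimization can switch whole paths on and off: discrete topology
search becomes smooth descent. Snapping each splitter to
transmit/reflect/split and each SLM panel and wave plate to on/off gives
$3^{9} \cdot 2^{48} \cdot 2^{24}$ discrete layouts for the default lattice,
a number we carry in exact arbitrary precision (`count_discrete_layouts`)
because it overflows doubles.

Sources of equal wavelength superpose coherently; different wavelengths are
mutually incoherent and add in intensity at the detectors -- the forward
model propagates each wavelength group independently through the same
network.

## Losses

The exploration loss is the inverse intensity density: with threshold
$\varepsilon\, i_{\max}$ (default $\varepsilon = 0.5$), pixels strictly above
threshold contribute their intensity to $I_\varepsilon$ and one unit each to
the Area, and the loss is $\mathrm{Area}/I_\varepsilon$. Minimizing it
concentrates detected light into few bright pixels. The gradient flows
through the retained pixel values; the pixel selection and the Area factor
are piecewise constant, so the Area acts as an adaptive scale -- larger
spots produce larger gradients. Strict inequality excludes threshold ties;
a sigmoid-softened variant is available behind `soft_threshold`. Detectors
are aggregated with the numerically stable soft minimum
$-\log\sum e^{-\beta \ell_d}/\beta$ (default $\beta = 100$), which lets the
best detector drive the update while staying smooth; both defaults are
config-exposed since the published forms leave the constants free.

Stimulated emission depletion is modelled without time-dependent kinetics by
a Beer--Lambert attenuation: $I_\mathrm{eff} = I_\mathrm{exc}
\exp(-\alpha\, I_\mathrm{dep}/\max I_\mathrm{dep})$. Normalizing by the
depletion maximum makes $\alpha$ a pure shape parameter; the default
$\alpha = 10$ makes the spiral-phase reference clearly sub-diffraction. The
adjoint treats the arg-max pixel of the normalization exactly (it is locally
constant almost everywhere), so the objective's gradient matches finite
differences everywhere off ties. The data-driven imaging loss is the mean
squared error between detected and target intensity patterns, both
normalized to unit total intensity so the objective is scale-free.

## The adjoint engine and the optimizer

No automatic-differentiation framework exists in this R stack, and the
differentiable simulation is the heart of the method, so the reverse-mode
engine is hand-written (`R/engine.R`). Every forward pass records a tape of
primitive operations on complex rasters -- phase multiplication, scalar
mixing (splitters, Jones rows), RS hops, zoom transforms with explicit
adjoints -- and the backward pass pulls Wirtinger cotangents
$g = \partial L/\partial \bar v$ through them, depositing
$\partial L/\partial p = 2\,\mathrm{Re}\sum \bar g\, \partial v/\partial p$
on each named parameter. Distances are differentiated through the analytic
$\partial H/\partial z$ of whichever kernel branch is active. Every rule is
validated against central finite differences (worst relative error below
$10^{-4}$ across all parameter families).

Optimization is AdamW with two learning-rate groups ($10^{-2}$ for scalar
families, $10^{-1}$ for phase rasters), a 1000-step default budget, early
stopping when the best loss moves less than $10^{-5}$ relative over a
50-step window, and random restarts ranked by final loss. Distances are
re-parameterized through a softplus (kept positive) and splitter ratios
through a logistic (kept in $(0,1)$), both invisible at the interface. The
initialization ranges are uniform: ratios on the lossless simplex, distances
in 1--100 cm, phases and wave-plate angles in $(-\pi, \pi]$. Runs are
deterministic given the seed, abort cleanly on non-finite losses, and resume
exactly from their stored optimizer state.

## Presets, scaled conditions, and what the tests show

The bundled presets reproduce the canonical design studies at reduced
computational scale. The preset grids keep a fixed physical width of
2.56 mm; `resolution` (default 64) only changes the sampling. The
fixed-mask topology presets expose exactly 25 scalars -- all 9 splitter
ratios plus the distances ($z_1, z_2$) and wave plates of the four building
units adjacent to the active ports. Which stubs carry the frozen masks is
not derivable from the published figures, so it is preset configuration: the
STED preset freezes a charge-1 spiral on the depletion source stub; the
sharp-focus preset freezes the radial converter and a spiral on the two
source-side stubs. The highly parameterized presets activate three
super-SLMs (six panels), three wave plates and eight distances, which at
the full 824x824 SLM resolution is the 4,073,870-parameter configuration;
the scaled runs use the same structure at 64x64.

Deliberate scaling choices (stated here as the package's own problem sizes):
discovery smoke runs use 64x64 grids, 120--200 steps and 2--3 restarts; the
data-driven magnifier trains at 32x32 with 20 pairs in batches of 10; the
reference 4f relay is validated at 512x512. The synthetic data generator
emulates the published training regime -- random binary shapes, mildly
low-pass filtered so a diffraction-limited relay can actually realize the
task, with the target being the imaged intensity under the ideal
point-reflected 2x map -- and holds out the triangle and the logo-like blob
silhouette for evaluation (the blob is a seeded synthetic stand-in for a
non-redistributable logo). What passing tests show is that the machinery
(propagators, gradients, losses, optimization loop) is correct and that the
scaled studies reach their qualitative goals (sub-diffraction effective
beams, longitudinally dominated spots, 5--10x loss reductions). They do not
show that full-scale runs reproduce specific published masks or
percent-level spot-size improvements: those are stochastic outcomes of
cluster-scale optimizations and are out of scope here.

## Numerical choices and degenerate inputs

* Zero-padding to twice the linear size before every convolution; the
  containment warning fires when more than 1% of the power sits in the
  outer 10% frame.
* The dual-domain switch at $z_c = P \Delta x^2 / \lambda$; a conservative
  sampling warning fires for short hops in the impulse-response regime.
* FWHM estimation interpolates the half-maximum crossings of the
  cross-sections through the peak pixel (deterministic; no 2-D fitting);
  `center = "axis"` measures the central lobe and raises an "unresolved
  spot" error for doughnuts. Exact on-axis statements need a pixel on the
  axis, i.e. odd rasters.
* Splitter ratios are clamped to $[10^{-9}, 1-10^{-9}]$ inside the
  scattering coefficients so the $1/\sqrt{T}$ derivatives stay finite at
  the discovered extremes.
* Mask-pixel gradients under an active misalignment model use the
  zero-shift approximation; discovery runs are noiseless, so the case that
  is optimized is exact.
* All-dark detectors contribute nothing to the soft-min (an all-dark
  network is an error); zero-step budgets return the initialization
  unchanged; `z = 0` hops are identities.

## Limitations

Monochromatic, fully coherent sources only (per-wavelength propagation with
incoherent detector sums); no amplitude-modulating SLMs, no media with
varying refractive index, no photon-count noise; the depletion model is a
deliberately simple Beer--Lambert surrogate with $\alpha$ as its single
shape parameter; field serialization uses plain-text CSV/JSON containers
rather than a binary format.
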