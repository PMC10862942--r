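---
title: "Single-mask differential phase contrast: model, retrieval and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-mask differential phase contrast: model, retrieval and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smpci)
```

## The imaging problem

X-ray attenuation contrast is weak for soft, low-Z materials, but the phase
shift such materials impose on the beam is typically three orders of
magnitude larger than their absorption. Single-mask differential phase
contrast (DPC) imaging converts that phase information into intensity with
one simple optical element: a periodic absorption mask (thin gold strips on
a substrate) placed upstream of the object, with period equal to **twice**
the detector pixel pitch and slit centres aligned to every other pixel
boundary. With this alignment an empty beam illuminates all pixel columns
equally; when an object refracts the beamlets, intensity is redistributed
between the two pixels flanking each slit, producing alternating bright and
dark column fringes whose amplitude is proportional to the local refraction
angle.

`smpci` implements the full chain for this modality: analytic projection
phantoms, a Fourier-series mask model, the transport-of-intensity (TIE)
forward model in both a directly integrated and a closed two-coefficient
form, a single-shot retrieval that separates a propagation-based (PB) image
and a DPC image from one exposure plus one flat field, and an independent
angular-spectrum wave-optics simulator used as a validation oracle.

## Image formation model

Linearising free-space intensity transport over a distance $z$ gives

$$ I(z) \;=\; I(0) \;-\; \frac{z}{k}\Big( \nabla_\perp I(0)\cdot\nabla_\perp\phi
   \;+\; I(0)\,\nabla_\perp^2\phi \Big), $$

with $k = 2\pi/\lambda$ the wavenumber and $\phi$ the object-induced phase
shift. Without a mask the gradient term is negligible for slowly varying
objects and one obtains the familiar propagation-based edge enhancement
$I = T(1 - \tfrac{z}{k}\nabla^2_\perp\phi)$. With a high-contrast mask
$M(x)$ multiplying the object transmission $T$, the intensity gradient is
dominated by the mask, $\nabla_\perp I(0) \approx T\,\partial_x M$, and
integrating over the footprint of pixel $n$ yields three terms
(transmission, gradient coupling, Laplacian coupling). Assuming $T$,
$\partial_x\phi$ and $\nabla^2_\perp\phi$ vary slowly within a pixel, the
whole mask enters through just two integrals over one pixel:

* $\int_{np}^{(n+1)p} M\,\mathrm{d}x = C_0\,p \equiv w_e$, the **effective
  aperture** (the per-pixel transparent width), and
* $\int_{np}^{(n+1)p} \partial_x M\,\mathrm{d}x = M((n{+}1)p) - M(np) =
  -\alpha(-1)^n$, with $\alpha = 2\sum_m C_{2m+1}$ the **mask contrast**,

where $C_m$ are the cosine-series coefficients of $M$ on the period $2p$.
The pixel signal becomes the closed form implemented by
`single_mask_image_closed_form()`:

$$ I_n \;=\; w_e\,T_n\,(1 - L_n) \;+\; \mathrm{par}\cdot(-1)^n\,
   \alpha\,T_n\,D_n, $$

with $T_n$ the pixel-averaged transmission, $L_n = \tfrac{z}{k}
\nabla^2_\perp\phi$ the Laplacian (edge-enhancement) term and $D_n =
\tfrac{z}{k}\partial_x\phi$ the **beamlet displacement** at the detector —
propagation distance times refraction angle, in metres. The first term is
the PB channel filtered by $w_e$; the second is the DPC channel, an
alternating fringe whose sign flips between adjacent columns.

### Sign and parity conventions

Two conventions are fixed once and used consistently everywhere:

* **Phase sign.** X-rays are phase-retarded ($n = 1-\delta$), so a
  projected thickness $t$ gives $\phi = -k\,\delta\,t \le 0$. Flipping this
  convention flips only the sign of the retrieved $D_n$.
* **Fringe parity.** With slit centres at even pixel boundaries
  ($x = 2jp$) and 0-based indexing starting at such a boundary, carrying
  the pixel integrals through gives the **plus** sign above with
  $\mathrm{par} = +1$: a positive displacement brightens even columns. The
  same model with the index origin shifted by one pixel is the
  conventional minus-sign form, available as `parity = -1`. The wave-optics
  simulator and the pixel-integrated model both realise the $+1$
  convention, and the package verifies they agree.

## Retrieval

Flat-field correction divides the sample image by the mask-only image
(uniform at $w_e$), giving
$\bar I_n = T_n(1-L_n) + \mathrm{par}(-1)^n \tfrac{\alpha}{w_e} T_n D_n$.
Adding and subtracting adjacent columns separates the channels:

$$ \widehat{T(1-L)} = \frac{\bar I_n + \bar I_{n+1}}{2}, \qquad
   \widehat{D} = \mathrm{par}\,(-1)^n\,\frac{w_e}{\alpha}\,
   \frac{\bar I_n - \bar I_{n+1}}{\bar I_n + \bar I_{n+1}}. $$

The prefactor of the displacement estimator is $w_e/\alpha$ (not
$\alpha/w_e$): dividing the pair difference by the pair sum cancels
$T_n(1-L_n)$ and leaves $\tfrac{\alpha}{w_e} D_n$, which must be rescaled by
$w_e/\alpha$. The $1-L_n \approx 1$ approximation is used only in this
second formula.

`retrieve_pb_dpc()` offers two pairings. **Disjoint** pairing (default)
uses pairs $(2j, 2j+1)$ — one estimate per slit, statistically independent,
at half resolution, each assigned the pair-boundary coordinate $(2j+1)p$
(the slit/strip centre between the two pixels). **Sliding** pairing uses
every adjacent pair, restoring full-width output at the price of correlated
neighbours; how to composite half-resolution pair estimates into
full-resolution images is a presentation choice, so the package keeps the
per-pair values and records the pairing in the result. Pairs containing
masked or near-zero-sum pixels propagate as `NA`.

## Phantoms and material constants

Three phantom families provide analytic ground truth: a solid cylinder
(rod) with chord-length thickness $t(x) = 2\sqrt{R^2 - x^2}$, a nested
tube/fill/rod composite, and a band-limited Gaussian bump for
approximation-error studies. All are sampled on a fine grid of `s`
sub-cells per pixel (default 16; 32–64 where the mask or the wave
simulator must be resolved), with derivatives taken by second-order central
differences.

The design energy defaults to 20 keV as a monochromatic stand-in for a
40 kVp tube spectrum; the effective energy of such a spectrum is not
uniquely defined, so the energy is an explicit configuration value. The
built-in material table at 20 keV (PMMA $\delta = 6.66\times10^{-7}$,
$\mu = 68\,\mathrm{m^{-1}}$; water $5.76\times10^{-7}$,
$81\,\mathrm{m^{-1}}$; polycarbonate $6.57\times10^{-7}$,
$65\,\mathrm{m^{-1}}$) was computed from electron densities via
$\delta = r_e \lambda^2 \rho_e / 2\pi$ and standard mass-attenuation
tabulations; values are approximate and overridable via
`xray_material()`. The geometry defaults (0.6 m propagation, 55 µm pixels,
7 µm source spot, 3 mm PMMA rod) mirror a typical table-top single-mask
setup. The model is parallel-beam; cone-beam magnification is outside the
pixel model and is not applied implicitly.

## The wave-optics oracle

`wave_image()` validates the transport model independently: the exit field
$U = \sqrt{T\,M(x)}\,e^{i\phi}$ is propagated with the exact scalar
angular-spectrum transfer function $\exp(i k z (\sqrt{1-(\lambda f)^2}-1))$,
the intensity is blurred with the projected source Gaussian (7 µm FWHM
default) and binned into pixels. Design choices:

* Propagation is 1-D in $x$, row by row, because the mask modulation is
  one-dimensional and the phantom's $y$ scales are far larger than the
  diffraction scale $\sqrt{\lambda z}\approx 6\,\mu\mathrm{m}$.
* FFT boundary conditions are periodic; a guard band of 8 mask periods per
  side cosine-tapers the object deviation to an empty beam so the
  wrap-around is consistent, and is cropped before binning. An even pixel
  count keeps a whole number of mask periods across the wrap.
* Binary masks are evaluated with their exact square-wave profile inside
  the simulator (the truncated Fourier series overshoots at the jumps —
  Gibbs — and its square root would be undefined), while the transport
  model uses the series coefficients.
* The oracle is monochromatic and noise-free; Poisson noise is applied
  separately by `add_poisson_noise()`.

For smooth weak phantoms at the reference geometry the flat-corrected
profiles of the two models agree to an RMS relative difference of a few
$10^{-4}$ with identical fringe parity for both an ideal square mask and
the smooth cosine mask $M = \tfrac12 + \tfrac12\cos(\pi x/p)$ (for which
$w_e = p/2$ and $\alpha = 1$ exactly); the test suite asserts agreement at
a conservative 5 % and the `validate` workflow reports the measured values.

## Numerical choices

* Binary-mask series truncation defaults to 256 harmonics; the
  alternating-series remainder bounds the contrast error by
  $4/(\pi N)$. The physical-range check $M \in [0,1]$ is enforced by dense
  sampling (4096 points/period) with a documented ripple allowance for
  series-represented discontinuous masks (Gibbs overshoot is ~9 % of the
  jump).
* Closed-form pixel operations require an aligned mask (`offset = 0`) and
  reject misaligned specs; misaligned masks remain representable for the
  wave simulator.
* Pixel averaging is an exact block mean of midpoint samples; it preserves
  the global mean to machine precision and is midpoint-exact for linear
  fields.
* The flat-correction division guard masks pixels with flat values below
  $10^{-6}\times$ the flat median; guarded pixels propagate as `NA`.
* Raw detector images carry units of length (metres, bounded by $p$), so
  flat correction is exactly dimensionless. They are written as 32-bit
  TIFF (quantised on $[0,1]$ at $2^{-32}$, i.e. $2.3\times10^{-10}$
  absolute); signed and dimensionless maps are written as full-precision
  CSV, which round-trips exactly.
* All randomness (Poisson noise) flows through one integer seed and is
  recorded in the run metadata; the caller's RNG state is never disturbed.

## What the tests do and do not show

The synthetic generator emulates monochromatic, parallel-beam, scatter-free
imaging of smooth objects with an ideal energy-integrating detector.
Passing tests therefore demonstrate the internal consistency of the model
chain (closed form ↔ direct pixel integration ↔ wave optics ↔ retrieval)
under those conditions; they do not address polychromatic spectra and
beam-hardening, detector point-spread/charge sharing, scatter or
dark-field signal, cone-beam magnification, or mask fabrication errors
beyond what the Fourier coefficients encode. Problem sizes used by the
test suite and the acceptance script — 64–256 pixel columns, 2–8 rows,
oversampling 8–64 — were chosen as the smallest grids on which each
property is resolved.

## Known limitations

* **Attenuation-gradient crosstalk.** The pair-difference estimator
  assumes $T_n \approx T_{n+1}$. A smooth attenuation gradient therefore
  leaks into the displacement channel with first-order bias
  $-\mathrm{par}\,(-1)^n \tfrac{w_e}{\alpha}\,
  \tfrac{p}{2}\,\partial_x \ln\!\big(T(1-L)\big)$ evaluated per pair. For a
  single-material object both $D_n$ and $\partial_x \ln T$ are proportional
  to the projected-thickness derivative, so the bias is a uniform
  multiplicative factor $w_e\,p\,\mu/(2\alpha z\delta)$ relative to the
  true displacement — about 13 % for PMMA at the reference geometry
  (55 µm pixels, 0.6 m, 20 keV, cosine mask). The retrieved profile
  *shape* is unaffected for such objects, and pure-phase or uniform
  objects are recovered to well below 1 %; the test suite measures both
  behaviours and the acceptance script reports the measured cylinder bias
  rather than hiding it. Equivalently: an attenuation-only object with a
  spatial gradient yields a spurious, smooth (non-alternating)
  displacement signal of the same origin.
* The closed form inherits the slow-variation assumption: its discrepancy
  against direct pixel integration grows quadratically as feature scales
  approach the pixel size, and the model is outside its regime when
  $|\alpha T_n D_n| > w_e T_n(1-L_n)$ (negative intensities; the package
  warns rather than clips).
* The retrieval performs no phase integration (recovering $\phi$ from
  $D_n$ is out of scope) and no dark-field/scatter channel.

## A worked example

```{r example, eval = FALSE}
g  <- imaging_geometry(z = 0.6, p = 55e-6, nx = 128, ny = 4, energy = 20, s = 16)
mk <- cosine_mask(g$p)
co <- mask_coefficients(mk)           # we = 27.5 um, alpha = 1

rod    <- make_cylinder_phantom(1.5e-3, builtin_material("pmma"), g)
fields <- compute_pixel_fields(rod, g)
img    <- single_mask_image_closed_form(fields, co)   # fringed raw image
flat   <- flat_field_image(co, g)

pair <- retrieve_pb_dpc(flat_correct(img, flat), co)  # PB + DPC channels
theta <- dpc_to_refraction(pair, g)                   # refraction angles
```

The same pipeline is scripted by the `smpci` command-line tool
(`smpci simulate`, `smpci retrieve`, `smpci validate`) driven by a YAML
configuration with explicit units.
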