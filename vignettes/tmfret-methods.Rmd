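---
title: "Models and methods behind tmfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tmfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmfret)
```

## The measurement

Transition-metal FRET replaces the usual organic acceptor dye with a bound
Cu²⁺ or Co²⁺ ion. These ions absorb weakly, so the Förster radius is short
(10–25 Å) and the technique resolves distances on the scale of individual
protein domains. The donor is L-ANAP, a small fluorescent amino acid placed
at a chosen residue by amber-codon suppression; the acceptor is either a
metal held by a TETAC chelator reacted onto one cysteine (point geometry) or
metals held by NTA-lipids distributed through the plasma membrane (planar
geometry). Experiments are done on unroofed cells — membrane sheets on
glass — imaged three times: before metal, with metal bound, and after the
metal is stripped with DTT or EDTA.

## From spectra to the Förster radius

The overlap integral uses the donor's *normalized* emission,

$$J = \frac{\int f_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,d\lambda}
          {\int f_D(\lambda)\,d\lambda},$$

so raw emission units cancel; `overlap_integral()` interpolates linearly
onto the union grid restricted to the wavelength intersection and applies
the trapezoidal rule (no extrapolation). Acceptor extinction comes from
replicate absorbance scans averaged pointwise and converted by Beer–Lambert
(`extinction_from_absorbance()`). The Förster radius is

$$R_0 = C\,(J\,Q\,\eta^{-4}\,\kappa^2)^{1/6}$$

with defaults `Q = 0.22` (the donor's quantum yield in stabilization
buffer), `kappa2 = 2/3` (dynamic isotropic orientation) and `eta = 1.33`.
The scaling constant `C = 0.2108` is the standard value giving R0 in Å when
J is in M⁻¹cm⁻¹nm⁴; it is exposed in `fret_calibration()` rather than
hard-wired because conventions differ between unit systems. The published
radii for the two acceptor chemistries (17.6/17.2 Å point, 12.4/12.6 Å
planar, at the resting and acidified conditions) cannot be recomputed
without the measured spectra, which are not distributed; the package treats
them as *inputs* to the distance stage, and tests the J→R0 path against a
closed-form Gaussian-band overlap and an algebraic inversion instead.

## Image quantification

Per cell and stage, the mean gray value of a cell-free background ROI is
subtracted from the cell ROI mean, and stages are normalized to the
pre-metal image. Photobleaching is estimated from *mock* experiments — the
full wash-and-image protocol with no metal — as the mean normalized
second-image fluorescence, pooled across donor positions within one pH
condition. Efficiency is then

$$E = 1 - \frac{F_{\mathrm{FRET}}}{F_{\mathrm{bleach}}}.$$

Negative efficiencies (no-quench Zn²⁺ controls, which bind the chelators
but do not absorb) are preserved and flagged, never used to adjust the
metal groups. Cells whose pre-metal signal does not exceed 3× the
background SD are excluded with a logged reason; the threshold is a
numerical stand-in for the experimenter's qualitative rejection of
non-unroofed cells, and is configurable. SEM uses the n−1 sample SD; with
one cell it is reported as 0 with N = 1 visible in the table.

## Distances

**Point geometry.** `distance_from_efficiency_point()` inverts the Förster
equation and reports the nearest integer Ångström (half away from zero),
keeping full precision internally. Non-positive efficiencies return a typed
no-distance result (`"N/A"`), not NaN.

**Planar geometry.** With acceptors a 2D Poisson field of density σ at
closest approach d, the donor's relative steady-state fluorescence in one
acceptor configuration is \(1/(1+K)\), \(K=\sum_i (R_0/r_i)^6\). Averaging
over configurations with the identity
\(1/(1+K)=\int_0^\infty e^{-\lambda(1+K)}d\lambda\) gives

$$E(d) = 1 - \int_0^\infty e^{-\lambda}
  \exp[-\sigma S(\lambda,d)]\,d\lambda,\qquad
S(\lambda,d)=2\pi\int_d^\infty\left[1-e^{-\lambda(R_0/s)^6}\right]s\,ds.$$

The inner integral is mapped to the finite domain \(u=(d/s)^2\) and both
levels use `stats::integrate` at relative tolerance 1e-6. Inversion is by
bisection on \([d_{\mathrm{floor}}, 10R_0]\); efficiencies at or above the
model value at `d_floor = 5` Å are reported as "≤5" — at that point the
donor is effectively within the headgroup layer and the model's geometric
premise has run out. A mean-rate ("rate-sum") closed form
\(E = 1/(1+2d^4/(\pi\sigma R_0^6))\) is provided as a documented
alternative: it upper-bounds the configurational average (Jensen's
inequality) and brackets the model ambiguity in prior planar-FRET
treatments. The configurational average is the default because the theory
being applied is an ensemble average; the published planar distances are
consequently reproduced only to within a couple of Ångström and are *not*
treated as exact targets.

`mc_planar_oracle()` is an independent check, not an implementation detail:
it simulates explicit Poisson acceptor fields in a disc (default radius
\(10R_0+d\), chosen so the truncated far field contributes well below the
Monte-Carlo standard error at 10⁵ configurations) and compares
\(1-\langle 1/(1+K)\rangle\) with the quadrature result. The surface
density itself is calibrated by `calibrate_surface_density()`, solving the
forward model for σ given the measured quenching of a lipid-anchored probe
at known height — the same experiment used to establish σ ≈ 0.002 Å⁻².

## pH activation

Activation is fit per cell with the Hill-type curve

$$I = \frac{1}{1 + 10^{(pH_{0.5}-pH)\,n}},$$

which is 0.5 at the midpoint for any slope. As printed, an acid-activated
channel (current grows as pH falls) requires a *negative* fitted n; the fit
is unconstrained and starts from both slope signs (keeping the better
optimum) so inverted or non-activating cells surface as `n > 0` with a
warning instead of a silent bad fit. Initialization takes the midpoint from
linear interpolation of the half-max crossing and n₀ = −3. Optimization is
BFGS on the residual sum of squares with an analytic gradient — chosen over
`nls()` because noiseless synthetic data (zero residual) must converge to
machine precision without error. The saturating pH 5.5 point participates
in the fit by default; `exclude_pH` removes it for sensitivity checks.

## The synthetic world

`gen_imaging_bundle()` encodes the three-stage protocol with ROI-mean
expectations

$$F_1 = S + B,\quad F_2 = S\,b\,(1-q) + B,\quad F_3 = S\,b^2 r + B,$$

(signal S, background B, per-stage bleach b, quench q, reversal r) and
per-pixel Poisson noise applied after the background is added, matching
camera counting statistics and making standard errors predictable. Defaults
are the conditions the analysis is specified against: S = 10⁴ expected
counts per ROI pixel, b = 0.9 per stage, r = 1 (full reversal), B = 50
counts. One seed governs a bundle; per-cell substreams derive from it, so
bundles are bit-reproducible. Spectra are Gaussian bands (analytic overlap
available for cross-checks); dose-response families place Gaussian noise of
SD 0.03 on the normalized Hill response, clipped at zero — noise is modeled
after normalization, so the separate `normalize_currents()` operation
handles raw-current input.

What the generator does *not* emulate: cell morphology, partial unroofing,
non-specific membrane binding of the chelator lipid, membrane deformation
around the protein, or donor photophysics beyond a constant per-stage
bleach factor. A green recovery test therefore establishes that the
pipeline algebra and statistics are right, not that those biological
confounds are absent.

## Numerical choices and limitations

* Quadrature tolerances: 1e-6 relative for the planar integral; bisection
  to 1e-6 in E (and ≤1e-9 Å interval) for inversion; density calibration by
  `uniroot` to machine tolerance in σ.
* Rounding: distances reported to nearest integer Å, half away from zero.
  A table built from rounded mean efficiencies can disagree with one built
  from unrounded means by 1 Å near a rounding boundary; the package keeps
  full precision internally for exactly this reason.
* The planar model assumes acceptors are randomly arranged and unperturbed
  by the protein; lipid binding to the protein or membrane deformation
  would concentrate acceptors and bias distances short. The steep r⁻⁶
  weighting also means the closest-approach configurations dominate mobile
  domains' signals.
* Beyond-range results ("≤5") and control groups ("N/A") are typed results
  throughout the pipeline, so downstream tables never contain accidental
  NaNs.
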