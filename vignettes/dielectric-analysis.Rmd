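---
title: "Dielectric relaxation of a glass former under temperature and pressure: models, estimators, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dielectric relaxation under temperature and pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdsfit)
```

This vignette is the package's own account of the science it implements:
the spectral models and their conventions, the estimators, the synthetic
study that everything is validated against, the numerical choices, and the
known limitations. No number quoted here is asserted anywhere else; every
empirical statement is recomputed by the test suite or by
`scripts/acceptance.R`.

## 1. The physical picture

A supercooled liquid approaching its glass transition shows a structural
(α) relaxation whose time τ_α grows from picoseconds to ~100 s at Tg, a
dc-conductivity contribution from ionic impurities and (in hydrogen-bonded
systems) proton hopping, and — in the glassy state — weak secondary
relaxations: a slow β-process of the Johari–Goldstein kind involving the
whole molecule, and a faster intramolecular γ-process. Pressure is the
second axis: compression slows the α-process (quantified by dTg/dp and by
activation volumes), while truly local processes barely feel it. The
package implements the analyses by which broadband dielectric spectroscopy
(BDS) turns measured loss spectra ε″(f; T, p) into these statements.

## 2. Spectral model and conventions

A spectrum is fitted to dc-conductivity plus Havriliak–Negami (HN)
processes,

$$\varepsilon''(\omega) = \frac{\sigma_{dc}}{\varepsilon_0\omega} +
\sum_k \mathrm{Im}\,\frac{\Delta\varepsilon_k}
{[1+(i\omega\tau_{HN,k})^{\alpha_k}]^{\gamma_k}}.$$

Conventions that the code pins in exactly one place each:

* **Loss sign.** The HN term's imaginary part is taken with the loss-positive
  convention; the high-frequency permittivity ε∞ enters only the real part
  and therefore never appears in loss fitting.
* **Frequencies.** All stored grids are ordinary frequencies in Hz; every
  lineshape formula works in angular frequency; the single conversion
  ω = 2πf lives in `model_loss()` (and the classic silent-2π bug lives
  nowhere).
* **Conductivity units.** σ_dc is carried in S/cm, the unit BDS papers
  report; the S/cm → S/m factor of 100 is applied once, next to the CODATA
  value of ε₀ (see `bds_constants`).
* **Relaxation times.** Fitted HN times are converted to model-free
  loss-peak times by the analytic peak identity
  τ_max = τ_HN [sin(πα/(2γ+2))]^(−1/α) [sin(παγ/(2γ+2))]^(1/α).
  Two equivalent printings of this identity circulate; rather than trusting
  either transcription the package pins its correctness by an invariant
  test against the numerical argmax of the loss curve (0.1 % over random
  shape draws).

## 3. The KWW transform

Shape analysis compares normalised α-peaks with the one-sided Fourier
transform of the stretched exponential Φ(t) = exp[−(t/τ)^β],
ε″(ω) = ∫₀^∞ (−dΦ/dt) sin(ωt) dt. The integrand oscillates badly at high
ωτ, so the package evaluates it on a rotated path: substituting
v = (t/τ)^β and taking t along the ray arg t = −π/4 gives an absolutely
convergent, essentially non-oscillatory integral valid for all β ∈ (0, 1]
(the integrand is entire and decays in the closed sector). Two practical
safeguards: the quadrature interval is split at the faster of the thermal
and frequency decay scales, so the adaptive rule cannot overlook a narrow
support at ωτ ≫ 1; and the tail beyond the split is dropped when its
analytic bound is exp(−40) of the peak scale. The implementation is
checked against two independent oracles — dense Simpson quadrature of the
real-axis integral for ωτ ≤ 10, and the convergent high-frequency series
Σ (−1)^{n+1} Γ(nβ+1)/n! sin(nπβ/2) (ωτ)^{−nβ} above — to a relative 10⁻⁴
over ωτ ∈ [10⁻⁴, 10⁴], and to the π Δε/2 normalisation sum rule.

## 4. Fitting protocol

**Objective.** All spectral fits minimise residuals in log₁₀ ε″. A loss
spectrum spans decades; least squares in linear ε″ would see only the
largest values, while the log objective weights the conductivity flank and
the peaks evenly.

**Multi-start.** The least-squares surface in (α, γ, log τ, log Δε) has a
narrow curved valley and well-known degenerate basins. `fit_spectrum()`
therefore starts from (i) peak-detected seeds with the conventional
(α, γ) = (0.8, 0.6) shapes, (ii) four fixed shape-space corners, each made
self-consistent by converting τ and Δε with its own shape, (iii) a
deterministic ladder of peak-time seeds across the window whenever no peak
is detectable (an α-peak can hide under a dominant conductivity flank),
and (iv) randomly drawn restarts under a fixed seed, with shape exponents
resampled over their whole range because local jitter cannot cross between
basins. Solutions whose relaxation time is pinned at its box bound are
power-law mimics of the conductivity term, not relaxations, and are
rejected whenever an interior solution converged. The restart seed is
fixed and restored, so fits are reproducible and do not disturb the
caller's random stream.

**Peak detection** operates on twice-smoothed log-loss with a topographic
prominence criterion (≥ 0.05 decades above the higher valley floor) and a
minimum peak separation of 0.4 decades; plain sign-of-derivative maxima on
noisy grids produce spurious seeds.

**Secondary relaxations** are deconvolved with the asymmetry exponent fixed
at γ = 1 (Cole–Cole), the conventional description of symmetric secondary
peaks. This is not cosmetic: with both shape exponents free, the weak
β/γ doublet (relative strengths a few per cent of the α-process) is not
identifiable at realistic noise, and the fit wanders between solutions
several decades apart. With the symmetry constraint the doublet round-trips
stably. In the pipeline the second component is seeded at a ladder of
offsets above the visible peak, which also serves as an absorber for the
flank of a mode whose maximum lies beyond the window; absorber components
of negligible strength, out-of-window components, and sub-decade
("unresolved") splittings never enter the relaxation map.

**Shape (KWW) fits** pin the model's peak position and height to the
normalised data maximum and float only β. The maximum itself is
interpolated by a parabola in (log f, log ε″) fitted over ±0.5 decade
around the discrete maximum — wide enough to average point noise, narrow
enough that the peak region is still parabolic. Points below 5 % of the
peak are excluded from shape fitting: decades below the maximum the
measured loss is dominated by secondary-process tails and dc-subtraction
residuals, not by the structural peak, and including them biases β
downward by several hundredths. For the same reason the
superpositioning protocol masks frequencies where the fitted conductivity
contributes more than half of the measured loss before subtracting it.

## 5. The τ(T, p) surface and its identifiability

The adopted pressure-extended Avramov surface is

$$\log_{10}\tau(T,p) = \log_{10}\tau_0 + \frac{C}{\ln 10}
\left(\frac{T_g(p)}{T}\right)^{a(p)},\qquad
a(p)=\alpha_0\left[1-\frac{C}{C_{p_0}}\ln(1+p/\Pi)\right],$$

with Tg(p) the closed-form curve quoted in the README. Its defining
property — built in, and enforced by an invariant test to 10⁻⁹ decades —
is that τ(Tg(p), p) is pressure-independent: Tg(p) is exactly the
isochrone of the surface.

One design decision deserves emphasis. At fixed pressure the model is
invariant under Tg₀ → k·Tg₀, C → C·k^(−α₀): with C free, Tg₀ is simply not
an identified parameter. The fit therefore constrains
C = ln10·(log₁₀τ_g − log₁₀τ₀) with the conventional τ(Tg) = 100 s
criterion (the level is an argument), which is the standard convention
that gives Tg its meaning. With that constraint the surface has six free
parameters, recovers its generating values exactly on noise-free data, and
under 0.05-decade noise on the study's own measurement grids recovers Tg₀
within 1 K and dTg/dp within 5 % (the closed form
dTg/dp|₀ = Tg₀ β/(α₀ Π) is cross-checked against a finite difference).
A single-isobar data set leaves Π unidentifiable and is flagged
ill-conditioned rather than silently fitted.

## 6. The synthetic study

`default_scenario()` defines the ground truth the pipeline is validated
against — a high-pressure BDS campaign on a hydrogen-bonded, drug-like
glass former:

| quantity | default | why |
|---|---|---|
| Tg₀ | 325 K (τ(Tg) = 100 s) | calorimetric Tg of the emulated system |
| dTg/dp at p→0 | 163 K/GPa (α₀ = 5, β = 0.6269, Π = 250 MPa, C/C_p0 = 0.075) | strong pressure sensitivity typical of H-bonded APIs |
| α-peak shape | HN(0.870, 0.496), constant in T and p | least-squares HN match to the KWW curve with β = 0.51; constancy is the superpositioning premise |
| Δε (α, β, γ) | 6, 0.3, 0.25 | polar molecule; small-amplitude secondaries; β at 5 % of α |
| E_β(p) | 66 + 0.043·(p−0.1) kJ/mol | reproduces 66/73.3/80.6 kJ/mol at 0.1/170/340 MPa and ΔV_β = 43 cm³/mol at any isotherm (linear E(p) ⇔ p-independent ΔV = dE/dp) |
| log₁₀ τ∞(β) | −18.6 | implied by pairing E_β = 66 kJ/mol with an Eyring entropy of ~105 J/(mol K) over the ambient glassy range |
| E_γ, log₁₀ τ∞(γ) | 38 kJ/mol, −15 | a local mode: smaller barrier; the prefactor places the γ-peak inside the window only below ~240 K at ambient pressure and beyond 10⁶ Hz at every elevated-pressure state point |
| γ pressure dependence | none | the insensitivity of intramolecular motion to density |
| FDSE | s = 0.65, σ^s·τ = 10^(−9.475) | mid-range of the 0.6–0.7 decoupling band; the constant anchors σ = 10^(−11.5) S/cm at τ_α = 10 ms so simulated dc flanks sit in realistic proportion to the α-peak across the window |
| grids | supercooled isobars 0.1/120/170 MPa, isotherms 347/381 K; glassy isobars 0.1/170/340 MPa, isotherm 273 K; f = 10⁻¹–10⁶ Hz at 10 pts/decade | the combined isobaric/isothermal design of a high-pressure campaign |
| noise | multiplicative, 0.01 decades (~2.3 %) | loss-proportional error typical of frequency-response analysers |

The generator always evaluates all processes; visibility in the window is
emergent (at 340 MPa the γ-maximum sits beyond 10⁶·(2π)⁻¹ s⁻¹ rather than
being removed). Relaxation strengths are constant in temperature by
default; a 1/T Curie law is available behind a flag but never analysed,
matching how such studies treat Δε.

What the generator does **not** emulate: electrode polarisation,
stray-capacitance artefacts, temperature gradients in the pressure cell,
physical aging of the glass, or any change of the α-peak shape with state
point. Passing tests therefore demonstrate the estimators' correctness and
stability under realistic noise and window truncation — not robustness to
every artefact of real cells.

Two quantitative notes on internal consistency of the emulated physics:

* A linear E_β(p) with a common prefactor **cannot** produce an exact
  Tg-scaled collapse of the β-branches: collapse requires
  E_β(p) ∝ Tg(p), and Tg(p) is sublinear while E_β(p) here is linear (and
  steeper: +22 % at 340 MPa versus +12 % for Tg). The default scenario
  accordingly fails the 0.2-decade collapse criterion (spread ≈ 1.3
  decades) and shows an isochronal α/β ratio drifting by ~0.4–0.6 decades
  between ambient pressure and 170 MPa. The collapse and isochronal
  diagnostics are therefore exercised in the tests on purpose-built
  scenarios (E_β ∝ Tg(p) → collapse; p-independent E_β with rising Tg →
  violation), and the default scenario documents the tension rather than
  hiding it.
* The Eyring entropy reported by the pipeline (~105 J/(mol K) at ambient
  pressure) is a derived consequence of the (E_β, τ∞) pair above, not an
  independent dial; ΔH_β comes out ≈ E_β − R·T̄ ≈ 64 kJ/mol, the standard
  relation between the two reductions, bracketed exactly by
  [E − R·T_max, E − R·T_min] in the tests.

## 7. Degenerate and edge inputs

* Spectra whose maximum sits on the grid edge are flagged by
  `peak_stats()` and their normalisation marked unreliable.
* `subtract_dc()` clips non-positive residual points to a configurable
  floor and counts them; shape fits exclude the clipped region via the 5 %
  rule.
* The relaxation-map stage keeps only converged fits whose log-space RMS is
  below 0.05 decades (five times the noise floor: anything above means the
  template cannot describe the spectrum, typically because the peak has
  left the window) and whose peak frequency lies inside, or for the
  α-process marginally below, the window.
* Arrhenius/Eyring/activation-volume fits run a Wald–Wolfowitz runs test on
  residual signs and flag systematic curvature (non-Arrhenius behaviour)
  instead of failing.
* `fdse_map()` groups state points into isobars/isotherms with 1 MPa / 0.1 K
  tolerance and skips conditions with fewer than three points, reporting
  them.
* Branch labelling below Tg uses two-line Arrhenius clustering: spectra
  showing two peaks anchor the β- and γ-lines (slower = β, the naming-by-
  slowness convention), single-peak fits join the nearer line; no ground
  truth is consulted.

## 8. Problem sizes

The default study simulates and deconvolves 123 spectra of 71 points in
about 15 s. The test suite holds ~1700 assertions including 50-replicate
surface closures, 500-replicate regression-bias checks, 75 random
deconvolution round-trips and the full oracle sweeps, and runs in well
under a minute; `scripts/acceptance.R` completes in a few seconds. These
sizes were chosen so that the full verification loop stays interactive
while every estimator is exercised across its operating range.

## 9. Known limitations

* The HN deconvolution assumes additive processes and no electrode
  polarisation; strongly overlapping α- and β-processes near Tg are
  returned with an "unresolved" flag rather than separated by an
  extended-coupling model.
* The KWW/TPS machinery floats only the stretching exponent with the peak
  pinned; a floating-normalisation variant would absorb normalisation
  noise at the price of a less interpretable β.
* `fit_avramov_surface()` commits to the τ(Tg) = 100 s convention; if a
  different isochrone criterion is scientifically appropriate it must be
  passed explicitly, and C is then defined relative to it.
* The FDSE exponent from the full spectral pipeline carries a small upward
  bias (~+0.03) inherited from fitting the α-peak under a dominant
  conductivity flank at the hottest state points; the closure on the
  relaxation map itself is exact to 10⁻¹⁰.
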