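---
title: "A temperature-gradient threshold model for pulsed-laser single-cell permeabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A temperature-gradient threshold model for pulsed-laser single-cell permeabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoporation)
```

## The problem

Tightly focused near-infrared femtosecond lasers can permeabilize the plasma
membrane of an individually targeted cell — letting otherwise impermeant
molecules such as propidium iodide enter — without harming its neighbours.
At 1550 nm the photon energy is too low, and the free-electron yield too
small, for the plasma-mediated poration mechanism usually invoked at 800 nm.
An alternative mechanism is *thermoelectrically guided
electropermeabilization*: absorption in water heats the focal volume, each
ultrashort pulse drives a steep transient temperature gradient across the
~7 nm plasma membrane, and through the thermoelectric effect in the
bilayer's polar molecules that gradient induces a transmembrane potential.
When the equivalent potential reaches the conventional electroporation
threshold (0.1–1 V), pores form.

This package implements that model chain quantitatively, so that an
exposure design (wavelength, pulse duration, pulse spacing, power, spot
size) can be assessed against the threshold, and the parameter space
explored for new designs.

## The model

### Dosimetry

An exposure delivering average power $W_{avg}$ into a spot of $1/e^2$
diameter $d$ in a medium with absorption coefficient $\alpha$ deposits its
power into volume $V = A\,\delta$ with penetration depth
$\delta = 1/\alpha$. The derived dose quantities are the average power
density $\langle w\rangle = W_{avg}/V$, the per-pulse peak energy density
$E_p = \tau_{rep}\langle w\rangle$ (equivalently $\tau_p W_{peak}/V$), and
the areal peak power density $W'_{peak} = E_p\,\delta/\tau_p$.

The illumination area convention is $A = d^2$, the square of the $1/e^2$
diameter, rather than $\pi d^2/4$. A Gaussian spot is conventionally
book-kept this way in this dosimetry tradition (it slightly over-counts the
disc area, roughly compensating the energy in the Gaussian skirt), and it is
the convention under which all the standard worked numbers for this exposure
regime — 2500 μm² for a 50 μm wide-field spot, 4 μm² for a 2 μm
optoinjection spot, and $\langle w\rangle$ of 6.6×10⁶–1.1×10⁷ W cm⁻³ for
15–24 mW in a 1.5 μm spot — come out. A circular option is exposed
(`area_convention = "circular"`) and every dose summary records which
convention produced it.

### The threshold inequality

The membrane temperature gradient produced by a pulse train has two parts: a
per-pulse transient scaling as $E_p\sqrt{\tau_{diff}/\tau_p}$ and a
steady-state accumulation term scaling as $E_p\,\tau_{diff}/\tau_{rep}$,
both normalized by $\rho c_v R$, where

$$\tau_{diff} = \frac{\rho c_v R^2}{\kappa}$$

is the thermal diffusion time across a cell radius ($7\times10^{-4}$ s for a
10 μm cell in water). Permeabilization by this mechanism requires

$$E_p\sqrt{\tau_{diff}/\tau_p} + E_p\,\frac{\tau_{diff}}{\tau_{rep}}
  \;\ge\; \rho c_v R\,\nabla T_{ep},$$

where $\nabla T_{ep}$ is the membrane temperature-gradient threshold. All
critical values in the package — `critical_tau_rep_fixed_Ep()`,
`critical_tau_rep_fixed_w()`, `critical_tau_p()`, `critical_Ep()`,
`critical_w()` — are closed-form inversions of this single inequality for
one variable at a time; the fixed-$E_p$ and fixed-$\langle w\rangle$ forms
are algebraically equivalent under $E_p = \tau_{rep}\langle w\rangle$, and
the test suite checks that equivalence over a thousand random draws, plus
agreement of every closed form with boolean bisection on the raw inequality
to $10^{-6}$ relative.

### The gradient threshold

The conventional electropermeabilization potential threshold $V_m$ of
0.1–1 V, across the 7 nm physical thickness of the membrane, converts
through a thermoelectric factor $S \approx 100$ K/V into

$$\nabla T_{ep} = \frac{S\,V_m}{d_m} \;\in\; [1.4\times10^9,\;
  1.4\times10^{10}]\ \mathrm{K/m}.$$

`membrane_model()` can derive $\nabla T_{ep}$ from $(V_m, S, d_m)$, but its
**default fixes $\nabla T_{ep} = 10^9$ K/m**, the order-of-magnitude lower
bound of that range, supplied directly and recorded as such. This is the
value under which the model's standard worked critical values
(6.53×10⁻⁹ s, 3.73×10⁻⁸ s, 6.77×10⁻⁸ s, …) are reproduced exactly; it
represents the most permissive (most easily satisfied) end of the threshold
range, so "unsatisfied at 10⁹ K/m" is a conservative statement.

### Membrane thickness: 7 nm, not 5 nm

Electrical models of the membrane often use a 5 nm effective thickness; the
model here uses the 7 nm physical dimension because it is the distance over
which the *temperature* drop develops. For an order-of-magnitude threshold
this difference is inside the other uncertainties.

## Parameters that matter

| Parameter | Symbol | Default | Units | Why |
|---|---|---|---|---|
| pulse duration | $\tau_p$ | 100 fs | s | sets the transient gradient strength |
| pulse spacing | $\tau_{rep}$ | 20 ns | s | sets accumulation between pulses |
| average power | $W_{avg}$ | 15–24 mW | W | scales all dose quantities linearly |
| spot diameter | $d$ | 1.5 μm | m | dose scales as $1/d^2$ |
| absorption coeff. | $\alpha$ | 10 cm⁻¹ | m⁻¹ | water at 1550 nm; sets $\delta = 1/\alpha$ |
| cell radius | $R$ | 10 μm | m | enters $\tau_{diff} \propto R^2$ and the threshold $\propto R$ |
| density, spec. heat, conductivity | $\rho, c_v, \kappa$ | 1000, 4200, 0.6 | SI | water-like medium |
| membrane thickness | $d_m$ | 7 nm | m | physical bilayer dimension |
| gradient threshold | $\nabla T_{ep}$ | 10⁹ | K/m | lower bound of the 0.1–1 V range |

Internally everything is strict SI; all user-facing boundaries accept the
field's customary mixed units (`"24 mW"`, `"100 fs"`, `"0.22 J/cm^3"`,
`"10 cm-1"`) through an explicit conversion table — the single-unit-system
rule exists because this literature mixes cgs-flavoured and SI quantities
and silently crossing them produces $10^4$–$10^6$ scale errors.

## Beam registration numbers

Focal registration uses a pinhole matched to the beam waist as a confocal
aperture: the transmission of a TEM00 Gaussian of radius $w(z) =
w_0\sqrt{1+(z/Z_R)^2}$ through a centered circular aperture of radius $a$
is $1-\exp(-2a^2/w(z)^2)$. With $a = w_0$ the transmitted power falls to
73.1% of its on-focus value at $z = Z_R$ and 92.3% at $z = Z_R/2$ — a
few-percent power change therefore localizes focus to ≲1 μm. The model is
scalar-paraxial with a perfectly centered aperture and no aberrations; those
idealizations are exactly what yields the 73%/92% working numbers.

A caveat worth recording: for a 1.5 μm $1/e^2$ diameter at 1550 nm the
standard formula gives $Z_R = \pi w_0^2/\lambda \approx 1.14$ μm, i.e. a
depth of focus $2Z_R \approx 2.3$ μm, whereas a depth of focus of ≈5.4 μm
is sometimes quoted for this geometry. No constant in this package is tuned
to force that number; the standard formula is computed and the discrepancy
is simply noted here.

## Numerical choices

* **Boundary rule.** The threshold inequality and all "satisfied" flags
  treat equality as satisfied, with a $10^{-9}$ relative slack so that an
  operating point constructed *from* a critical value lands on the
  satisfied side despite floating-point round-off (margin = 1 is a pass).
* **Degenerate outcomes are flagged values, not errors**, so grid sweeps
  never abort: `always_satisfied` (value `Inf` or 0 — the threshold holds
  for every value of the inverted variable) and `unreachable` (the critical
  fixed-$E_p$ pulse spacing is shorter than the pulse itself, so no physical
  train exists).
* **Interpolation.** `place_point()` interpolates regime curves log-log
  between grid nodes and uses the exact closed form when the query is a
  node; degenerate-flagged brackets propagate their verdict rather than
  interpolating a non-finite value.
* **Exact inversions vs diagram readings.** At the 20 ns / 100 fs operating
  point the exact critical dose levels are 0.354 J cm⁻³ and
  1.77×10⁷ W cm⁻³. Estimates of ≈0.32 J cm⁻³ and ≈1.6×10⁷ W cm⁻³ quoted
  from graphical regime-diagram readings sit ~10% lower; the package reports
  the exact values and its threshold report carries a note about the gap
  rather than absorbing it into either number.
* **Display rounding only.** All quantities are carried at full precision;
  two-significant-figure rounding happens exclusively in print methods and
  report "conventional" views.

## The synthetic scenario generator

`sample_scenarios()` draws parameter records log-uniformly (every parameter
spans orders of magnitude) within ranges chosen to cover the plausible
design space for this class of experiment: $\tau_p$ 1 fs–100 ps,
$\tau_{rep}$ 1 ns–10 μs, $W_{avg}$ 1–200 mW, spots 0.5–50 μm, cells
2–20 μm, water-like media ($\rho$ 900–1100 kg m⁻³, $c_v$ 3500–4500
J kg⁻¹ K⁻¹, $\kappa$ 0.4–0.7 W m⁻¹ K⁻¹, $\alpha$ 1–100 cm⁻¹), $V_m$
0.1–1 V, $S$ 50–200 K/V, $d_m$ 4–10 nm. The $\tau_p < \tau_{rep}$
constraint is enforced by rejection so the marginals stay log-uniform. The
seed is a mandatory argument and the caller's RNG stream is left untouched;
serialization is byte-stable for diff-based testing.

What the generator emulates is *parameter records*, not biology: it
contains no model of uptake statistics, viability, membrane heterogeneity,
or cell-to-cell variation in the thermoelectric response. Passing property
tests on generated records therefore demonstrates the internal consistency
and numerical robustness of the model chain over the plausible parameter
space — it says nothing about whether a real cell at those parameters
permeabilizes.

## A worked evaluation

```{r worked}
sc <- reference_scenario()
report <- evaluate_operating_point(sc$exposure_high, sc$medium, sc$membrane)
report
```

At 24 mW the exposure reaches $\langle w\rangle \approx 1.07\times10^7$
W cm⁻³ against a critical $1.77\times10^7$ W cm⁻³: margin ≈ 0.60, a factor
≈1.7 below threshold (≈2.7 at 15 mW). The mechanism is thus close to, but
not by itself past, the threshold at these settings — consistent with
contributions from bulk heating (which lowers the electroporation
threshold) and from the laser field itself making up the difference in
practice.

## Known limitations

* No depth-resolved (Beer–Lambert) absorption profile, scattering, or
  thermal lensing; the exposure volume is a single slab of depth $1/\alpha$.
* The transient/steady-state gradient decomposition is used as given; its
  derivation (and any waveform dependence beyond $\tau_p$, $\tau_{rep}$) is
  outside scope.
* No time-resolved membrane temperature profile, no coupling to
  conventional field-driven electroporation, and no temperature dependence
  of the threshold itself.
* Beam optics are scalar and paraxial; high-NA vector corrections and
  chromatic aberration are not modelled.

## Problem sizes in the test suite

Property suites use 1000–1200 random draws for the predicate-equivalence
test, 60 bisection-oracle comparisons at 80 geometric-bisection iterations,
3000 synthetic records for degenerate-flag coverage, and 200-point default
regime grids — sizes at which the full suite completes in well under a
minute on one CPU while leaving each property's failure modes plenty of
room to surface.
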