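---
title: "AFM cell microrheology with afmrheo: models, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AFM cell microrheology with afmrheo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmrheo)
```

## The measurement and the models

An AFM force curve on a living cell records the cantilever deflection $d$
while the z-piezo extends by $z$ toward the sample. After baseline
subtraction, force is $F = k\,d$ and indentation is
$\delta = (z - z_0) - d$, where $k$ is the spring constant and $z_0$ the
contact point. `afmrheo` analyzes the sweep-frequency variant of this
experiment, which has four phases: a quasi-static approach ramp up to a
trigger force, a 1 s dwell during which the approach stress relaxes, a
stepped-frequency sinusoidal z modulation while the tip stays in contact,
and a retract ramp.

Two models carry the analysis.

**Hertz contact.** On the approach, the force--indentation relation for a
spherical or parabolic tip of radius $R$ on an incompressible sample
($\nu = 0.5$ by default) is
$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$
and for a cone of half-angle $\theta$,
$F = \frac{2}{\pi}\tan\theta\,\frac{E}{1-\nu^2}\,\delta^2$. The fitted $E$
is an *apparent* Young's modulus: cells are viscoelastic, and the
rate-dependent dissipation that produces approach/retract hysteresis is
folded into it.

**Power-law structural damping.** The modulation segment measures the
complex modulus over frequency. Its model is
$$E^*(f) = E_0\,(1 + i\eta)\left(\frac{f}{f_0}\right)^{\alpha}
  + i\,2\pi f \mu, \qquad \eta = \tan\!\frac{\pi\alpha}{2},$$
a weak power law in the storage modulus whose damping is coupled to the
exponent (hysteresivity $\eta$), plus a Newtonian viscous term $\mu$. The
loss tangent $E''/E'$ is solid-like below 1 and liquid-like above 1. At
the reference frequency $f_0$ (1 Hz throughout) the storage modulus equals
$E_0$; $\mu$ contributes only to the loss modulus. Exponents near 0.1, as
typical for fibroblasts, correspond to a soft glassy material close to its
glass transition.

The conversion from the demodulated force/indentation transfer to $E^*$
linearizes the contact about the operating indentation $\delta_0$ reached
at the end of the dwell:
$$E^*(f) = \frac{1-\nu^2}{2\sqrt{R\,\delta_0}}\,
  \frac{\hat F(f)}{\hat\delta(f)}$$
for sphere/paraboloid tips (cone analog with
$\pi(1-\nu^2)/(4\tan\theta\,\delta_0)$). Before conversion, the cantilever
drag force $i\,2\pi f\,b(0)\,\hat z$ is subtracted; $b(0)$ comes from
out-of-contact calibration sweeps at several heights, extrapolated linearly
to zero separation over the smallest heights.

## Pipeline and numerical choices

`analyze_sweep_curve()` chains the full analysis; each stage is exported
for standalone use.

- **Segmentation** (`segment_curve`) classifies z increments into
  ramps/holds. Because the lowest sweep frequency starts with
  sub-resolution z motion, the dwell/modulation boundary is placed from the
  sweep schedule carried in the curve metadata (the modulation duration is
  known exactly); the retract is the final monotone descent, validated
  against the constant-velocity line it must follow so the boundary is
  exact to the sample.
- **Contact point** (`find_contact_point`) scans candidate $z_0$ over the
  approach, modeling a constant (optionally linear, for drift) baseline
  before contact and a Hertz arc after it, and picks the least-squares
  minimum; golden-section refinement between grid points then makes $z_0$
  continuous. On noise-free curves the residual vanishes at the true
  contact point, so the refinement is exact to optimizer precision. A
  curve whose post-contact force rise does not exceed five baseline
  standard deviations is rejected as "no contact". `fit_hertz()` can
  re-optimize a contact-point shift jointly with $E$, which removes the
  residual sample-resolution error; the analysis pipeline also applies
  this shift to the operating indentation.
- **Demodulation** (`demodulate`) fits each channel in each scheduled
  frequency window to $A\cos\omega t + B\sin\omega t + C$ by least
  squares, reporting the complex amplitude $A - iB$. This is exact for any
  window length (no integer-period requirement), and $C$ of the
  indentation channel measures $\delta_0$. Windows truncated below 2
  cycles are skipped with a warning.
- **Structural damping fit** (`fit_structural_damping`): for fixed
  $\alpha$ the model is linear in $(E_0, \mu)$, so the fit profiles the
  linear part (with $\mu \ge 0$ enforced by re-solving on the boundary)
  and minimizes over $\alpha$ alone on a 0.01-step grid followed by
  golden-section refinement; ties prefer the smallest $\alpha$. Real and
  imaginary parts are weighted equally by default (`weights = "relative"`
  switches to magnitude-relative weighting). Frequencies above 100 Hz are
  excluded from the fit by default -- the z-piezo response rolls off there
  -- though they remain in the spectrum. Negative corrected loss moduli
  are kept, not clipped.
- $\eta$ is constrained to $\tan(\pi\alpha/2)$; `free_eta = TRUE` fits it
  freely for model comparison.

## The synthetic generator

Because per-cell ground truth is unobservable in a real experiment, every
stage is validated against `generate_force_curve()`, which synthesizes
curves from known `cell_params()`:

- approach: quasi-static Hertz ramp with the cell's apparent modulus,
  sampled on a strictly increasing z grid ending exactly at the trigger;
- dwell: exponential force relaxation toward a plateau
  (`relaxation_factor` 0.8 of the trigger force, time constant 0.15 s);
  the modulation carrier is frozen at the end-of-dwell operating point;
- modulation: per scheduled frequency, the in-contact response follows the
  linearized contact transfer $T(f) = (H + i\omega b_0)/(k + H)$ with
  $H(f)$ the contact stiffness of the structural damping modulus at the
  realized $\delta_0$, plus additive Gaussian force noise;
- retract: ramp with stiffness scaled by `hysteresis_factor` (1.3),
  reproducing approach/retract hysteresis qualitatively (the analysis only
  uses approach data).

The default sweep runs 1 Hz--1 kHz. A stepped schedule with at least two
full cycles per frequency cannot total exactly 8.7 s at 10 frequencies per
decade (that sums to 9.72 s), so the default uses 9 per decade -- 28
frequencies, 8.85 s -- the closest integer-cycle schedule to the nominal
duration. The modulation amplitude (20 nm) and per-frequency cycle count
(2) are not constrained by the experimental description and are exposed in
`sweep_schedule()`.

Cohort dispersion (`draw_cohort`) is lognormal and independent per
parameter: each cell draws `median * exp(N(0, sigma))`, consistent with
the log-scale histograms used for cell stiffness; parameter correlations
are unreported and therefore not modeled. Drag calibration curves follow
$b(h) = b_0 h_s/(h_s + h)$ (or a linear variant); only $b(0)$ matters
downstream, so the exact height law is not asserted. The cohort presets
carry the published median parameters; the scar cohort's viscosity is not
printed alongside the healthy (7 Pa s) and Dupuytren (13 Pa s) values, so
the preset interpolates 10 Pa s.

Time courses (`generate_timecourse`) draw a fate per cell -- dead,
recovered, or no change -- and produce stiffness trajectories relative to
baseline: responding cells descend linearly to `drop_factor` (0.1) of
baseline by `response_time` (30 min); recovering cells then relax
exponentially toward `recovery_fraction` (0.5) of baseline; dying cells
sit at a 5% death floor and detach with probability 0.5. All measurements
carry 5% lognormal noise. Classification (`classify_fate`) is
rule-based on $r(t) = E'(1\,\mathrm{Hz}, t)/\mathrm{baseline}$: detachment
means dead; $\min r \ge 0.7$ means no change; a post-minimum rise of at
least $\max(0.1,\ 0.15\,(1 - \min r))$ means recovered; a final value
below 0.2 without such a rise means dead. The recovery coefficient 0.15
was chosen so that the canonical inhibitor-response trajectory (baseline
2 kPa, drop to 0.2 kPa, recovery to 0.5 kPa) classifies as recovered; a
stricter coefficient of 0.25 would reject exactly that trajectory. These
rules are operational definitions of this package, not a published
criterion, and all thresholds are configurable via `fate_thresholds()`.

**What the generator does not emulate:** thermal cantilever noise spectra,
tip adhesion (JKR/DMT), the second high-frequency power-law regime above
100 Hz, instrument tilt or virtual deflection, and piezo nonlinearity.
Passing round-trip tests therefore demonstrates correctness of the
analysis chain under the stated model, not robustness to every artifact of
real instrument data.

## Statistics

Cohort comparisons use the per-cell force-map median modulus.
`rank_test()` offers the independent-samples rank-sum test (default --
cohorts of different cells are independent) and the paired signed-rank
variant. With `min(n)` at most 8 the null distribution is enumerated
exactly over rank assignments (midranks make tied data exact too); larger
samples use the tie-corrected normal approximation with continuity
correction. Effect sizes are Cohen's d with the pooled-SD definition, and
`significance_marks()` applies the conventional strict thresholds: `*`
for p < 0.01, `#` for 0.2 < |d| < 0.5, `##` for 0.5 < |d| < 1. No
multiple-testing correction is applied.

## Problem sizes and verification

The test suite and the acceptance script synthesize curves with the sweep
capped at the 100 Hz analysis band and 1 kHz sampling, which keeps a full
four-segment curve near $10^4$ samples and the whole closed-loop suite --
a 27-point parameter grid, 200 noisy replicates, 2000-cell fate cohorts
and 2000 null rank-test replicates -- in well under a minute each. The
package defaults remain the full study conditions (1 kHz sweep, 10 kHz
sampling). Noiseless round trips recover $(E_0, \alpha, \mu)$ and the
apparent modulus to better than $10^{-4}$ relative; all headline
quantities reported by `scripts/acceptance.R` are recomputed at run time
by these same code paths.

## Known limitations

- The linearized contact conversion assumes small oscillations about
  $\delta_0$; large modulation amplitudes would introduce harmonic
  distortion the demodulator ignores.
- Only a scalar $b(0)$ drag correction is applied; no frequency-dependent
  cantilever hydrodynamics, and no inertial correction (relevant near the
  cantilever resonance, well above the analysis band).
- The single power-law model is fitted only up to 100 Hz; it cannot
  describe the second regime reported at higher frequencies.
- Fate classification thresholds are calibrated to the generator's
  kinetics; applying them to real time courses requires re-tuning against
  observed trajectories.
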