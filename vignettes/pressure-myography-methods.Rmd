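---
title: "Pressure myography with a digital vessel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure myography with a digital vessel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasomyo)
```

## Scope

`vasomyo` is a computational counterpart to an ex-vivo pressure myograph:
a cannulated vessel segment is held at controlled intraluminal pressure
while its outer and inner diameters are tracked optically. The package
provides (i) the pressure protocols such a device applies, (ii) a
forward constitutive model of the vessel wall that turns those protocols
into synthetic diameter recordings (with measurement noise, rupture, and
rendered frames), and (iii) the analysis chain applied to recordings:
pulse detection, FFT pulse frequency, dynamic compliance, burst and
plateau pressure, vasoreactivity normalization, and inverse fitting of
the wall parameters with linearized stiffness. Everything downstream of
the protocols is testable against the forward model, which is the point:
every analysis statistic in the package has a synthetic ground truth.

## Pressure protocols

Two drives are modeled. The *pulsatile* drive mimics an occlusion-arm
pulse generator: each cycle of length $60/\text{beat rate}$ seconds sits
at the diastolic baseline and ends with a smoothed-square systolic pulse
occupying `systolic_fraction` (default 0.35, a typical arterial systole
fraction) of the cycle, with raised-cosine rise and fall ramps each
spanning `rise_fraction` (default 0.3) of the systolic window. Setpoints
are taken literally — transducer overshoot and occlusion-arm lag are not
modeled.

Two conventions matter and are deliberate:

* Traces start at $t = 0$ at the diastolic baseline, and the systolic
  window sits at the **end** of each cycle. Consequently a recording of
  duration $T$ contains exactly $\lfloor T f \rfloor$ complete pulses —
  a trace cut mid-cycle truncates a pulse that has not yet started
  rather than one in progress. One minute at 1.06 Hz therefore carries
  63 complete pulses, which is what the pulse counter reports.
* The flat pulse top is an exact plateau; peak detection treats a
  plateau as a single maximum at its midpoint.

The *stepwise* drive mimics a click-quantized ratchet: levels
$P_0 + k\,\Delta P$ held for a fixed time (typically 20 s), ending at
the first level at or above the target pressure. The default click size
of 64.37 mmHg corresponds to a 3 mL syringe in the device this emulates.

## The vessel wall model

The wall is an incompressible hyperelastic membrane with a
four-fiber-family stored-energy function, the standard form used for
murine vessel phenotyping: an isotropic neo-Hookean matrix plus four
exponential fiber families (axial, circumferential, and a symmetric
diagonal pair at $\pm\alpha_0$ from the axis, default
$\alpha_0 = 45^\circ$):

$$W = \frac{c}{2}\left(\lambda_\theta^2 + \lambda_z^2 + \lambda_r^2 - 3\right)
  + \sum_{k=1}^{4} \frac{c_{1k}}{4 c_{2k}}
    \left[e^{c_{2k}\left(\lambda_k^2 - 1\right)^2} - 1\right],
\qquad \lambda_k^2 = \lambda_\theta^2 \sin^2\alpha_k +
\lambda_z^2\cos^2\alpha_k,$$

with $\lambda_r = 1/(\lambda_\theta\lambda_z)$ by incompressibility. A
family with $c_2 = 0$ degrades continuously to the quadratic limit
$(c_1/4)(\lambda_k^2-1)^2$. The circumferential Cauchy stress is
$\sigma_\theta = \lambda_\theta\,\partial\hat W/\partial\lambda_\theta$
(computed analytically; a finite-difference oracle on $\hat W$ checks it
in the tests to $10^{-6}$ relative).

Three modeling choices were genuinely open and are resolved as follows:

* **Thin-wall equilibrium.** Pressure and stress are linked by the
  Laplace closure $P = \sigma_\theta h/a$ rather than thick-wall
  integration, because the analysis computes a single stress/stretch per
  loaded state, consistent with a membrane treatment. The closure is
  isolated in `equilibrium_pressure()` so a thick-wall variant can be
  swapped in.
* **Mid-wall stretch convention.** $\lambda_\theta = r_m/R_m$ with
  $r_m$ mapped through exact incompressible kinematics (wall
  cross-sectional area conserved exactly, to $10^{-12}$ in the tests),
  not the arithmetic mean of the loaded radii.
* **Axial stretch.** Testing protocols hold a constant axial stretch
  whose value is rarely reported; the default is $\lambda_z = 1$ and it
  is configurable everywhere.

Units are fixed: mmHg at every user-facing pressure interface, kPa for
stresses internally, with 1 mmHg = 0.133322 kPa.

The pressure–diameter map inverts $P(\lambda_\theta)$ by a safeguarded
vectorized Newton iteration on $[\lambda_{lo}, 2.5]$ (tolerance
$10^{-10}$ on the stretch, residual $< 10^{-6}$ mmHg). Newton steps that
leave the bracket *or fail to halve the previous step* fall back to
bisection; the second guard matters because strongly exponential walls
(large $c_2$) produce pressure cliffs that plain damped Newton descends
in thousands of tiny steps. Pressures beyond the reachable range at
$\lambda_{max}$ raise a convergence error naming the bracket.

## Presets and what the generator does and does not emulate

Two shipped walls share a carotid-like unloaded geometry (inner radius
200 um, wall 40 um):

| preset | c (kPa) | c1 (kPa) | c2 | behavior |
|---|---|---|---|---|
| `compliant` | 30 | (5, 5, 5) | (0.1, 0.1, 0.1) | long elastin-dominated toe; plateau near 200 mmHg; ~88 um distension over 80–120 mmHg |
| `stiff` | 40 | (20, 20, 20) | (16, 16, 16) | early collagen engagement; plateau near 125 mmHg; ~7 um distension |

These are calibration choices of this package — tuned once, by grid
search, to the qualitative contrast between a normotensive vessel
(plateau ~200 mmHg) and a remodeled/stiffened one (plateau ~125 mmHg),
with the stiff stress–stretch curve left-shifted (it reaches 50 kPa at
stretch 1.13 vs 1.35) — not measurements of any particular vessel.

The synthetic recording adds independent, homoscedastic Gaussian noise
to each diameter series and to each of the two simulated pressure
transducers; there is no temporal autocorrelation, no vasomotion, no
active smooth-muscle tone, no viscoelasticity, and no temperature
dependence. Rupture is instantaneous at the first sample whose wall
stress reaches the failure stress, with no damage accumulation; the wall
sustains the failing level for a short `rupture_delay` (default 1 s)
before pressure drops to zero and diameters go missing, so the failing
level itself appears in the record — which is what "maximum pressure
before rupture" measures on the real device. Passing tests on this twin
therefore demonstrate correctness of the *analysis chain*, not fidelity
to any real tissue's noise structure or failure physics.

Rendered frames are idealized: a horizontal, vertically centered vessel
drawn as two dark wall bands and a brighter lumen on a bright
background, anti-aliased analytically so band edges land at their exact
sub-pixel positions, plus Gaussian pixel noise. Real myography frames
have sutures, debris, uneven illumination and defocus that this
generator does not attempt; the tracker is validated only on synthetic
frames and is a minimal, documented stand-in for production trackers.

## Analysis conventions

**Pulse detection.** Peaks are interior local maxima with topographic
prominence above a threshold (default: $3\times$ the MAD of the trace
after removing a ~2 s running median; explicit values override),
separated by at least 0.3 s (supports pulse rates to 200/min). Boundary
samples never count, so edge-truncated pulses are excluded. The
baseline $D_{min}$ is a single global value — the median of inter-peak
minima — matching the convention of one baseline diameter per
recording; per-pulse distension is $D_{max,i} - D_{min}$.

**Pulse frequency.** The dominant spectral peak of the mean-subtracted
signal, refined to the fundamental: among local spectral peaks within
6 dB of the maximum, the lowest frequency wins. This guards against
harmonic capture for square-ish pulses. Resolution is $1/T$ Hz.

**Dynamic compliance.**
$D_c = \left[(D_{max}-D_{min})/D_{min}\right]/(P_{max}-P_{min})$ in
mmHg$^{-1}$, evaluated per diameter pulse with one recording-level
pressure amplitude: $P_{max}$ and $P_{min}$ are the median pressure-peak
height and median pressure baseline from the same peak detector. Outer
diameter is used throughout. On a zero-noise periodic recording every
pulse is identical and the per-pulse spread is exactly zero — a test.

**Burst pressure.** Maximum recorded pressure strictly before the
rupture time, after a ~0.5 s running-median filter so the max statistic
is not inflated by sensor-noise extremes (a no-op on noiseless
staircases). Without rupture the protocol completed and the maximum
pressure is reported but not labeled a burst.

**Plateau pressure.** Lowest pressure where the central-difference
slope $dOD/dP$ falls below `slope_fraction` (default 0.1) of its
maximum and stays below at all higher pressures; `NA` when it never
settles (a straight line has no plateau).

**Vasoreactivity.** Constriction is min–max normalized (0% at the
largest observed diameter, 100% at the smallest); relaxation is anchored
at the pre-dose diameter (0%) and the largest diameter (100%). Both are
invariant to diameter offsets.

## Inverse fitting and stiffness

`fit_4ff()` minimizes squared *outer-diameter* residuals — diameter is
the measured quantity at prescribed pressure — over log10-scaled
parameters with box bounds ($c, c_1 \in [10^{-3}, 10^3]$ kPa,
$c_2 \in [10^{-3}, 50]$), L-BFGS-B, and seeded multistart (default 8
starts; log-uniform factor-of-2 perturbations of the initial guess).
The diagonal pair shares one modulus and exponent and $\alpha_0$ is
fixed by default: single-protocol pressure–diameter data cannot identify
all parameters, and the honest outputs are the recovered *curve* and the
*stiffness at loaded states*, which the tests require to 0.5 um and 5%
respectively — recovered parameter vectors may differ freely from the
generating ones.

Linearized stiffness is the incremental modulus
$d\sigma_\theta/d\lambda_\theta$ at the equilibrium state solved for
each requested pressure (defaults 20, 90, 120 mmHg: low, normotensive,
hypertensive), computed analytically and cross-checked against central
differences. A small-on-large tensor component would be a defensible
alternative behind the same interface; the simple incremental modulus
was chosen because it is fully determined by the model as stated. Note
the instructive reversal the model reproduces: a crosslink-like wall
(high matrix modulus, nearly linear response) can out-stiffen a
strain-stiffening wall at 20 mmHg yet under-stiffen it at 120 mmHg.

## Problem sizes and numerical hygiene

The shipped tests exercise: 60 s traces at 100 Hz for frequency and
peak-count checks; 10–30 s at 50 Hz for compliance; 100 seeded
512-pixel frames for noisy tracking (error $\le 2$ px at 5% contrast
noise); and 4-vessel noise-free refit sweeps with 3 multistarts each.
These sizes make the whole suite run in well under a minute while
leaving every statistic's sampling error far below its test tolerance.
All randomness flows through explicit integer seeds; zero-noise paths
are deterministic and seed-independent, and identical seeds reproduce
recordings and fits bit for bit.

## Known limitations

No residual stress or opening angle; no active tone; no axial force
balance (fits use pressure–diameter only); thin-wall stress only;
tracker assumes a roughly horizontal vessel with four clean edges;
the pulse generator does not model setpoint overshoot. These bound what
agreement with real recordings can be claimed from this package alone.
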