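---
title: "Mechanics and numerics of the osteomill force simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics and numerics of the osteomill force simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomill)
```

## The problem

Bone removal in surgery is a machining problem: a rotating micro end-mill
removes cortical bone, and the cutting force governs tissue damage, heat and
tool deflection. Cortical bone is a natural fibre composite — osteons make its
shear strength and rake-face friction depend on the angle between the cutting
velocity and the osteon axis. Superimposing a small two-dimensional vibration
(micrometre amplitudes, kilohertz frequencies) on the workpiece turns the cut
intermittent, which can lower the mean force. `osteomill` simulates this
process mechanistically: given material, tool, process and vibration
parameters it predicts the instantaneous uncut chip thickness and the
workpiece-frame force components `Fx`, `Fy`, `Fz`, plus the summaries
(filtered RMS, single-factor sweeps) used to compare conditions.

## Model structure

The flute is discretised into axial micro-elements. An element of height
$\mathrm{d}z$ cutting chip thickness $h$ experiences

$$\mathrm{d}F_t = K_{tc}\,h\,\mathrm{d}z + K_{tp}\,\mathrm{d}z,\qquad
  \mathrm{d}F_r = K_{rc}\,h\,\mathrm{d}z + K_{rp}\,\mathrm{d}z,\qquad
  \mathrm{d}F_a = K_{ac}\,h\,\mathrm{d}z,$$

i.e. a shear (chip-area) term plus a ploughing (edge-length) term. Elements
with $h = 0$ are separated from the material and transmit nothing — under
vibration this is the mechanism that reduces the mean force, because the
rubbing contact disappears during the empty-cut phases.

**Shear coefficients** come from oblique-cutting (Armarego) theory with the
chip-flow rule $\eta_c = \lambda$ (chip flow along the edge inclination, which
for an end mill equals the helix angle). Per cutting direction $i$ the
friction angle is $\beta_i = \arctan\mu_i$, the shear angle
$\varphi_i = \pi/4 - (\beta_i - \gamma_n)/2$, and

$$K_{tc} = \frac{\tau_i\left[\cos(\beta_i-\gamma_n) + \tan\eta_c\tan\lambda\sin\beta_i\right]}{\sin\varphi_i\,D},\quad
  K_{rc} = \frac{\tau_i\sin(\beta_i-\gamma_n)}{\sin\varphi_i\cos\lambda\,D},\quad
  K_{ac} = \frac{\tau_i\left[\cos(\beta_i-\gamma_n)\tan\lambda - \tan\eta_c\sin\beta_i\right]}{\sin\varphi_i\,D}$$

with $D = \sqrt{\cos^2(\varphi_i+\beta_i-\gamma_n) + \tan^2\eta_c\sin^2\beta_i}$.
Some transcriptions of this model drop the radical on $D$; we implement the
square-root form of the original oblique-cutting theory and expose
`armarego_sqrt = FALSE` for the alternative reading. At $\lambda \to 0$ the
expressions collapse to the orthogonal-cutting closed form and $K_{ac} \to 0$;
this limit is asserted in the tests.

**Ploughing coefficients** use a slip-line picture of the blunt edge: the slip
line leaves at $\eta_i = \tfrac12\cos^{-1}\mu_i$ over a contact length
$l_{MN} = r_e\sin\eta_i$, giving a force per unit width
$F_p/b = \tau_i\cos(2\eta_i)\,l_{MN}$, resolved through the *equivalent rake
angle* of the rounded edge,

$$\gamma_e(h) = \begin{cases}
  \arccos\!\dfrac{r_e-h}{r_e} - \dfrac{\pi}{2}, & h \le r_e(1+\sin\gamma_n)\\[4pt]
  \gamma_n, & \text{otherwise,}
\end{cases}$$

as $K_{tp} = (F_p/b)\,|\sin\gamma_e|$ and $K_{rp} = (F_p/b)\cos\gamma_e$. The
two $\gamma_e$ branches agree exactly at the changeover, so the coefficients
are continuous in $h$; at $h \to 0$, $\gamma_e \to -\pi/2$ with a square-root
modulus (the derivative of $\arccos$ diverges), which is physical, not a bug.
Two conventions are worth stating explicitly:

* the expression `re*sin(eta)` for the contact length admits a quotient
  misreading (`re/sin(eta)`, ~120x larger); we use the product and provide
  `slipline_length = "quotient"` so the effect can be examined;
* $\gamma_e < 0$ would make a literal $\sin\gamma_e$ factor negative; the
  coefficients are stored as nonnegative magnitudes and the resistive sense of
  ploughing is applied once in the force decomposition. Ploughing acts only on
  engaged elements with $h > 0$ — no rubbing force during separation.

There is no closed-form axial ploughing coefficient in this model; `Kap`
defaults to 0 (configurable), and the analysis concentrates on the XOY plane
where the dominant forces live.

## Kinematics and chip thickness

In the workpiece frame the tip of tooth $j$ moves as

$$x = vt + r\sin(\omega t - 2\pi j/N) + r_0\sin(\omega t + \psi) + A_x\sin(2\pi f_x t + \varphi_x),$$
$$y = \phantom{vt+{}} r\cos(\omega t - 2\pi j/N) + r_0\cos(\omega t + \psi) + A_y\sin(2\pi f_y t + \varphi_y),$$

superposing feed ($v = f_z N n/60$), rotation, tool runout ($r_0$, $\psi$) and
the platform vibration folded into the relative trajectory. The tooth angle
convention puts $\theta = 0$ on the +Y axis with the slot-milling engagement
arc $\theta \in [0, \pi]$; $\theta$ is tracked unwrapped and reduced modulo
$2\pi$ only for engagement tests. "sin–cos" drive means a 90° phase lead on Y
(both axes are written as sines), "sin–sin" means in-phase; which physical
axis carries the cosine is not standardised, so the preset is configurable.

The uncut chip thickness is the radial gap between the current tip and the
surface left by earlier passes, measured along the ray from the tool centre
$O(t)$ through the tip $B(t)$. A prior-trajectory point $P_s(t_s)$ lies on
that ray when the cross product $(x_o-x)(y-y_s) - (y_o-y)(x-x_s)$ vanishes.
Two candidate surfaces are considered, per the four cutting cases the
vibration creates: the *previous tooth's* pass ($t_s$ near $t - 2\pi/\omega N$)
and the *same tooth one revolution earlier* ($t_s$ near $t - 2\pi/\omega$).
Each window is scanned at 200 points for sign changes of the residual and
every bracket is bisected to ~1e-12 s; crossings behind the centre (negative
ray parameter) are discarded. With the crossing distance $L_{OP_s}$, each
candidate contributes $h = r - L_{OP_s}$.

**Governing-surface rule.** A pass clears material along the ray out to its
crossing radius, so the machined boundary sits at the *largest* crossing
radius — equivalently the *smallest* $h$ candidate. We therefore take
$h = \max(0, \min_k h_k)$ over all admissible crossings: if any candidate is
negative the tip is inside an already-cleared region and the cut is empty.
(Taking the "minimum nonnegative" candidate instead would let a tooth cut
material that an outer contour has already removed, and it breaks material
conservation under vibration.) The winning candidate's trajectory tags the
sample as chip/empty formed by the other tooth or by the same tooth;
`not-engaged` marks angles outside the slot arc.

During the first tooth pass no machined surface exists; the thickness falls
back to the classical $f_z\sin\theta$ against the ideal initial arc. The
first revolution is flagged and discarded from every reported statistic, so
this start-up convention never reaches a result.

**Accuracy.** The solver is validated against an independent brute-force
oracle (1e5-point dense sampling of the prior trajectories with local
refinement): over randomized probes in both conventional and vibratory
conditions the agreement is at machine precision, far inside the 1e-4·fz
acceptance tolerance. Material conservation closes the loop: in steady state
the removed cross-section per revolution equals $N f_z \cdot 2r$ (feed per
revolution times slot width) within 2% whether vibration is on or off —
vibration redistributes removed material between teeth and phases but cannot
create or destroy it.

**A deliberate caveat on the classical limit.** With vibration and runout off
the thickness is often summarised as $h = f_z\sin\theta$. The exact trochoid
deviates from that sinusoid by the successive-pass correction, up to
$\approx 1.1\,f_z^2/2r$ ($\approx 1.4\%$ of $f_z$ at the default
$f_z/r = 1/40$), largest towards the ends of the engagement arc; at the
thickness peak the agreement is better than 0.1%. We assert the exact
behaviour rather than forcing the solver to reproduce the approximation.

## Force integration

Each flute is split into 20 axial slices (default; doubling changes RMS by
<0.5%). The slice at height $z$ lags the bottom edge by
$\theta_z = z\tan\lambda/r$, so its thickness is the bottom-edge profile read
one lag time earlier (linear interpolation on the simulation grid), and its
angle is $\theta - \theta_z$. Engaged slices are rotated into the workpiece
frame as $\mathrm{d}F_x = \mathrm{d}F_t\cos\theta + \mathrm{d}F_r\sin\theta$,
$\mathrm{d}F_y = -\mathrm{d}F_t\sin\theta + \mathrm{d}F_r\cos\theta$,
$\mathrm{d}F_z = -\mathrm{d}F_a$, and summed over slices and flutes. A
`flip_y` switch accommodates dynamometer frames with inverted Y. Runout makes
the two flutes cut unequal thicknesses ("long/short teeth"), which shows up
as alternating per-tooth force peaks; with $r_0 = 0$ the teeth are
interchangeable to solver precision.

## Time grid and summaries

The default step is $\mathrm{d}t = 1/(K f_{max})$ with $K = 50$ samples per
cycle of the fastest process frequency (vibration or tooth passing). At
3000 Hz vibration this is 6.7 µs — about 30 vibration cycles per engagement
arc, each resolved by 50 samples, enough for the oscillating thickness and
the separation intervals. Force summaries use 3 simulated revolutions
(discarding the first) — RMS values are converged well below the percent
level at that length; the conservation check uses 11 revolutions to average
the per-revolution bookkeeping.

The 120 Hz low-pass used before RMS comparison is a zero-phase 4th-order
Butterworth (order configurable), realised as analytically-derived
second-order sections through a forward-backward pass. Direct high-order
designs are numerically fragile at the very low normalised cutoffs a
kilohertz-resolved grid implies ($W \sim 10^{-3}$); sections are not. The
signal is extended by an odd reflection (~6 cutoff periods) before filtering
so the zero-state transients die inside the padding — without this the
backward pass leaks a transient into the steady-state RMS window. RMS is
taken over the last $n_{rev} - 1$ full revolutions.

## The experiment grid and the synthetic "experiment"

`single_factor_grid()` encodes the 14-run single-factor design: three conventional
baselines (one per cutting direction), a direction sweep at A = 1 µm /
3000 Hz, an amplitude sweep 0.5–3 µm at 3000 Hz, and a frequency sweep 1–4 kHz
at 1.5 µm — all at 3000 rpm, $f_z$ = 10 µm/tooth, H = 100 µm, sin–cos phase.
`run_sweep()` simulates the relevant rows and reports filtered RMS with
percent change against the direction-matched conventional baseline.

`synth_experimental_trace()` stands in for a dynamometer recording: it
resamples the model trace to an instrument-like rate (default 10 kHz) and
adds seeded Gaussian noise. It emulates acquisition-rate mismatch and sensor
noise only. It deliberately does **not** emulate what makes real bone data
hard: tissue inhomogeneity (osteon vs interstitial strength), brittle
chipping and crack-driven force fluctuations, machine dynamics, or tool wear.
A pipeline that passes against the synthetic traces is verified as a
computation, not validated against tissue.

## What the model reproduces, and what it does not

Reproduced at the study conditions: the direction ordering of forces
(vertical > cross > parallel, following the shear-strength anisotropy), the
long/short-tooth alternation under 2 µm runout, the vibration-frequency
content of the force signal, tool–workpiece separation intervals in the
thickness profile, and a monotone *decrease* of filtered RMS with vibration
amplitude and frequency over the tested range (≈ −5% in Fx at A = 3 µm,
≈ −2.5% at 4 kHz).

Not reproduced: the *upturn* of force at large amplitude reported on physical
rigs (attributed to impact-thickened cutting layers — a dynamic effect a
purely kinematic trajectory model does not contain), and the magnitude of the
measured force reductions (~9–14%), which involve strain-rate, crack-path and
friction physics outside this model. The trend checks over the sweep grids
are therefore reported as soft diagnostics, not hard assertions. Further
limitations: trajectories are prescribed, not force-coupled (no regenerative
chatter); anisotropy enters through three per-direction constants rather than
a continuous orientation dependence along the cutter arc; there is no
temperature, wear, or Z-axis vibration.

## Reproducibility

All simulation is deterministic — identical configurations give bit-identical
traces, and the only randomness in the package (synthetic-experiment noise)
is seeded. `scripts/acceptance.R` recomputes the headline quantities from
scratch; see the README for how to run it.
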