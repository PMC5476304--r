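---
title: "Methods: fitting conductance-based model populations to membrane potential resonance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitting conductance-based model populations to membrane potential resonance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mprfit)
```

## The scientific problem

The pacemaker PD neuron of the crab pyloric network shows membrane potential
resonance (MPR): driven in voltage clamp through its natural slow-wave range
(about -60 to -30 mV) by a swept-frequency sinusoid, the amplitude of the
clamp current passes through a minimum near 1 Hz, i.e. the impedance
amplitude $Z(f)$ peaks at a resonant frequency $f_{res}$, and the impedance
phase $\varphi(f)$ crosses zero at a nearby phasonant frequency
$f_{\varphi=0}$. Two voltage-gated currents shape this behaviour: the
hyperpolarization-activated inward current $I_H$ (one slow resonant
activation gate) and a low-threshold calcium current $I_{Ca}$ with
multiplicative activation and inactivation ($m^3 h$).

Ionic conductances in this system vary several-fold across animals while the
network output stays stable. The package therefore does not fit one best
model; it fits a *population* of models whose impedance attributes all match
a target profile, and then asks which parameters the target constrains
tightly, which co-vary along correlation manifolds, and which attribute each
correlation protects.

## The model

A single compartment in ideal voltage clamp. The command $V(t)$ is imposed;
three gating ODEs are integrated along it,
$$\frac{dx}{dt} = \frac{x_\infty(V) - x}{\tau_x}, \qquad
x_\infty(V) = \frac{1}{1 + \exp((V - V_{1/2,x})/k_x)},$$
for $x \in \{m_H, m_{Ca}, h_{Ca}\}$, and the measured clamp current is
$$I_{clamp} = C_m \dot V + g_L (V - E_L) + \bar g_{Ca} m_{Ca}^3 h_{Ca}
(V - E_{Ca}) + \bar g_H m_H (V - E_H).$$
Units are mV / ms / µS / nF, so currents come out in nA and impedances in
MΩ. The slope factors are fixed ($k_{mCa} = -8$, $k_{hCa} = +6$,
$k_{mH} = -7$ mV), as is the H-current half-activation (-70 mV; a -96 mV
variant is available through `fixed_constants()`), and $\tau_{mH}(V) =
\tau_{mH}^{max} / [1 + \exp((V + 110)/(-13))]$. Eight parameters are free
(`param_bounds()`): the three maximal conductances, $\tau_{mH}^{max}$, the
Ca activation/inactivation midpoints and their two time constants.

**Reversal potentials.** $E_L$, $E_{Ca}$, $E_H$ are not constrained by the
impedance attributes alone. The defaults (-60, +120, -20 mV) are typical
crustacean stomatogastric values and are configurable. Because a gating
current enters as $\bar g\, x\, (V - E)$, fitted maximal conductances trade
off against the assumed driving forces: absolute conductance values are
comparable only within one choice of reversal potentials, and this is the
largest single source of quantitative discrepancy when comparing fitted
populations against values obtained under unknown reversal-potential
conventions.

**Integration.** Heun's explicit trapezoidal method ("modified Euler"),
default step 0.2 ms. Gating variables are clamped to $[0,1]$ after each
step, and a time constant below numerical resolution makes the gate track
its steady state. A warning is issued when the step exceeds half the
smallest time constant. A fast mode with $dt = 0.5$ ms is used for
evolutionary runs; the convergence tests show every extracted attribute
changes by well under 0.5% between $dt = 0.5$ and the reference 0.2 ms (the
capacitive current uses the analytic command derivative, and peak times are
refined by local parabolic interpolation, which removes the step-size
quantization of peak-based phase estimates).

## Stimulus

The logarithmic ZAP command is generated exactly as
$V(t) = v_0 + v_1 \sin(2\pi F(t))$, $F(t) = f_{lo}\, t\, (f_{hi}/f_{lo})^{t/T}$
with $t$ in seconds ($v_0 = -45$, $v_1 = 15$ mV, $f_{lo} = 0.1$,
$f_{hi} = 4$ Hz, $T = 100$ s), preceded by three sinusoidal pre-cycles at
$f_{lo}$ that join the sweep continuously and with matching derivative
(total 130 s). Literally interpreted, the instantaneous frequency of this
printed sweep exceeds $f_{hi}$ toward the end; since frequencies are
assigned per measured cycle, the profile is simply truncated at
$1.15 \times f_{hi}$. The three pre-cycles double as gating equilibration
(gates start at steady state for the first command voltage) and are excluded
from analysis.

## Impedance measurement and attributes

Cycles are delimited trough-to-trough on the command. Per cycle, the
impedance amplitude is the ratio of voltage to current peak-to-peak
amplitudes, and the phase is $2\pi f\,(t_{peak,I} - t_{peak,V})$ wrapped to
$(-\pi, \pi]$ — a current peaking before the voltage (capacitive lead) has
negative phase. Spectral (FFT) estimation is deliberately not used; the
cycle-to-cycle method is robust to the sweep's nonstationarity.

The profile is reduced to the ten-point attribute description used for
fitting: $Z_0 = Z(0.1)$, the resonance peak $(f_{res}, Z_{max})$ (local
quadratic fit around the discrete maximum), $Z(4)$, the two half-height
frequencies where $Z = Z_0 + Q_Z/2$ ($Q_Z = Z_{max} - Z_0$, bandwidth
$\Lambda_{1/2}$), and on the phase side $\varphi(0.1)$, the maximal advance
$(f_{\varphi max}, \varphi_{max})$, the phasonant frequency $f_{\varphi=0}$
(linear interpolation of the downward zero crossing), $\varphi(2)$ and the
maximal delay $\varphi_{min}$. Because the excluded pre-cycles leave the
first measurable cycle slightly above 0.1 Hz, the fixed-frequency values at
$f_0$ are obtained by local linear extrapolation from the first two cycles;
flat clamping would systematically read the rising flank of a resonant
profile as its $Z_0$.

**Target.** `pd_target()` carries the representative biological attribute
points: amplitude (Hz, MΩ) $(0.1, 8.2)$, $(1, 13.7)$, $(0.4, 11.65)$,
$(2.5, 11.65)$, $(4, 9.6)$; phase (Hz, rad) $(0.1, 0)$, $(0.4, 0.5)$,
$(1.05, 0)$, $(2, -0.25)$, $(4, -0.4)$. Two caveats are inherited from the
printed values and kept deliberately: the half-height points sit above
$Z_0 + Q_Z/2$ computed from the printed $Z_0$ and $Z_{max}$ (they are used
literally as objective targets), and the printed phase at 2 Hz is not a
valid angle — the package defaults to -0.25 rad, overridable via
`pd_target(phi_f2 = ...)`.

**Objectives.** Each of the ten objectives is the Euclidean distance between
the measured and target attribute points after normalizing frequency
coordinates by the target frequency, impedance coordinates by the target
impedance, and phase coordinates by 0.5 rad (the magnitude of the target's
maximal advance). Attributes pinned to a fixed frequency contribute their
normalized value difference. Undefined attributes (no interior impedance
maximum, no phase zero crossing) draw a large finite penalty ($10^6$) so the
individual stays inside the sorting machinery.

**Acceptance.** A model is *accepted* when every acceptance-relevant
attribute is within 5% relative error of its target: $Z_0$, $f_{res}$,
$Z_{max}$, the two half-height frequencies, $Z(4)$, $f_{\varphi=0}$,
$\varphi(2)$ and $\varphi_{min}$; the phase at $f_0$, whose target is zero,
must satisfy $|\varphi(0.1)| \le 0.05$ rad; the maximal phase advance is
excluded from acceptance (a single compartment without the A-current cannot
capture it, and the biological analysis excluded it for the same reason).

## The evolutionary search

`nsga2_evolve()` implements NSGA-II: uniform random initialization within
the Table-of-bounds box, binary tournament selection, simulated binary
crossover (distribution index 20, pair probability 0.9, per-gene exchange
probability 0.5), bounded polynomial mutation (index 20, per-gene rate
$1/8$), and $(\mu + \lambda)$ elitist survival over the pooled parent and
child populations, ranked by non-dominated sorting with crowding distance
computed per front.

One departure from the classic selection scheme proved necessary and is a
deliberate design choice of this package. With ten objectives, nearly the
whole population is mutually non-dominated within a few generations, so the
dominance rank carries no information and the classic crowding-only
tie-break actively pushes the population toward the extremes of the front —
the search then never approaches the target (we verified that a scalarized
control with the identical variation operators reaches sub-1% attribute
errors on the same problem, so the failure is in many-objective selection,
not in the landscape). Selection here therefore breaks ties among
equal-rank candidates toward the goal: the secondary sort key is the worst
acceptance-attribute error (a Chebyshev distance to the acceptance box),
with crowding distance retained as the final tie-break, and front truncation
always keeps each objective's minimizer, so the best value of every single
objective is non-increasing across generations. This is reference-point
guidance in the spirit of preference-based NSGA-II variants: the "region of
interest" is the target itself. In addition, every accepted model
encountered at any generation is stored in an archive; the pooled optimal
dataset is the union of archives and final populations across runs,
deduplicated at 7 significant digits — mirroring how large pooled
populations of optimal models are accumulated over repeated runs.

`mpr_fit()` wraps the whole procedure — several independent runs with
derived seeds, pooling, acceptance filtering — and returns an S3 object with
`print`, `summary`, `coef` (accepted parameter matrix), `residuals`
(objective scores), `predict` (attributes for new parameter sets under the
fitted stimulus) and `plot` (accepted profiles against the target points)
methods.

### Problem sizes

Fitting runs in this package's tests and reproduction script use the fast
integration mode ($dt = 0.5$ ms, validated above) with populations of 100
and 100–200 generations, pooling 2–3 runs — a scaled-down version of the
published protocol (5 runs × 200 generations at $dt = 0.2$ ms). A single
130-s clamp evaluation costs ~8 ms, a 200-generation run about 3 minutes on
one CPU.

## Downstream analyses

**Correlations.** `pearson_permutation()` reports the pooled Pearson
coefficient, a permutation p-value (default 1000 shuffles, two-sided on
$|R|$; the one-sided variant is available), the regression slope with its
t-test, and a stability screen: 2000 random 20-model subsets, each tested by
permutation, reporting the percentage significant at $p < 0.01$. Raw
p-values are reported; an optional Benjamini–Hochberg column is labelled as
an extension. `partition_gca()` splits the population at
$\bar g_{Ca} = 0.05$ µS (boundary value assigned to the high group);
`correlation_p_matrix()` arranges per-group p-values with the low group in
the lower triangle.

**Voltage-floor experiment.** `vlow_shift()` re-profiles each model with the
ZAP range lowered from $(-60, -30)$ to $(-70, -30)$ mV and reports
$\Delta f_{res}$ and $\Delta Z_{max}$; models losing resonance at either
range are flagged and excluded from group means. `intermediate_filter()`
keeps the models that reproduce the biological response — $f_{res}$ reduced
by 0.24 Hz, $Z_{max}$ unchanged, both within 5% — and the emergent
$\bar g_{Ca}$–$\bar g_H$ correlation of that subset can then be examined.

**Sensitivity.** `sensitivity_1d()` follows the step schedule: multiplicative
parameters (conductances, time constants) move on a log scale with offsets
$0.001 \times 1.15^n$ in both directions, additive voltage midpoints in
±0.5 mV increments; points are added until the linear fit's $R^2$ drops
below 0.98 and the slope of the retained fit is the sensitivity.
Multiplicative parameters and attributes are compared as log-ratios, so a
pure power law $a \propto p^k$ yields slope $k$ exactly at any step size
and "sensitivity 1" means a 2-fold parameter change doubles the attribute;
for small steps this is the ordinary fractional change. For additive
parameters the abscissa is in mV.

For 2D sensitivity along a correlation, `correlation_line_family()` fits the
pair's correlation line and shifts it through sampled models; perpendiculars
are taken in a normalized space (multiplicative parameters divided by their
population median; additive midpoints in raw mV) because perpendicularity is
undefined across heterogeneous units — an interpretation that affects the
magnitude, not the sign, of perpendicular sensitivities.
`compare_line_sensitivity()` compares parallel and perpendicular slope
magnitudes per model with a paired one-sided Wilcoxon signed-rank test; this
paired comparison replaces repeated-measures ANOVA machinery, which is out
of scope.

## Synthetic targets

`make_target()` closes the loop without any recording: a ground-truth
parameter set (given, or sampled until its profile is resonant with
$Q_Z/Z_0 \ge 0.1$) is pushed through the identical simulate → profile →
attributes chain, and its attribute set becomes the fitting target. Noise,
when requested, multiplies the impedance and phase attribute values (never
the frequencies) by $1 + \mathcal N(0, \sigma)$ — the fitting operates on
attributes, so that is where measurement variability belongs.
`recovery_report()` then compares the accepted population against the truth
per parameter: range containment and the coefficient of variation of
median-normalized values.

What the synthetic generator emulates — and what it does not: it produces
exactly the attribute-level information the fitting consumes, from a model
inside the fitted class, so recovery tests probe the estimator's behaviour
under ideal conditions (identifiability up to correlation manifolds, CoV
ordering). It does not emulate electrode artifacts, trial-to-trial
variability, spiking contamination, or any biophysics outside the
three-current model — passing recovery tests therefore demonstrates the
machinery, not robustness to model misspecification.

## Numerical choices and degenerate inputs

* Quadratic peak refinement falls back to the discrete maximum when the
  three-point curvature is not negative or the vertex leaves the bracket.
* A profile without an interior maximum is flagged non-resonant
  ($f_{res} = f_0$, $Q_Z = 0$, bandwidth undefined); a phase profile without
  a downward zero crossing is flagged and the phasonant frequency is
  undefined. Both flags disqualify a model from acceptance and draw the
  penalty on the affected objectives.
* Exact ties at the $\bar g_{Ca}$ partition threshold go to the high group.
* Duplicate objective values in a crowding front contribute zero gap (no
  division by zero); fronts of one or two members are all-boundary
  (infinite crowding).
* A gene sitting exactly on a bound can only mutate inward (the polynomial
  kernel's support is the feasible interval); SBX children are clipped.
* Failed or non-finite evaluations never abort a run: they receive the
  penalty score and remain ordinary members of the sorting machinery.

## Known limitations

* The printed biological target sits at the edge of what this model class
  can reach under the package's measurement conventions: a dedicated
  minimax search bottoms out at ~4.95% worst-attribute error, so the
  5%-acceptance region for that specific target is a knife-edge pocket and
  population searches at the standard scale typically return an empty
  accepted set for it. Synthetic targets generated from within the model
  class do not suffer from this: their acceptance regions are well-posed
  and the search populates them densely. The main drivers are the assumed
  reversal potentials and the printed target's internal tensions (the
  half-height points versus the printed $Z_0$/$Z_{max}$; a 5% gap between
  printed $f_{res}$ and $f_{\varphi=0}$ in a model class whose central
  property is that those two frequencies coincide).
* Absolute fitted conductances depend on the assumed reversal potentials
  (see above); only their correlation structure and dispersion pattern are
  robustly comparable. In particular, under the default reversal potentials
  the leak conductance is *not* tightly identified: it trades against
  $\bar g_H$ along a near-perfect negative correlation across most of its
  allowed range, so pooled accepted populations show a wide $g_L$ spread.
  Which single parameters come out tight (here the Ca activation midpoint
  and, usually, its time constant) versus degenerate is itself a function
  of the assumed driving forces.
* Reference-point-guided selection concentrates each run; the diversity of
  the accepted population comes from the archive and from pooling runs, and
  is narrower than a brute-force characterization of the full acceptance
  manifold would give.
* Current clamp, multicompartment structure, spiking currents and calcium
  dynamics are outside the model by design.
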