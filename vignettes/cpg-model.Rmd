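---
title: "A Wilson-Cowan chain model of larval peristalsis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Wilson-Cowan chain model of larval peristalsis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crawlwave)
```

## The model

*Drosophila* larvae crawl by peristaltic waves: the eight abdominal
segments (A8, the most posterior, through A1) contract in sequence, left
and right sides in near-perfect synchrony. The rhythm persists when
sensory input is blocked, implicating a central pattern generator (CPG).
crawlwave implements a population-rate model of that CPG.

Each segment is one Wilson-Cowan unit: an excitatory population $E_i$ and
an inhibitory population $I_i$ with first-order dynamics

$$\tau_E \dot E_i = -E_i + (k_E - E_i)\,
   G_E\!\big(a E_i + c I_i + b\,(E_{i-1} + E_{i+1})
   + d\,(I_{i-1} + I_{i+1}) + \beta S_i + P_{\mathrm{ext},i}(t)\big),$$
$$\tau_I \dot I_i = -I_i + (k_I - I_i)\,
   G_I\!\big(e E_i + f I_i + \gamma S_i\big),$$

where the response function
$G(x) = \left[1 + e^{-\lambda(x-\theta)}\right]^{-1} -
\left[1 + e^{\lambda\theta}\right]^{-1}$
is a logistic sigmoid shifted so that $G(0) = 0$: rest (all activities
zero) is an exact equilibrium, and activity must be evoked by external
drive. The saturation factors $k_E$, $k_I$ equal the analytic suprema of
the corresponding sigmoids (`response_ceiling()`), so activities remain
bounded in $[0, k)$.

All connection weights are stored **signed** and enter the sigmoid
argument with a plus sign: within a segment $a = 16$ (recurrent
excitation), $c = -12$ ($I \to E$), $e = 15$ ($E \to I$), $f = -3$
(recurrent inhibition); between nearest-neighbour segments $b = 20$
(excitatory, $E \to E$, bidirectional) and $d = -20$ (inhibitory, each
segment's $I$ onto both neighbouring $E$). A convenience flag in the
config loader (`negate_inhibitory`) accepts files written in the
alternative unsigned-magnitude convention; for the default parameter set
the two conventions give identical dynamics. End segments simply lack the
missing-neighbour terms, which makes the chain symmetric: a pulse to
$E_8$ evokes a forward wave, the same pulse to $E_1$ the exactly mirrored
backward wave.

An isolated unit with these parameters is an oscillator under constant
input; in the chain, neighbour inhibition $d$ terminates each segment's
burst after its successor has taken over, converting oscillation into a
travelling pulse.

### Sensory feedback

The optional stretch-sensor extension adds one sensory population per
segment,

$$\tau_S \dot S_i = -S_i +
  G_S\!\big(\alpha[E_{i+1}-E_i]_+ + \alpha[E_{i-1}-E_i]_+\big),
  \qquad [x]_+ = \max(x, 0),$$

with single-neighbour terms at the ends. The rectified difference mimics
a stretch receptor: a segment is "stretched" while a neighbour contracts
more strongly than itself. $S_i$ feeds back into $E_i$ with weight
$\beta$ and into $I_i$ with weight $\gamma$. Sensory populations carry no
$(k - S)$ saturation factor; their activity is bounded through the
dynamics by the sigmoid's supremum. Their sigmoid threshold (2) is lower
than the excitatory one (4) so sensory activity leads excitatory
activity.

### Two-sided model

The two-sided variant duplicates the chain into left and right
hemisegment networks sharing all parameters, coupled within each segment
by exactly one of four contralateral connection kinds: $E\to E$,
$I\to E$, $E\to I$, $I\to I$ (`contralateral_spec()`). Simulations drive
both posterior segments with slightly different strengths (1.7 and 1.72)
so that synchrony, when observed, is a property of the coupling rather
than of identical deterministic initial conditions.

## Wave quantification

A model "contraction" is an interval of suprathreshold excitatory
activity, $E_i > \theta_C$. Against a wave duration defined from the
initiating segment's contraction onset to the terminal segment's offset,
the package computes per-segment **normalized contraction durations** and
per-neighbour-pair **intersegmental phase lags** (onset-to-onset time over
wave duration) — both dimensionless, which makes them insensitive to the
choice of time constants (the package's time-rescaling test verifies this
to $10^{-3}$).

Key numerical choices:

* **Crossing times** are refined by linear interpolation between adjacent
  samples; a sample lying exactly on the threshold counts as a crossing at
  that sample time. At the default output resolution (0.005 t.u.)
  crossing times are stable to well under $10^{-3}$ t.u.
* **$\theta_C = 0.3$** is the default everywhere; 0.2 is used as a
  secondary threshold in high-inhibition two-sided regimes where peak
  activity stays below 0.3. $\theta_C$ is an explicit argument of every
  metric function.
* **Validity**: a wave is valid when segments activate in propagation
  order and deactivate in the same order (`classify_wave()`). The
  `endpoint_relaxed` rule additionally accepts the terminal segment
  deactivating before its neighbour, which without sensory feedback it
  always does. Note that under sustained drive (2 t.u. or more) the
  *initiating* segment's externally prolonged contraction can also
  outlast its neighbour's; the wave-detection operation (`count_waves()`,
  built on onset ordering) is therefore the primary notion of "a wave",
  with offset-order classification layered on top. For the coupling-grid
  and robustness experiments the package defaults to the 1.2 t.u.
  criterion drive, under which the baseline network produces a wave valid
  under the relaxed rule.
* **Wave counting** attributes one potential wave to each complete
  suprathreshold excursion of the initiating segment and requires
  strictly ordered onsets of all remaining segments before the initiator's
  next excursion. Excursions clipped by the analysis window (no actual
  threshold crossing) are not counted — in particular, tonically
  saturated activity contains no waves. Under drives stronger than the
  single-wave threshold the initiating segment stays active long after
  the wave has passed; this is reported via the `prolonged` flag rather
  than as extra waves.
* **Left/right synchrony** pairs the $k$-th post-transient excursion of
  each segment's two sides and averages absolute onset differences.
  Classification: *synchronous* when every excursion is matched and the
  mean difference is at most 0.1 t.u.; *alternating* when each side's
  excursions fall in the other side's subthreshold gaps; *no wave* when a
  side shows no crossings; *asynchronous* otherwise. Two tolerances
  appear in the source analyses (0.1 t.u. for synchrony, 1 t.u. for
  discarding); both are exposed (`sync_tolerance`, `discard_above`).
  The default analysis window is the final 9 t.u. of a sustained-drive
  run.

## Integration

No ODE-solver package is available in the target environment, so the
integrator is part of the package (compiled C++): classical RK4 with a
fixed 0.001 t.u. step (default) and an embedded Dormand-Prince 5(4)
adaptive pair. Drive pulses are ideal rectangles; integration proceeds
piecewise between pulse edges so no step straddles a discontinuity, and
the (piecewise-constant) drive is sampled once per span at its midpoint,
which keeps Runge-Kutta stages that land exactly on an edge from reading
the wrong side of it and makes the dynamics exactly
translation-invariant in time. The two methods agree on all wave metrics
to better than $10^{-3}$, as do runs at halved resolution and
tightened tolerances. The default initial condition is rest — the unique
natural pre-wave state, since $G(0)=0$.

## Experiments

The `sweep_*` functions script the package's computational experiments,
each returning a long-format tibble (one row per grid cell) with a
machine-readable failure reason — never a fabricated metric — for
invalid cells, alongside the 0-sentinel the source figures use:

* `sweep_drive()`: strength x duration grid; locates the no-wave region,
  the multiple-wave regime under sustained intermediate drive, and the
  single-wave-regardless-of-duration regime above strength ~3.1.
* `sweep_intersegmental()`: joint ($b$, $d$) variation. Wave generation
  tolerates a wider range of inhibitory than excitatory coupling.
* `robustness_noise()`: Gaussian perturbation of $b$ and $d$, sampled
  once per undirected neighbour pair and applied symmetrically (the
  model's bidirectional-symmetry premise; a per-directed-edge mode is
  exposed). Sign preservation is enforced by rejection sampling — redraw
  rather than clip, so no probability mass piles up at zero. Success
  follows the published criterion: drive 1.7 for 1.2 t.u., a single wave,
  endpoint-relaxed ordering. Fully reproducible given a seed.
* `sensory_sweep()`: ($\beta$, $\gamma$) grids at fixed $\alpha$;
  $\beta$ equalizes and lengthens contractions (mean normalized duration
  ~0.6 at $\beta = 20, \gamma = 0$) and uniformly shortens lags;
  $\gamma$ restores the observed ~0.41 duration and slows the anterior
  pairs specifically.
* `rescue_experiment()`: matched runs without/with sensory feedback. The
  packaged weak-excitation regime uses $b = 16$ — a value chosen (the
  source prints none) as the largest $b$ that fails to propagate unaided
  while being rescued to exactly one valid wave by the printed rescue
  parameters ($\alpha = 25$, $\beta = 40$, $\gamma = 0$); weaker chains
  ($b \le 14$) ring indefinitely under that much sensory excitation.
* `two_sided_sweep()`: contralateral weight x chain weight grids with
  sustained 35 t.u. drives, classifying synchrony at $\theta_C = 0.3$
  and 0.2. $E\to E$ synchronizes up to weight ~10 and then eliminates
  waves by saturation; $I\to E$ yields the widest synchronous region;
  $I\to I$ never synchronizes; $E\to I$ synchronizes only in a small
  region.

## Reference data and what green tests establish

The package ships the published pooled behavioural summaries (35 forward
waves, 12 animals, 25 °C: normalized contraction duration
0.415 ± 0.076, intersegmental phase lag 0.087 ± 0.050, wave duration
1.39 ± 0.25 s, duty cycle 0.83 ± 0.22; wave counts for the 34 °C
conditions) as a checksum-pinned fixture, with `compare_to_reference()`
reporting deviations in units of the reference SD. Only pooled-level
comparison is possible: the per-segment behavioural curves were never
printed numerically.

The model is a stated idealization, not a fit to raw data. Green tests
establish that the implementation reproduces the model's published
quantitative behaviour (ceilings, drive thresholds, sensory durations,
synchrony regimes) and its internal invariants — not that the model
captures every feature of real crawling. Known, inherited limitations:
duty cycles are out of scope (the model omits the head/thorax movements
between waves); without sensory feedback the posterior segment contracts
longest and the anterior shortest, unlike the roughly uniform behavioural
profile; panel-specific coupling values of some published robustness
figures are unprinted, so those exact panels are reproduced at protocol
level only.

## A worked baseline

```{r baseline}
spec <- cpg_spec()   # published parameter set
traj <- simulate_cpg(spec,
                     drive_protocol(segment = 8, strength = 1.7,
                                    duration = 2),
                     t_end = 12)
m <- wave_metrics(traj, threshold = 0.3, direction = "forward")
glance(m)
tidy(m)
```

```{r plot, fig.width = 6, fig.height = 7}
autoplot(traj, threshold = 0.3)
```
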