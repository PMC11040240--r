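---
title: "Locating bat roosts from static acoustic surveys: model and methods"
author: "roostfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating bat roosts from static acoustic surveys: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roostfinder)
```

## The problem

Bat roosts — and maternity roosts in particular — are focal points for
conservation, but finding them is slow, expensive field work. Static
acoustic detectors offer an indirect route: an array of ultrasound
recorders spread over a landscape registers echolocation passes as bats
disperse from the roost each evening. The spatial pattern of those passes
carries information about where the dispersal started. `roostfinder`
turns a table of per-detector call counts into (i) a best-guess roost
position and (ii) a ranked map of search regions, so that a surveyor can
visit terrain in order of decreasing promise rather than combing the
whole area.

## Movement model

For the first 90 minutes after sunset, greater horseshoe bat
(*Rhinolophus ferrumequinum*) movement away from the roost is well
described by isotropic diffusion (the package takes this as given; it was
established by radio-tracking studies that fitted mean squared
displacement against time). If all bats start the night at a roost
$z = (z_x, z_y)$, the probability density of a bat's position at time $t$
is the free-space heat kernel

$$\phi(x, y, z, t) = \frac{1}{4\pi D t}
  \exp\!\left(-\frac{(x-z_x)^2+(y-z_y)^2}{4Dt}\right),$$

with diffusion coefficient $D$. Two values of $D$ appear in the package,
deliberately distinct:

* **Search model:** $D = 80$ m²/s (`diffusion_params()` default) — the
  rounded literature value carried into inference.
* **Simulator:** $D = 81.7$ m²/s (`sim_scenario()` default) — the value
  fitted from tracked trajectories.

Keeping the mismatch mirrors real use: the searcher never knows the true
movement rate of the population being surveyed, so validation exercises
should not hand the estimator the exact simulation parameter.

After 90 minutes the population begins returning to the roost and the
diffusive description fails; inputs to the package are therefore call
counts restricted to the first 90 minutes after sunset
(`horizon = 5400` s). The model is also isotropic and landscape-blind:
hedgerows, rivers, roads and lighting all modulate real bat movement and
are *not* represented (see Limitations).

The tail bound justifying a finite map: the probability of a bat being
beyond radius $R$ at time $t$ is $\exp(-R^2/4Dt)$
(`prob_beyond_radius()`), about 0.0055 at $R = 3$ km with the defaults —
conveniently, 3 km is also roughly the species' core sustenance zone.

## From density to expected call proportions

A detector at $X_i$ hears everything inside a disk $\Omega_i$ of radius
$r = 15$ m (a typical acoustic footprint for this quiet species). The
probability of a bat being detectable there at time $t$ is
$P_i(t) = \int_{\Omega_i} \phi\, d\omega$, the expected passes over the
night are $E_i = \int_0^T P_i(t)\, n\, dt$ for $n$ bats, and the expected
*share* of calls at detector $i$ is

$$F_i(z) = \frac{E_i(z)}{\sum_j E_j(z)},$$

in which $n$ cancels — the method never needs the colony size. The
observed counterpart is $C_i = c_i / \sum_j c_j$, where $c_i$ is the
detector's average calls per *active* night (detectors fail mid-survey,
so each is averaged over its own active nights; a detector that was
active but silent is kept with $C_i = 0$, because silence is evidence).

Two evaluation routes are provided:

* `detection_prob_exact()` integrates $\phi$ over the disk with a tensor
  polar rule (Gauss–Legendre in radius × uniform in angle, 16 × 32 nodes
  by default). It reproduces the closed form
  $1 - \exp(-r^2/4Dt)$ for a roost-centred disk to ~1e-10 and agrees
  with Monte-Carlo to sampling error.
* `detection_prob_approx()` exploits that $\phi$ is nearly constant
  across 15 m once the detector is some hundreds of metres from the
  roost: $\tilde P_i(t) = \frac{r^2}{4Dt}\exp(-d_i^2/4Dt)$, i.e. centre
  density × disk area. This is the default for grid scans — it turns a
  three-dimensional integral into a one-dimensional one and makes
  landscape-scale scanning cheap.

$\tilde P$ diverges as $t \to 0$ at $d = 0$, so it is clamped to
$[0, 1]$; it is a probability, and the clamp only engages at/very near
the roost, where the approximation is out of its regime anyway. The
worst-case-over-time error $\max_t |P_i - \tilde P_i|$ decreases
strictly with distance (about 3e-4 at 50 m, 2e-8 at 1 km);
`cmd_validate_approx()` reports this table. Note that the error at a
*fixed* time is not monotone in distance — the leading error term is
proportional to the Laplacian of $\phi$, which changes sign at
$d = \sqrt{4Dt}$ — which is why the worst-case-over-time error is the
quantity reported and tested.

The time integral has no elementary antiderivative (the integrand
behaves like $e^{-1/t}/t$), so both routes use Simpson's rule on a
uniform grid over $[0, T]$, with the $t = 0$ endpoint set to its
analytic limit (0 for $d > 0$, 1 for a detector exactly at the
candidate). The default is 501 nodes. Convergence is the contract: at
the default resolution the integral is accurate to ~0.1% for detectors
100 m from the candidate and to better than 1e-6 beyond 500 m; accuracy
degrades *only* in the first one or two time intervals for detectors
within ~100 m, where the integrand switches on abruptly. One honest
caveat: for a detector exactly at the candidate position, $P$ and
$\tilde P$ genuinely differ on a short initial time window, and the gap
in the resulting proportion vector grows (towards ~1e-2) as the time
quadrature is refined — it is an approximation-regime effect, not a
quadrature artefact.

## The error surface and point estimates

Given observed proportions $C$ and a candidate roost $z$, the raw misfit
is $\sum_i (F_i(z) - C_i)^2$ (`rho_metric()`; the exponent is
configurable to 1 or 3, with 2 the default — squaring emphasises the
high-traffic detectors most likely to sit near the roost).
`build_rho_surface()` evaluates this at the centre of every cell of an
`n × n` grid (default 500 × 500) spanning the detector bounding box,
then divides by the grid-wide maximum:

$$\rho(z) = \frac{\sum_i (F_i(z) - C_i)^2}
  {\max_{z'} \sum_i (F_i(z') - C_i)^2} \in [0, 1].$$

Because the normalizer is the maximum over the *evaluated grid*, ρ
values are grid-dependent; comparisons of ρ across differently sized
maps are not meaningful, while the *ordering* of cells (which drives
searching) is. Cells are independent, so evaluation order is
irrelevant and the scan parallelizes trivially; ties at the minimum are
broken to the first cell in row-major (north-to-south, west-to-east)
order and logged.

Two point estimates come out:

* $z_p$: the argmin cell centre of ρ — the model-based prediction.
* $CC = \sum_i C_i X_i$ (`centre_of_calls()`): the call-weighted mean of
  detector positions. Cheap and surprisingly strong when the detectors
  surround the roost — but as a convex combination it cannot leave the
  detector hull, so it fails structurally when the roost is outside the
  array. The ρ surface has no such constraint.

The separation $|z_p - CC|$ doubles as a confidence heuristic
(`confidence_heuristic()`): when both estimators agree to a few hundred
metres the roost tends to be within a few hundred metres of them;
defaults flag `high` below 500 m and `low` above 1000 m.

`search_statistics()` turns the surface into search effort: with a known
roost $z_R$, $\rho_c$ is the surface value at the cell containing $z_R$
(nearest cell, no interpolation — area statistics then stay exact
cell-count multiples), and the area/percentage of the map with
$\rho \le \tau$ is reported at $\tau = 0.1, 0.2, 0.3$ and $\rho_c$. The
$\rho_c$ entry answers: *searching cells in order of increasing ρ, how
much terrain would have been visited when the roost is found?*

## The simulator

`simulate_survey()` generates synthetic surveys from the stochastic
counterpart of the model: each of `n_agents` bats starts at the roost
and performs planar Brownian motion,
$x \leftarrow x + \sqrt{2D\Delta t}\,\xi$ per axis per step. Brownian
increments are exact in distribution at any step size, so `step_dt`
(default 1 s) only sets the resolution at which footprint crossings are
detected. A detector records one pass per *entry event*
(outside → inside its disk), with a 30 s refractory window per
agent-detector pair to avoid double-counting boundary jitter; the
refractory period is configurable, including 0. Pass counting from
trajectory crossings is a modelling choice of this package (field "bat
pass" semantics), and detection within the footprint is treated as
certain.

Nightly RNG streams are derived from the scenario seed, so
`simulate_night(sc, k)` is reproducible in isolation and whole surveys
are bit-identical under a fixed seed. `apply_failures()` overlays the
real-world nuisance of detectors dying mid-survey: each detector
survives each night with probability $p$, so active nights are
truncated-geometric, and counts from dead nights are discarded. What the
simulator does **not** emulate: landscape-steered movement, the
return-to-roost phase, inter-night behavioural variation, male bats
roosting separately, imperfect detection, and species misclassification.
Passing the validation experiments below therefore demonstrates
*internal* consistency of estimator and movement model — not performance
on field data, where those un-modelled effects dominate the error
budget.

Sanity anchors tested: the empirical mean squared displacement is
$4Dt$ within sampling error, and the fraction of agents beyond 3 km at
90 min matches $\exp(-R^2/4DT)$.

## Validation experiments and problem sizes

Two experiments mirror the method's intended use, at sizes chosen to
keep the full suite comfortably fast on a single CPU:

* **Roost inside the array:** 20 detectors on a 1.5 km-radius ring, the
  roost at (400, 250) m from the ring centre, 600 agents/night × 5
  nights, estimated on a 100 × 100 grid. Over 10 seeds the median
  $|z_p - z_R|$ is a few hundred metres (tested ≤ 500 m, about two
  grid-cell diagonals) and $z_p$ is on average at least as close as
  $CC$.
* **Roost outside the array:** same ring, roost 1 km east of the
  easternmost detector, map padded 3 km east. $CC$ is trapped inside
  the hull (error ≥ 1 km by construction, asserted every seed), while
  the low-ρ region extends toward the true roost and the median
  $|z_p - z_R|$ beats the median $|CC - z_R|$.

Numerical/design choices already fixed above, gathered for reference:
cell centres (not corners) as evaluation points; grid-max
normalization; row-major argmin tie-break; nearest-cell $\rho_c$;
Simpson 501 nodes on $[0,T]$ with analytic-limit endpoint; 16 × 32
polar rule for exact disks; clamped $\tilde P$; exponent 2; per-detector
night averaging; zero-call detectors retained, zero-night detectors
dropped.

## A worked run

```{r example, eval = FALSE}
sv <- load_survey(system.file("extdata", "synthetic_ring_survey.csv",
                              package = "roostfinder"),
                  roost = c(150, -100))   # known truth, for evaluation
surf <- build_rho_surface(sv, grid_from_survey(sv, n_x = 100))
est <- search_statistics(surf)
est
confidence_heuristic(est)
plot(surf)
```

## Limitations

* Isotropic, homogeneous diffusion: terrain effects (hedgerows as
  corridors, roads and lit areas as barriers) are the main known source
  of bias in field application and are not modelled.
* Single roost: the misfit assumes one Gaussian source. Satellite
  roosts or nearby colonies contaminate the counts.
* Seasonality: the diffusive description and the fitted $D$ come from
  the maternity season; late-summer surveys (mating behaviour,
  roost-switching) fit it worse.
* ρ is relative: only within-map comparisons and orderings are
  meaningful.
* $CC$ degrades gracefully but uninformatively when the array does not
  surround the roost; use the surface, and treat a large $|z_p - CC|$
  as a warning that the survey, not the estimator, is the problem.
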