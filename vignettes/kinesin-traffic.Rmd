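---
title: "Modelling kinesin-1 traffic on microtubule protofilaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling kinesin-1 traffic on microtubule protofilaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kintraffic)
library(dplyr)
```

## The model

Kinesin-1 walks processively towards the plus end of a microtubule along a
single protofilament, and in a cell it does so in the company of many other
motors competing for the same binding sites. `kintraffic` implements a
driven lattice gas for this situation. Each motor is a rigid dimer
occupying two adjacent lattice sites (site length $a = 8.4$ nm, the tubulin
heterodimer repeat) on a one-dimensional lattice. The dynamics is a
totally asymmetric exclusion process with Langmuir kinetics, extended by a
crowding interaction:

* **hopping** at rate $\nu$ to the next site, allowed only if that site is
  empty (hard-core exclusion); the free-motor speed is $V_0 = \nu a$;
* **attachment** from a reservoir at volume concentration $c$ at rate
  $\omega_A = \omega_a c$, wherever two adjacent sites are empty;
* **spontaneous detachment** at rate $\omega_D$;
* **facilitated detachment**: when a motor's leading head is directly
  adjacent to the trailing head of the motor in front, the rear motor's
  unbinding rate is enhanced by $\theta$ (it "bounces off"). The mirror
  rule, in which the leading motor is kicked off instead, generates an
  identical bulk law — the package exposes both and the exact
  small-ring solver confirms the equivalence to machine precision.

A second model variant adds **stochastic pausing**: a bound motor switches
into an inactive state at rate $r_\mathrm{inact}$ (equivalently a per-step
probability $p_\mathrm{inact} = r_\mathrm{inact}/\nu$) and back at
$r_\mathrm{act} = 1/T$ with $T$ the mean pause duration. Inactive motors
cannot step but remain bound, keep both detachment channels, and block the
motors behind them — the minimal rule consistent with "cannot move".
Because inactivation is rate-based it also accrues while a motor is
blocked.

The default kinesin-1 rates are $\nu = 0.66\,\mu\mathrm{m\,s^{-1}}/a
\approx 79\,\mathrm{s^{-1}}$, $\omega_D = 1/1.9\,\mathrm{s} =
0.53\,\mathrm{s^{-1}}$, $\lambda_0 = 0.018\,\mu\mathrm{m^{-1}s^{-1}}$
(anchored at low concentration), the globally fitted $\omega_a =
0.054\,\mathrm{nM^{-1}s^{-1}}$ and $\theta = 2.4\,\mathrm{s^{-1}}$, and
pausing rates $r_\mathrm{inact} = 0.004\,\nu$, $T = 0.12$ s. Internally
lengths are lattice sites and times seconds; micrometres and nanometres
appear only at I/O boundaries.

## Mean-field theory

Writing $\rho$ for the probability that a site carries a leading head
($\rho \in [0, 1/2]$; $\rho = 1/2$ is full decoration), factorising joint
occupation probabilities with the dimer correlation factor $1/(1-\rho)$
gives the bulk balance

$$\omega_A \frac{(1-2\rho)^2}{1-\rho} \;=\; \omega_D \rho +
\theta \frac{\rho^2}{1-\rho},$$

whose root is available in closed form (`stationary_density()`); at
$\theta = 0$ it reduces to the known dimer TASEP/LK result. The current is
$j(\rho) = \nu\rho(1-2\rho)/(1-\rho)$, maximal at $\rho = (2-\sqrt2)/2
\approx 0.29$ — above half of full decoration, close to the intuitive
value $1/3$ at which every dimer is followed by one vacancy. The
single-motor observables follow from the same factorisation:
$\tau = [\omega_D + \theta\rho/(1-\rho)]^{-1}$,
$V = V_0(1-2\rho)/(1-\rho)$, $l = \tau V$, and the tracer landing rate
$\lambda = \lambda_0 (1-2\rho)^2/(1-\rho)$ (`predict_observables()`).

Two derived quantities are worth singling out. The facilitated share of
the detachment flux is $\theta\rho/(\theta\rho + \omega_D(1-\rho))$ and
crosses one half at the concentration where $\rho = \omega_D/(\omega_D +
\theta)$ — about 7 nM for the fitted rates, far below the ~20 nM
half-decoration concentration (`crossover_concentration()`). And the
ratio $f = \omega_D/\theta \approx 0.22$ estimates the fraction of the
stepping cycle spent in the weakly bound one-head-bound state, if
$\theta$ is read as the dissociation rate from that state
(`weak_state_fraction()`).

`density_profile()` relaxes the site-resolved mean-field equation by
forward time-stepping (step $0.2/(\nu + \omega_A + \omega_D + \theta)$,
converged when the maximal time-derivative falls below $10^{-10}$
s$^{-1}$). On a ring it reproduces the uniform bulk value to $10^{-8}$;
with open boundaries the model does not specify the boundary processes,
and we choose zero injected flux at the minus end and unobstructed exit
at the plus end (densities beyond the lattice treated as zero), the
natural choice for a motor with no reported end-residence. At 5 nM the
entry layer flattens onto the bulk plateau within roughly 100 sites,
which is why bulk (ring) simulations suffice for micrometre-long
filaments.

The `one_site` landing variant replaces the attachment term by
$\omega_A(1-\rho)$; its landing rate is taken as $\lambda_0(1-\rho)$ by
analogy, since no microscopic geometry is defined for where the second
head would sit. It is therefore mean-field-only; the simulator always
uses the two-site rule.

## The Gillespie simulator

`simulate_lattice()` runs the exact stochastic simulation on a ring
(default $L = 2000$ sites, large enough that a ~100-step run never feels
the topology). The C++ core keeps per-channel membership sets (hoppable
motors, facilitated-eligible motors, empty adjacent pairs, active and
inactive motors) that are updated locally in the neighbourhood of each
event, with total rates assembled from set sizes; an R-level enumeration
(`enumerate_event_rates()`) recomputes the channel list from scratch and
serves as the validation oracle for this bookkeeping. All randomness is
drawn from R's RNG, so a `set.seed()`-style seed in `sim_config()` yields
bit-identical runs.

Burn-in defaults to $20/\omega_D$ (capped at half the run), after which
the simulator accumulates time-weighted densities and pair vacancies, per
block (20 blocks) for Monte-Carlo standard errors, bond crossings, and
per-event counts. Trajectories are recorded every 0.1 s as cumulative
displacement, so ring wrap-around never corrupts run lengths; run records
carry dwell, step count and detachment cause. The landing rate can be
measured two ways: from the time-averaged pair vacancy (low variance) or
by counting the landings of a sparse tracer subpopulation
(`measure_observables(..., tracers_only = TRUE)`), which is what the
experiments do.

`exact_stationary()` provides an independent oracle on rings small enough
to enumerate: it builds all configurations of dimers (with activity
flags, when pausing is on) reachable from an initial condition, assembles
the generator from the same channel enumeration, and solves the
stationary linear system. Restricting to the reachable communicating
class keeps reducible cases well-posed — with $\omega_a = 0$ the empty
lattice absorbs all mass, and the closed single-motor sector is uniform
with current $\nu/L$ per bond.

## Detecting periods of no or slow motion

Frame-based tracking at 0.1 s intervals cannot distinguish a genuinely
paused motor from a stochastically slow one frame by frame. The detector
(`detect_periods()`) therefore uses the displacement-threshold protocol:
a frame-to-frame displacement below $d_c$ (strictly; backward motion is
the 1D collapse of the off-axis criterion and counts as small) is an
onset candidate; a period starts at the frame preceding the first of
three consecutive small displacements, tolerates isolated large
displacements, and terminates at the first pair of consecutive large
ones. Two anchor choices needed fixing:

* the **duration** counts only the slow frames (start to the frame
  preceding the termination pair), so the shortest detectable period is
  exactly `onset_run` frames = 0.3 s and the censoring correction below
  extrapolates cleanly;
* the **progression** is measured to the frame at which normal motion is
  confirmed (after the termination pair). With this choice the detector
  reproduces the characteristic progressions of the protocol on this
  model — about 28–30 sites at $d_c = 5$ (40 nm), three times the
  experimental 10 sites, dropping towards ~13 at $d_c = 2$ — whereas
  ending at the last slow frame halves all of these.

On the original (never-pausing) model the detected periods are almost all
at the 0.3 s detection floor: stochastic jams drain at $\sim\nu$ per
motor, so long slow spans are exponentially suppressed and the duration
histogram has its mode in the first bins, in sharp contrast to the
exponential distribution the pausing variant produces. This qualitative
difference — not any single number — is what identifies spontaneous
pausing as the cause of the observed periods.

Durations coming off a 0.1 s grid are integer multiples of the frame
interval, and the censoring correction (`correct_pause_stats()`) accounts
for that: the tail above `tail_min` (default 0.5 s) is fitted by the
geometric maximum-likelihood estimate
$\hat\tau = -\Delta/\log\!\big(m/(m+\Delta)\big)$ (with $m$ the mean
excess and $\Delta$ the frame interval), which reduces to the continuous
mean-excess estimator for continuous data and removes the half-frame
downward bias the naive estimator suffers on grid data. Counts are then
extrapolated below the 0.3 s cutoff as $n/\exp(-\mathrm{cutoff}/\hat\tau)$
and divided by the motors' total steps for a per-step probability. Note
that pauses ended by detachment never complete in the data, so at low
concentration $\hat\tau$ estimates $1/(r_\mathrm{act} + \omega_D) =
0.113$ s rather than $T = 0.12$ s; the tests check against this
censoring-aware value.

The alternative jam-membership detector (`jam_periods()`) bypasses
displacement thresholds: a motor is in a period iff it is inactive or
chained strictly behind an inactive motor (front head exactly one site
behind the back head in front, i.e. gap zero; the model does not define
jam contiguity, and strict adjacency is the choice that excludes by
construction jams assembled with no inactive member). Across 5–50 nM the
two detectors agree within a factor of two on the per-step probability,
confirming that inactive motors — amplified by the jams behind them —
dominate the detected periods.

The amplification itself has a closed form (`jam_size()`): during a pause
of duration $T$ a jam of $N_1 = TV/(\rho^{-1} - 2)$ motors forms, its
dispersal captures more, and the geometric series gives
$N = TV/(\rho^{-1} - 2 - V/\nu)$, which with the mean-field $V(\rho)$
reduces to $N = T\nu\rho/(1-2\rho)$ — finite on $(0, 1/2)$ and divergent
only at full decoration. If jammed motors pack onto single sites
("compact" spacing) the gap term becomes $\rho^{-1} - 1$ and $N$ is
smaller at equal density. The detected per-step frequency is then
$p = p_\mathrm{inact}(1 + N)$ (`period_probability()`).

## Parameter estimation

`fit_global()` estimates $(\omega_a, \theta)$ from a concentration series
of run length, dwell time, velocity and landing rate, each cell weighted
by its standard error, with $\nu$, $\omega_D$, $\lambda_0$ fixed at their
low-concentration anchors — the same fixed/fitted split as the original
analysis. The objective is minimised by Nelder–Mead on the log scale
(positivity for free), from eight seeded multi-starts with the winner
polished by a restarted simplex; datasets whose predictions are
insensitive to $\theta$ (relative change under doubling below $10^{-3}$)
are flagged non-identifiable instead of returning an arbitrary number.
Missing cells are skipped, never imputed.

The experimental tables behind the published fit are not deposited, so
exact reproduction of $\omega_a = 5.4\times10^{-2}$ nM$^{-1}$s$^{-1}$ and
$\theta = 2.4$ s$^{-1}$ requires a user-supplied digitised CSV
(`read_dataset_csv()`; columns `c_nM, l_um, l_se, tau_s, tau_se, V_um_s,
V_se, lam_um_s, lam_se`). What the package can verify end-to-end is
recovery: `generate_synthetic_dataset()` draws the four observables from
the mean-field curves on a grid spanning the pre- and post-saturation
regimes (1–100 nM) with Gaussian noise of relative standard deviation
`rel_noise` (recorded as the cell's standard error; at zero noise the
clean curves are returned with unit weights, since zero weights are
meaningless). Noise-free data force the optimum onto the generating
rates to $10^{-4}$ relative; at 5% noise the replicate mean over 100
datasets sits within two empirical standard deviations of the truth with
relative bias below a percent.

## Study sizes and numerical choices

The bundled checks run at sizes chosen to put Monte-Carlo error at the
few-percent scale of the mean-field approximation itself:

* bulk sweeps ($\rho(\theta)$, $j(\theta)$ at $\omega_A = 0.01\nu$,
  $\omega_D = \omega_A/10$) on $L = 1000$ rings in units $\nu = 1$, 6000
  time units with a 2000-unit burn-in, over $\theta \le 0.05\nu$ — the
  regime containing the current maximum and the fitted
  $\theta/\nu \approx 0.03$. Mean-field accuracy degrades visibly
  (>10%) for $\theta \gtrsim 0.2\nu$;
* concentration series at $L = 2000$, 100 s measurement windows, with
  observables taken from cohorts of at most 400 tracer runs per
  concentration — the scale of experimental data sets; at much larger
  cohorts the few-percent mean-field bias becomes statistically
  resolvable, which is a property of the approximation, not of the
  simulator;
* pause statistics over 5–50 nM with 100 s windows (~1000–2500 detected
  periods per concentration); oracle comparisons on $L \in \{4, 6, 8\}$
  rings over $1.6\times10^4$ time units.

Tolerances: the stationary-density root is closed-form (plug-back defect
below $10^{-10}$ over random rate draws); the one-site root is bracketed
to $10^{-12}$; profile relaxation stops at $10^{-10}$; report-level
comparisons round to the two significant figures at which the constants
are quoted.

## What the synthetic data do and do not show

The generator emulates mean-field concentration curves plus independent
Gaussian noise with exactly known standard errors. Real concentration
series have correlated errors across observables (all four come from the
same movies), non-Gaussian uncertainty at low event counts, and
systematic digitisation error if extracted from figures — so passing the
recovery tests demonstrates that the estimator is consistent and
well-conditioned on its own model, not that the published rates are
correct. Likewise the trajectory generator produces ideal frame-sampled
positions; localisation noise is available (`add_localization_noise()`,
$\sigma = 20$ nm Gaussian per frame) but blinking, tracking failures and
off-axis motion are not modelled, and the off-axis angle criterion of the
experimental protocol is deliberately collapsed into the single
threshold $d_c$, as the model is strictly one-dimensional.

## Known limitations

Open-boundary *simulation* (injection/extraction at filament ends),
multi-protofilament lattices and motor mixtures are out of scope; the
spatial solver handles open boundaries only at mean-field level.
Facilitated detachment applies regardless of the rear motor's activity
state — the model does not say otherwise, and this is the simplest rule.
The compact-jam geometry enters only the amplification heuristic, not the
microscopic rules. Labelled tracers differ from bulk motors only in
their landing statistics; their bound-state kinetics are identical.
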