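# kintraffic

Stochastic and mean-field modelling of collective kinesin-1 transport
along microtubule protofilaments, for biophysicists studying motor
crowding: how steric exclusion and crowding-induced detachment shape the
concentration dependence of single-motor observables, and why
frame-sampled trajectories show long periods of no or slow motion.

## The model

Motors are rigid dimers on a 1D lattice (site length a = 8.4 nm, one
tubulin heterodimer), evolving as a totally asymmetric exclusion process
with Langmuir kinetics plus a crowding interaction:

- hopping at rate ν towards the plus end, onto empty sites only
  (V₀ = νa is the free speed);
- attachment at ω_A = ω_a·c wherever two adjacent sites are empty;
- spontaneous detachment at ω_D;
- **facilitated detachment**: the rear motor of a directly adjacent pair
  unbinds at an extra rate θ;
- optionally, **stochastic pausing**: motors switch into an immobile but
  bound inactive state at r_inact = 0.004 ν and back at 1/0.12 s.

Mean-field theory gives the stationary density ρ from the balance
ω_A (1−2ρ)²/(1−ρ) = ω_D ρ + θ ρ²/(1−ρ), the current
j = νρ(1−2ρ)/(1−ρ), and the four measurable quantities: dwell time
τ = [ω_D + θρ/(1−ρ)]⁻¹, velocity V = V₀(1−2ρ)/(1−ρ), run length
l = τV, and tracer landing rate λ = λ₀(1−2ρ)²/(1−ρ).

The package provides

- an exact Gillespie simulator (Rcpp core) with trajectory frames, run
  records, and Monte-Carlo standard errors (`simulate_lattice()`);
- an exact master-equation solver on small rings as an independent
  oracle (`exact_stationary()`);
- closed-form and iterative mean-field predictions, including spatial
  density profiles (`predict_observables()`, `density_profile()`);
- the frame-based detector of periods of no or slow motion with
  censored-exponential correction, the jam-membership detector, and the
  traffic-jam amplification theory (`detect_periods()`,
  `correct_pause_stats()`, `jam_periods()`, `jam_size()`);
- weighted least-squares estimation of (ω_a, θ) from concentration
  series, with a synthetic-dataset generator for recovery studies
  (`fit_global()`, `generate_synthetic_dataset()`);
- CSV/JSON readers and writers and a command-line interface
  (`exec/kintraffic` with subcommands
  `simulate | meanfield | detect | fit | synth | oracle`).

## Worked example

Mean-field predictions across concentrations, a stochastic simulation at
20 nM, and the two headline scalar anchors:

```r
library(kintraffic)

p <- kinesin1_params(c = 20)   # nu=79/s, omega_D=0.53/s, omega_a=0.054/nM/s, theta=2.4/s
predict_observables(p, c(0, 5, 10, 20, 50))
#>       c   rho     j   tau     V     l     lam
#> 1     0 0      0    1.89  0.66  1.25  0.018
#> 2     5 0.156  9.98 1.03  0.538 0.553 0.0101
#> 3    10 0.205 12.0  0.870 0.490 0.426 0.00787
#> 4    20 0.256 13.2  0.738 0.433 0.320 0.00577
#> 5    50 0.318 13.3  0.606 0.352 0.214 0.00350

sim <- simulate_lattice(p, config = sim_config(L = 2000, t_end = 60,
                                               burn_in = 20, seed = 1))
glance(sim)[, c("rho", "j", "tau", "V", "l", "lam")]
#>     rho     j   tau     V     l     lam
#> 1 0.258  13.6 0.751 0.441 0.334 0.00560

crossover_concentration(p)          # 7.14 nM: facilitated = spontaneous flux
weak_state_fraction(p$omega_D, p$theta)  # 0.22: weakly bound step-cycle share
```

At zero concentration the predictions reproduce the single-motor
anchors (τ = 1.9 s, V = 0.66 μm/s, λ = 0.018 μm⁻¹s⁻¹); with crowding all
four observables fall, and the simulation agrees with the analytic
curves at the few-percent accuracy of the mean-field factorisation.
Parameter recovery closes the loop:

```r
d <- generate_synthetic_dataset(p, rel_noise = 0.05, seed = 7)
tidy(fit_global(d))
#>   term    estimate unit
#> 1 omega_a   0.0534 1/nM/s
#> 2 theta     2.33   1/s
```

From the shell, the same pipelines are available as, e.g.

```sh
exec/kintraffic simulate --c 20 --t-end 60 --seed 1 --out-prefix run
exec/kintraffic detect --traj run_trajectories.csv --dc-nm 40 --out-prefix run
```

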