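# etslaw

Delay-corrected Michaelis–Menten-type rate laws for molecules whose total
concentrations change actively in time.

## The problem

The Michaelis–Menten (MM) law and its total quasi-steady-state (tQSSA)
correction describe the concentration `C(t)` of a complex formed by two
species with totals `A(t)`, `B(t)`, under the assumption that `C`
equilibrates essentially instantaneously. Many cellular processes —
signalling transients, circadian protein rhythms, gene induction — violate
that assumption: complex formation has a finite relaxation time, and for
protein–protein and TF–DNA interactions that lag leaves a visible imprint
on the dynamics.

This package implements the *effective time-delay scheme* (ETS): complex
formation relaxes on the timescale

    τ(t) = [k_δ Δ_tQ(t)]⁻¹ ,
    Δ_tQ = sqrt(1 + 2(A+B)/K + ((A−B)/K)²),   K = k_δ/k_a ,

and the delay-corrected law simply evaluates the quasi-steady state at the
delayed time:

    C_γ(t) = min{ C_tQ(t − τ(t)), A(t), B(t) } ,
    C_tQ  = ½{K + A + B − K Δ_tQ} .

For a transcription factor on a single DNA site the analogous pair is the
master-equation occupancy `C_TFQ = A_TF / [V (K + A_TF)]` and its delayed
version evaluated at `t − k_δ⁻¹ K/(K + A_TF(t))`.

Around this core the package provides, as tested modules:

* exact reference simulators (mass-action ODE; exact single-site
  two-state chain and its master-equation mean),
* a state-dependent delay-differential-equation engine (`solve_dde`),
* a bistable positive-autoregulation circuit in full / QSSA / ETS
  variants, with bifurcation scans, induction response times, and the
  analytic near-threshold response-time gap,
* a PTM-cascade model of rhythmic circadian protein degradation with the
  delay-based degradation-rate estimator,
* least-squares kinetic parameter estimation benchmarks (the
  delay-corrected laws recover `k_δ`, which quasi-steady-state laws
  cannot see),
* experiment orchestration (YAML configs, CSV/JSON outputs) and a thin
  command-line wrapper (`inst/cli/etslaw.R`).

Intended users: systems-biology modellers who fit or simulate binding
kinetics with time-varying inputs, and anyone needing a cheap, accurate
closed-form replacement for stiff mass-action binding sub-models.

## Worked example

A rhythmic partner (`A(t) = 1 + 0.5 sin(2πt/24)`) binding a constant one,
with `K = 1` and a slow complex decay `k_δ = 0.5 h⁻¹`:

```r
library(etslaw)
bp <- binding_params(K = 1, k_delta = 0.5)
dA <- driver_sinusoid(1, 0.5, period = 24)
dB <- driver_constant(1)

tt    <- seq(24, 96, by = 0.05)
exact <- simulate_binding_ode(dA, dB, bp, C0 = complex_tqssa(1, 1, bp),
                              times = seq(0, 96, by = 0.05))
ref   <- trajectory(tt, C = exact$series$C[exact$times >= 24])

c(tqssa = trajectory_error(ref, trajectory(tt, C = complex_tqssa(
    driver_value(dA, tt), driver_value(dB, tt), bp))),
  ets   = trajectory_error(ref, trajectory(tt, C = complex_ets(dA, dB, tt, bp))))
#>   tqssa     ets
#> 0.02306 0.00295

effective_delay_pp(driver_value(dA, 36), driver_value(dB, 36), bp)
#> [1] 0.894
```

The quasi-steady-state law misses the exact complex profile with RMSE
0.023 (about 7% of the mean complex level); carrying the same formula to
the delayed time cuts that error eight-fold to 0.003. The delay itself is
0.89 h at this state — bounded by `1/k_δ = 2 h` and shortened by free
molecules.

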