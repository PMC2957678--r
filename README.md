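# pathmc

Stochastic simulation and statistical model checking of intracellular
signalling networks, built around a 31-species model of HMGB1 signal
transduction.

## The problem

Extracellular HMGB1 (high-mobility group box-1) binds surface receptors
(lumped here into RAGE) and activates three coupled pathways that together
decide a cell's fate between proliferation and apoptosis:

* the **RAS-ERK cascade** (RAS → RAF → MEK → ERK → CyclinD, plus Myc), which
  drives G1-phase progression;
* the **p53-MDM2 module**, a delayed negative feedback loop
  (PI3K → PIP3 → AKT → MDM2 ⊣ p53 → *mdm2* transcript → MDM2) with a PTEN
  positive loop (p53 → PTEN ⊣ PIP3), which generates p53 pulses and
  oscillations;
* the **Rb-E2F switch** (CyclinD ⊣ Rb ⊣ E2F → CyclinE ⊣ Rb, with the explicit
  Rb-E2F complex RE), which gates the G1-S transition at about 10 h.

Crosstalk ties them together: RAS activates PI3K; E2F induces ARF which
degrades phosphorylated MDM2; p53 induces P21 which degrades the cyclins;
INK4A degrades CyclinD.  The model has 31 molecular species and 59 reactions;
the six transcription-driven syntheses (PTEN, *mdm2*, CyclinD, Myc, E2F,
CyclinE) use Hill kinetics `basal + vmax·R^n/(K^n + R^n)`, everything else is
mass action.  Eight conservation relations (e.g. `AKT + AKT_p = AKT_tot`)
leave 23 free dynamical variables.

The package simulates this network two ways — deterministically (`lsoda`) and
with Gillespie's exact direct-method SSA — and verifies temporal behaviour by
**Bayesian statistical model checking**: a property is written in Bounded
Linear Temporal Logic (BLTL), e.g.

```
F^100(p53 > 5.3*10^4)                      # p53 exceeds 5.3e4 within 100 min
(CyclinE < 10) U^300 (RAS_a/(RAS_a+RAS) > 0.5)
```

and the hypothesis `Pr≥θ[φ]` vs `Pr<θ[φ]` is decided sequentially: iid SSA
traces are model-checked one at a time and the Bayes factor

```
B_n = P(H1)/P(H0) · (1/F_(x+α, n−x+β)(θ) − 1)
```

(`F` the Beta distribution function, `x` successes in `n` samples,
Beta(α, β) prior) is compared against a threshold `T`; the error probability
of the verdict is bounded by `1/T`.

## A worked example

```r
library(pathmc)

net <- hmgb1_network(hmgb1_init = 1e3)   # baseline stimulus
net
#> Reaction network: 31 species, 59 reactions, 8 conservation relations
#> Free dynamical variables: 23

# deterministic baseline: CyclinE peaks at the G1-S transition
baseline_run("ode", t_end = 1200)
#> Baseline ODE run (1200 min horizon)
#>   CyclinE peak: 850 molecules at 655 min
#>   p53 amplitude before G1-S: 52183 molecules
#>   p53 peaks after G1-S: 0

# stochastic baseline: p53/MDM2_p keep oscillating after 10 h
baseline_run("ssa", seed = 1, t_end = 1200)
#> Baseline SSA run (1200 min horizon)
#>   CyclinE peak: 876 molecules at 616 min
#>   p53 amplitude before G1-S: 53340 molecules
#>   p53 peaks after G1-S: 8

# verify a property by sequential statistical model checking
verify_property(hmgb1_network(1e5),
                "F^20(PI3K_a/(PI3K_a + PI3K) > 0.5)",
                hypothesis_test_spec(theta = 0.9, T = 1000), base_seed = 1)
#> SMC verdict: accept_h0 (n = 65 samples, x = 65 successes, B = 1046)
#> error bound: 0.001
```

The first run says the deterministic CyclinE trajectory peaks near 600 min
(the G1-S transition) and the deterministic p53 oscillation has died out by
then; the stochastic run keeps producing p53 pulses well past 600 min — the
qualitative contrast between the two engines that motivates verifying the
stochastic model directly.  The verification call accepts, with error
probability below 1/1000, that at a high HMGB1 dose at least half of PI3K is
activated within 20 minutes in ≥ 90% of runs.

`hmgb1_properties()` returns the seven BLTL properties of the shipped suite,
`property_suite()` runs the full (property, condition) grid, `run_sweep()`
reproduces the dose-response studies, and `load_network()`/`save_network()`
read and write the YAML network config (`inst/extdata/hmgb1_network.yaml`).
A thin command-line wrapper with `simulate`/`check`/`verify` subcommands is
installed at `inst/scripts/pathmc.R`.

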