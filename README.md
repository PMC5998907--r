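# gentimefix

Fixation probabilities for beneficial mutations that shorten the
**generation time**, in constant and changing environments.

## The problem

When a new beneficial mutation arises in a large population it is at first
carried by a single lineage that can easily be lost to drift. The classical
branching-process answer for a **fecundity** mutant — one producing on
average (1+*s*)-fold more offspring per generation — is Haldane's
*p* ≈ 2*s*. But many mutants (e.g. antibiotic-resistant bacteria that
complete the cell cycle faster) produce the *same* number of offspring in a
*shorter* generation: for these **generation-time** mutants the correct
constant-environment result is *p* ≈ *s*/ln 2, so treating them as
fecundity mutants overestimates fixation by a factor 2 ln 2 ≈ 1.39.

This package models generation-time mutants with a time-dependent
Galton–Watson branching process and extends their fixation probability to
environments where the advantage *s*ₖ changes over generations:

* **Lineage model.** Each serial-passage cycle is τ Poisson growth stages
  (PGF `exp(m(x−1))`, mean *r*, default 2) followed by one binomial
  bottleneck stage (survival *r*^−τ^), composed as probability generating
  functions. A mutant with scaled advantage *s̃* = log*ᵣ*(1+*s*) has
  generation time *t*₉ = 1/(1+*s̃*) and squeezes its *i*-th **extra**
  growth generation into the cycle where the cumulative scaled advantage
  passes *i* (for constant *s*, before bottleneck
  *nᵢ* = ⌈*i*/(*s̃*τ)⌉).
* **Exact value.** The extinction probability is the nested limit
  *q* = limₙ φ₀(φ₁(⋯φₙ(0))) of the per-cycle PGFs, evaluated by backward
  accumulation with horizon doubling; *p* = 1 − *q*.
* **Effective selective advantage.** For small fluctuations around a
  reference advantage *s̄* (the Cesàro mean of *s*ₖ), first-order
  perturbation condenses the whole environment into
  *s*ₑ = Σₖ ωₖ *s*ₖ with geometric weights ωₖ = *s̄*(1−*s̄*)ᵏ, giving
  *p* ≈ *s*ₑ/ln 2 (generation time) or *p* ≈ 2*s*ₑ (fecundity).
* **Scenarios.** Closed forms for four environments: monotone relaxation of
  *s*ₖ, cyclic (seasonal) selection, Beverton–Holt census change, and AR(1)
  stochastic selection — each checked against the exact nested iteration
  and a seeded Monte Carlo lineage simulator.

## Worked example

```r
library(gentimefix)

# constant environment, s = 0.01: exact vs the two first-order limits
gentime_fixation_numeric(s = 0.01)
#> <fixation_result> p = 0.0141667 (q = 0.985833), method = nested, n = 4096
fecundity_fixation_numeric(s = 0.01)
#> <fixation_result> p = 0.0197364 (q = 0.980264), method = fixed_point, n = 1911
```

The generation-time mutant fixes with probability 0.01417 ≈ 0.01/ln 2
(the Wahl–DeHaan limit), the fecundity mutant with 0.01974 ≈ 2·0.01
(Haldane); their ratio approaches 2 ln 2.

```r
# advantage relaxing from 0.001 to 0.01: closed form, exact, Monte Carlo
monotone_closed_form(s0 = 0.001, s_inf = 0.01)
#> # A tibble: 1 × 3
#>   s_bar     s_e      p
#> 1  0.01 0.00977 0.0141
scenario_point("monotone", list(s0 = 0.001, s_inf = 0.01),
               mc = list(replicates = 1e5, seed = 102))
#>   scenario       mechanism    s0 s_inf p_exact p_approx rel_err mc_estimate mc_ci99
#> 1 monotone generation_time 0.001  0.01 0.01395   0.0141 0.01057     0.01451 0.000974
```

The early deficit (s₀ < s∞) depresses the effective advantage to
*s*ₑ = 0.00977 < *s̄* = 0.01; the approximation (0.0141) sits 1.1% from the
exact nested value (0.01395), and the 10⁵-replicate simulation agrees
within its 99% CI.

```r
# where the i-th extra mutant generation first fits (tau = 5, s_tilde = 1/20)
extra_generation_schedule(1 / 20, 5, 8)
#> # A tibble: 2 × 2
#>       i bottleneck
#> 1     1          4
#> 2     2          8
```

A command-line front end over the same functions is installed at
`inst/cli/gentimefix.R` (per-scenario flags or a YAML/JSON sweep config via
`run_config()`).

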