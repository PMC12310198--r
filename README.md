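# wormforage

Stochastic simulation and changepoint analysis of *C. elegans* foraging
reorientations.

## The problem

Off food, *C. elegans* reorients (pirouettes/omega turns) at a rate that
starts around 1.5 events/min and decays over tens of minutes to a low
baseline — the classic shift from area-restricted local search to global
search. Individual cumulative reorientation traces often show what looks
like a single abrupt switch, which has been interpreted as a discrete
behavioural decision. `wormforage` implements and tests the stochastic null
hypothesis: reorientations are random point events whose propensity decays
*smoothly*, and apparent switches are what stochastic bunching looks like.
The package is for behavioural neuroscientists and modellers who want to
simulate the null model, fit its kinetics to rate curves, run the standard
two-segment changepoint analysis, and compare model variants against data
distributionally.

## The model

Two channels evolve by the exact Gillespie stochastic simulation algorithm:

| event | update | propensity |
|---|---|---|
| reorientation | Ω ← Ω + 1 | a₁ = (α/M₀)·M + β |
| decay of the latent factor | M ← M − 1 | a₂ = γ·M |

Each step draws the waiting time τ = −ln(r₁)/a₀ from the total propensity
a₀ = a₁ + a₂ and selects the channel with probability aᵢ/a₀. Since
E[M(t)] = M₀·e^(−γt), the expected reorientation rate is
**a₁(t) = α·e^(−γt) + β**; ln(2)/γ is the memory half-life of the last food
encounter. Defaults (α = 1.49/min, β = 0.1937/min, γ = 0.11/min,
M₀ = 1000, 1631 worms, 45 min) are the decay-fit constants of the reference
population. `M₀ = 1000` makes the decay effectively continuous; `M₀ = 1`
turns the same equations into an explicit two-state switch — the
alternative hypothesis the comparison machinery discriminates against.

The analysis stack mirrors the behavioural literature: rolling 2-min-window
rate curves, bounded nonlinear least squares for (α, β, γ), exhaustive
two-segment OLS changepoint fits on cumulative curves (slopes s₁, s₂ and
transition time at the line intersection), Jensen–Shannon divergence
between joint (s₁−s₂, t_trans) histograms, and an M₀ sweep compared by
Tukey's range test.

## Worked example

```r
library(wormforage)

params <- sim_params(n_worms = 1631, seed = 1)   # defaults: decaying mode
pop    <- simulate_population(params, record_m = FALSE)
fit    <- fit_decay(population_rate(pop))
fit
#> Exponential decay fit: rate(t) = alpha * exp(-gamma t) + beta
#>   alpha = 1.4846 /min, beta = 0.1912 /min, gamma = 0.1089 /min
#>   RSS = 0.01417 over 91 points; converged: TRUE
#>   half-life = 6.36 min
```

The fitted constants recover the generating values (α = 1.49, β = 0.1937,
γ = 0.11) to within ~1%: simulating 1631 worms and re-fitting the mean
rolling-rate curve closes the loop between the event-level model and its
rate-level description. The per-worm changepoint analysis then shows the
point of the exercise — a smoothly decaying model still produces worms with
large apparent switches:

```r
cps <- population_changepoints(pop)
head(cps, 3)
#>   worm_id        s1        s2 slope_diff   t_trans rss_total degenerate
#> 1       1 0.2635369 0.0000000  0.2635369 43.808440  51.94644      FALSE
#> 2       2 1.6264706 0.2887055  1.3377650  7.809843 100.51863      FALSE
#> 3       3 0.7765182 0.1307095  0.6458088 19.456827  29.80921      FALSE
median(cps$slope_diff)
#> [1] 0.770
```

Worm 2 looks like a sharp "decision" at ~7.8 min (slope drop of 1.34
events/min); worm 1 looks like no decision at all. Both came from the same
switch-free process. `m0_sweep_study()` quantifies which variants are
distinguishable from a reference distribution; `half_life(0.07)` ≈ 9.9 min
converts a decay constant into the memory timescale it implies.

A command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/wormforage.R synth --n-worms 200 --seed 7 --out run/
Rscript inst/cli/wormforage.R changepoint --events run/events.csv --duration 45 --out run/
```

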