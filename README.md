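# cointsim

Monte Carlo tools for asking a practical question of longitudinal research in
psychology and psychosomatic medicine: **how well does cointegration
methodology survive psychometric data?** Diary and experience-sampling studies
produce exactly the data that multivariate time-series methods were *not*
designed for — ratings on coarse ordinal or interval scales, skipped
measurement occasions, and instruments with ceiling or floor effects.
`cointsim` simulates bivariate systems with known dynamics, degrades them the
way real measurement does, and scores how often the Johansen trace test still
identifies the right system type and how accurately it recovers the
equilibrium relation.

## The model and the test

Three bivariate system types are generated:

* **Stationary, I(0)** — two independent AR(1) processes
  `y_{i,t} = beta_i y_{i,t-1} + u_{i,t}`, `|beta_i| < 1`.
* **Integrated, I(1)** — each series loads on its own unit random walk:
  `y_{i,t} = b_i x_{i,t} + u_{i,t}` with `x_1 ⊥ x_2` (no common trend;
  `b_1 ≠ b_2` gives unequal variances).
* **Cointegrated, CI(1)** — both series load on the *same* walk `x_t`, so
  `y_1 − (b_1/b_2) y_2` is stationary and the cointegrating vector is
  `(1, beta_0)'` with `beta_0 = −b_1/b_2`.

Inference runs through the vector error correction model with an unrestricted
constant and one lagged difference,

```
Δy_t = Π y_{t−1} + Γ_1 Δy_{t−1} + c + u_t ,        Π = α β′
```

estimated from scratch by reduced-rank regression: the residual
product-moment matrices `S00, S01, S11` of `Δy_t` and `y_{t−1}` (each
concentrated on the short-run terms) yield the generalized eigenproblem
`|λ S11 − S10 S00⁻¹ S01| = 0`; the trace statistic for H0 `r ≤ j` is
`−T Σ_{i>j} log(1 − λ_i)`. Testing sequentially at the 1% level, rank 0 ⇔
I(1), rank 1 ⇔ CI(1), rank 2 ⇔ I(0); the leading eigenvector, normalized to
`(1, beta_0)'`, estimates the equilibrium relation. An augmented
Dickey–Fuller test (`adf_test()`) is included for univariate diagnostics.

## A worked example

```r
library(cointsim)

# a cointegrated pair with known equilibrium beta0 = -0.4/0.6 = -0.67
spec <- dgp_spec("CI1", n_obs = 200, b1 = 0.4, b2 = 0.6, seed = 1)
s    <- simulate_system(spec)
johansen_trace(s)
#> Johansen trace test (bivariate VECM, unrestricted constant)
#>
#>        statistic 10pct  5pct  1pct
#> r = 0      97.60 15.66 17.95 23.52
#> r <= 1      6.43  6.50  8.18 11.65
#>
#> Estimated rank: 1  =>  system classified as CI1 (1% level)
#> Cointegrating vector (1, beta0)': beta0 = -0.6817
```

The test rejects rank 0 decisively (97.60 > 23.52) but not rank 1
(6.43 < 11.65): one equilibrium relation, i.e. cointegration, and the
estimated `beta0 = -0.68` sits next to the true `-0.67`.

Degrade the same system into diary-style data and score a whole condition:

```r
r <- mc_condition(n_reps = 1000, master_seed = 2001,
                  degradation = list(scale = scale_spec("interval", 10),
                                     bound = bound_spec("above", 0.50)))
round(as.data.frame(r)[1:7], 3)
#>   misclass_i1 misclass_ci1 misclass_i0   mean median   iqr pct_out
#> 1        28.3         10.6           0 -1.019 -0.998 0.124      14
```

With half of all observations squashed into the ceiling category, more than a
quarter of the integrated systems are mistaken for cointegrated or stationary
ones, and the spread of the `beta0` estimates doubles relative to continuous
data — while stationary systems are still classified perfectly.
`reproduce_table("missing" | "scales" | "bounds" | "sweep", ...)` runs the
full condition grids; `mc_sweep()` traces performance against sample size.

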