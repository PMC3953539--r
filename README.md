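# signalsim

Spatially explicit agent-based simulation of animal signalling systems,
asking a comparative question from behavioural ecology: **which kinds of
signals let receivers rank signalers accurately?**

Signalers on a continuous 500 x 500 toroidal landscape display whenever
their energy budget allows, otherwise they forage; receivers try to rank
them by display effort. Three dichotomies define a 2 x 2 x 2 factorial of
model builds:

* **Items needed** — must a non-food display item (a twig, a nuptial
  gift) be secured before each display?
* **Sequential vs. lek assessment** — does a receiver inspect one
  territory per time step, or observe every displaying signaler at once?
* **Real-time vs. cumulative observation** — must displays be witnessed
  as they happen, or does effort accumulate in a persistent structure
  (nest, bower, ornament) whose current value a receiver can read in one
  observation?

Each 1440-step run ends in a 21-judge rating table (true efforts plus 20
receiver estimate vectors over 20 signalers). Ranking accuracy is the
tie-corrected Kendall's coefficient of concordance,

W = 12 S / ( m²(n³ − n) − m Σⱼ Tⱼ ),  S = Σᵢ (Rᵢ − R̄)²,  Tⱼ = Σ (t³ − t),

whose tie correction keeps zero-variance judges (receivers that never
observed anything) in the statistic. A full-factorial sweep over builds
and resource abundances feeds an OLS general linear model of W on the
design factors, with partial eta-squared (SS_F / (SS_F + SS_E)) as the
effect-size measure.

## A worked example

```r
library(signalsim)

cfg <- sim_config(n_food_init = 5000, flags = build_flags(sequential = TRUE))
res <- run_sim(cfg, seed = 7)
res
#> <run_result> build no-items/sequential/cumulative, 1440 steps, seed 7
#>   true display effort: min 0, median 45.5, max 406
#>   Kendall's W = 0.4219; lost opportunities = 0
```

Display effort varies widely across signalers (0–406 displaying steps out
of 1440, driven by initial energy reserves and foraging luck), and a
sequential receiver's tour recovers that ranking imperfectly: W = 0.42.

A miniature sweep and its linear model:

```r
sp  <- sweep_spec(food_levels = c(1000, 10000), display_levels = 2500,
                  replicates = 3, master_seed = 7)
tab <- factorial_sweep(sp)
fit_glm(tab)
#> General linear model of Kendall's W on the design factors
#>   food coding: fraction; eta^2 from sequential SS; residual df 43
#>
#>          term estimate std_error t_value eta_sq_partial  p_value
#>   (Intercept)  0.63616    0.0339  18.775             NA  < 2e-16
#>          food  0.06036    0.0321   1.879        0.07586   0.0671
#>  items_needed -0.16340    0.0289  -5.652        0.42622 1.17e-06
#>    sequential -0.24662    0.0289  -8.530        0.62854 8.54e-11
#>      realtime -0.00942    0.0289  -0.326        0.00246   0.7462
```

Needing display items and assessing signalers sequentially both cost
substantial accuracy; having to observe effort in real time (rather than
reading a cumulative structure) costs almost nothing — the persistent
pattern across builds. `condition_summaries()` produces the
means ± s.e.m. behind the figure-style views, and
`lost_opportunity_summary()` tracks steps in which a signaler had the
energy to display but could not find an item.

A thin command-line wrapper lives at `inst/scripts/signalsim.R`
(`run` / `sweep` / `analyze` subcommands over YAML configs).

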