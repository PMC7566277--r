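# anammoxr

Nitrogen mass-balance and community-succession analysis for autotrophic
nitrogen-removal bioreactors.

## The problem

Bench-scale continuously stirred tank reactors (CSTRs) fed ammonium as the
sole nitrogen source remove nitrogen through a division of labour: aerobic
ammonia oxidizers (AOB) make nitrite, nitrite oxidizers (NOB) and comammox
make nitrate, and anammox bacteria convert ammonium plus nitrite
anaerobically to dinitrogen gas, with a small nitrate by-product. Because
N₂ leaves in the gas phase it cannot be measured by ion chromatography; it
is inferred from the daily nitrogen deficit

```
N2-N = NH4-N_in − (NH4-N + NO2-N + NO3-N)_out        [mg N/day]
```

and measured nitrate is partitioned by the anammox stoichiometry — 0.26 mol
NO₃⁻ formed per 1.02 mol N₂ — into an anammox-derived pool
`apNO3 = N2 · 0.26/2.04` and a nitrification-derived remainder `npNO3`.
The ratio **N₂/npNO₃⁻** is the system performance index: anammox end
product versus the nitrate leak of nitrification. The package couples this
chemistry to 16S community time series: rarefied diversity, Bray–Curtis /
NMDS ordination, Ward + elbow successional staging, indicator-taxon
analysis, Mann–Kendall / Sen trend statistics per stage, standardized
regression of the index on environment (ENV), diversity (DIV) and
composition (COM) predictor groups with exhaustive AIC subset selection,
and db-RDA of composition on the environment.

A mechanistic guild-based CSTR simulator (Monod kinetics, attached and
suspended biomass, disturbance events, exact nitrogen conservation) plus a
Dirichlet-multinomial sequencing emulator generates fully synthetic
chemistry + count-table inputs with known ground truth, so every statistic
can be validated by recovery of planted structure. It is intended for
environmental engineers and microbial ecologists analysing reactor time
series, and as a testbed for succession statistics.

## Worked example

```r
library(anammoxr)

run  <- simulate_scenario("succession", seed = 1)   # 56-day disturbed CSTR
part <- partition_nitrogen(run$chem)
part$ratio_smoothed <- moving_average(part$day, part$ratio, 6.25)
print(part)
#> Nitrogen partition over 56 days (mg N/day)
#>   mean N2 61.81 | mean npNO3- 16.56 | mean apNO3- 7.88
#>   N2/npNO3- ratio: mean 5.656 (defined on 56/56 days)

stages <- cluster_stages(bray_curtis(run$community))
print(stages)
#> Stage assignment: 3 stages over 56 samples
#>   blocks: stage 1 [1-14], stage 2 [15-34], stage 3 [35-56]

trend_by_stage(run$community$sample_days,
               part$ratio_smoothed[match(run$community$sample_days, part$day)],
               stages$labels)
#>   stage  n    S     Z  p_value sen_slope
#> 1     1 14  -65 -3.50 4.59e-04    -0.170
#> 2     2 20  190  6.13 8.68e-10     0.262
#> 3     3 22  227  6.37 1.86e-10     0.156
#> 4   all 56 1322  9.34 9.98e-21     0.221
```

Reading this: most of the influent nitrogen (61.8 of 86.4 mg N/day on
average) leaves as inferred N₂. Ward clustering of the Bray–Curtis matrix
finds three successional stages, one sample off the planted boundaries
(truth: 1–13, 14–34, 35–56). The performance index falls during the
post-disturbance stage (Sen's slope −0.17/day), recovers through the
middle stage (+0.26/day) and keeps improving more slowly late (+0.16/day)
— the succession-drives-performance pattern the simulator plants.

`run_full_pipeline(pipeline_config(scenario = "succession", seed = 1))`
writes all result tables (partition, diversity, ordination, stages,
indicators, trends, model comparison, db-RDA) as CSV plus a run log; the
same config and seed give byte-identical outputs. A thin CLI over the same
functions lives at `inst/cli/anammoxr.R`
(`simulate`, `partition`, …, `run-all`). File formats and custom scenarios
(YAML/JSON) are described in `vignettes/nitrogen-succession.Rmd`.

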