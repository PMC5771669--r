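# nucbarrier

Quantitative analysis of asymmetric DNA-circle inheritance in budding
yeast: how the lateral diffusion barrier in the outer nuclear membrane at
the bud neck confines non-centromeric DNA circles (including the
aging-driving extrachromosomal rDNA circles, ERCs) to the mother cell, and
what that retention costs the mother in replicative lifespan.

The package is organised as an analysis workflow — numbered drivers under
`analysis/` over a fully tested package in `R/` — and covers five stages:

1. **Synthetic cohorts** (`gen_flip_traces()`, `gen_circle_observations()`,
   `gen_timelines()`, `gen_rim_profiles()`): seeded generators that emulate
   the statistical structure of the underlying microscopy assays, so every
   downstream estimator is testable without raw images.
2. **Circle segregation** (`propagation_frequency()`, `stage_durations()`,
   `propagation_flux()`): the circle-weighted propagation statistic

   ```
   1 - (n1*p1 + 2*n2*p2 + 4*n4*p4) / (n1 + 2*n2 + 4*n4)
   ```

   over cells carrying 1, 2 or 4 circles, anaphase stage durations
   (early: nuclear entry to dumbbell; late: dumbbell to karyokinesis), and
   the per-minute circle passage flux per stage.
3. **FLIP Barrier Index** (`normalize_traces()`, `pool_profiles()`,
   `fit_one_phase_decay()`, `time_to_fraction()`, `barrier_index()`):
   control-normalized photobleaching decays fit to
   `Y(t) = P + (100 - P) exp(-K t)` with Y0 fixed at 100, inverted at the
   75% threshold, and summarized as `BI = t75(bud) / t75(mother)` with
   delta-method errors. Higher BI = tighter barrier; a bud that never
   decays gives a censored BI ("n.d.").
4. **NPC colocalization** (`align_profiles()`, `circle_fold_change()`):
   nuclear-rim intensity profiles aligned to the brightest mCherry pixel
   (the circle), averaged where more than 10 cells contribute, and
   expressed as the GFP fold change at the circle versus the rim mean.
5. **ERC accumulation and lifespan** (`simulate_lineages()`,
   `survival_summary()`, `load_at_generation()`,
   `southern_fold_change()`): a stochastic retention/firing/excision model
   of ERC load in the mother (`E[L_{g+1}] = (1+f) r E[L_g] + r e`), with
   death at a load threshold, survival summaries and densitometry fold
   changes.

See `vignettes/nuclear-barrier-methods.Rmd` for the models, assumptions,
parameter meanings and numerical choices.

## Worked example

```r
library(nucbarrier)

# simulate a wild-type-like FLIP cohort and measure the Barrier Index
cfg <- flip_sim_config(n_cells = 30, seed = 11)
bi  <- flip_barrier_index(gen_flip_traces(cfg), background = cfg$background)
bi
#> Barrier Index = 39.9 +/- 12.2 (t75 bud 907 s / mother 22.7 s)

# segregation statistic on 10,000 cells with 17% per-circle passage
obs <- gen_circle_observations(segregation_sim_config(
  n_cells = 10000, class_mix = c(0.6, 0.3, 0.1), p_pass = 0.17, seed = 201))
propagation_frequency(obs)
#> Propagation frequency: 0.171 (mean 0.171 +/- 0.003 SEM over 3 experiment(s), n = 10000 cells)

# ERC model: tight (96%) vs relaxed (83%) retention
for (r in c(0.96, 0.83)) {
  lin <- simulate_lineages(erc_config(r = r, n_lineages = 20000, seed = 501))
  cat(sprintf("r = %.2f: median lifespan %g generations, load at g16 = %.1f\n",
              r, survival_summary(lin)$median, load_at_generation(lin, 16)$mean))
}
#> r = 0.96: median lifespan 24 generations, load at g16 = 138.1
#> r = 0.83: median lifespan 36 generations, load at g16 = 23.4
```

The Barrier Index of ~40 is the tight-barrier regime of wild-type cells;
the propagation frequency recovers the generating per-circle passage
probability (0.17, the heat-stress regime, versus 0.04 under optimal
growth); and relaxing circle retention from 96% to 83% simultaneously
extends the simulated median lifespan and lowers the ERC load of
16-generation-old mothers several-fold — the core trade-off the pipeline
quantifies.

## The analysis workflow

```sh
Rscript analysis/01_simulate_cohorts.R    # synthetic tables -> results/data/
Rscript analysis/02_flip_barrier.R        # Barrier Index per condition -> results/bi.csv
Rscript analysis/03_circle_segregation.R  # frequencies, durations, flux -> results/*.csv
Rscript analysis/04_npc_colocalization.R  # aligned profiles, fold change -> results/coloc.csv
Rscript analysis/05_erc_lifespan.R        # survival curves, ERC loads -> results/erc_*.csv
```

Each driver prints what it found and writes plain-CSV tables under
`results/`.

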