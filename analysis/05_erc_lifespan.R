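#!/usr/bin/env Rscript
# ERC accumulation and replicative lifespan as a function of circle
# retention. Simulates mother lineages at the measured retention levels
# (96% optimal, 83% heat), summarizes survival and 16-generation ERC loads,
# and illustrates lane densitometry. Writes results/erc_survival.csv and
# results/erc_summary.csv.

suppressPackageStartupMessages(library(nucbarrier))
dir.create("results", showWarnings = FALSE)

retentions <- c(optimal = 0.96, heat = 0.83)
surv_rows <- sum_rows <- list()
for (cond in names(retentions)) {
  lin <- simulate_lineages(erc_config(r = retentions[[cond]],
                                      n_lineages = 20000,
                                      seed = 500 + match(cond, names(retentions))))
  ss <- survival_summary(lin)
  la <- load_at_generation(lin, 16)
  surv_rows[[cond]] <- data.frame(condition = cond,
                                  generation = ss$generations,
                                  survival = ss$survival)
  sum_rows[[cond]] <- data.frame(condition = cond, r = retentions[[cond]],
                                 median_lifespan = ss$median,
                                 load_g16 = la$mean, load_g16_se = la$se,
                                 n_lineages = ss$n)
}
write.csv(do.call(rbind, surv_rows), "results/erc_survival.csv",
          row.names = FALSE)
summ <- do.call(rbind, sum_rows)
write.csv(summ, "results/erc_summary.csv", row.names = FALSE)

cat("ERC model at measured retention levels (f = 0.6 origin firing,",
    "e = 0.1 excisions/division, death at 1000 copies):\n")
print(summ, row.names = FALSE)
cat(sprintf("\nRelaxed retention extends median lifespan (%g -> %g generations)\n",
            summ$median_lifespan[summ$condition == "optimal"],
            summ$median_lifespan[summ$condition == "heat"]))
cat(sprintf("and lowers the 16-generation ERC load %.1f-fold.\n",
            summ$load_g16[summ$condition == "optimal"] /
              summ$load_g16[summ$condition == "heat"]))

# densitometry of aged-cell lanes: four concatemer bands summed per lane
lane_optimal <- c(10, 5, 3, 2)
lane_heat <- c(3, 2, 0.5, 0.56)
cat(sprintf("Southern lane fold change (optimal/heat): %.2f\n",
            southern_fold_change(lane_optimal, lane_heat)))
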