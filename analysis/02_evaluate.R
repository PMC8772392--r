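#!/usr/bin/env Rscript
# Stage 2: station-based model evaluation.
#
# Treats the gridded cube as the "model" and the sampled noisy stations as
# the observation network, then computes mean bias (MB), mean gross error
# (GE) and RMSE per station plus the unweighted all-station average, with
# benchmark flags (|MB| <= 0.5 degC, GE <= 2 degC). With 0.5 degC
# observation noise and an unbiased model, MB should sit near 0, GE near
# 0.5 * sqrt(2/pi) ~= 0.40 degC and RMSE near 0.5 degC.

library(urbanheat)

cfg <- default_config(variant = "all", out_dir = "results/pipeline")
run_stage("evaluate", cfg, verbose = TRUE)

tab <- read.csv(file.path(cfg$out_dir, "metrics.csv"))
print(tab, digits = 3)
all_row <- tab[tab$station_id == "ALL", ]
cat(sprintf("\nAll-station average: MB %.3f, GE %.3f, RMSE %.3f degC over %d paired hours\n",
            all_row$MB, all_row$GE, all_row$RMSE, all_row$n))
cat(sprintf("Benchmark pass rate: %d/%d stations on |MB|, %d/%d on GE\n",
            sum(tab$mb_ok[tab$station_id != "ALL"]), nrow(tab) - 1,
            sum(tab$ge_ok[tab$station_id != "ALL"]), nrow(tab) - 1))
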