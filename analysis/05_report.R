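#!/usr/bin/env Rscript
# Stage 5: human-readable digest of all prior outputs.

library(urbanheat)

cfg <- default_config(variant = "all", out_dir = "results/pipeline")
run_stage("report", cfg, verbose = TRUE)

cat("\n")
cat(readLines(file.path(cfg$out_dir, "report.txt")), sep = "\n")
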