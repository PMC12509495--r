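#!/usr/bin/env Rscript
# Object-location-memory behavior: sliding-window discrimination index and
# the headline windows (first 3 min of test, first 12 min of sample), with
# the paired test-vs-sample comparison.

suppressPackageStartupMessages(library(cholinepipe))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

run <- run_experiment(experiment_config(seed = 1, render = FALSE))
di <- analyze_di(run)

write.csv(di$sliding, "results/analysis/di_sliding.csv", row.names = FALSE)
write.csv(di$headline, "results/analysis/di_headline.csv", row.names = FALSE)

test_di <- di$headline$di[di$headline$phase == "test"]
sample_di <- di$headline$di[di$headline$phase == "sample"]
tt <- t.test(test_di, sample_di, paired = TRUE)
cat(sprintf("DI (test, first 3 min):    %.2f +/- %.2f (mean +/- SD, n = %d)\n",
            mean(test_di), sd(test_di), length(test_di)))
cat(sprintf("DI (sample, first 12 min): %.2f +/- %.2f\n",
            mean(sample_di), sd(sample_di)))
cat(sprintf("paired t(%d) = %.2f, p = %.3g\n", tt$parameter, tt$statistic,
            tt$p.value))
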