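#!/usr/bin/env Rscript
# Delta-F/F correction quality on the simulated study: per session, the
# adjusted-control fit (alpha, beta) and the correlation between the
# recovered activity (corrected, resampled to 30 Hz, smoothed 0.5 s,
# z-scored) and the known latent signal.  On synthetic ground truth this
# quantifies the correction's fidelity, including the slow-signal
# attenuation discussed in the methods vignette.

suppressPackageStartupMessages(library(cholinepipe))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

cfg <- experiment_config(seed = 1, render = FALSE)
run <- run_experiment(cfg)

rows <- do.call(rbind, lapply(run$sessions, function(s) {
  ses <- simulate_session(s$generator, mouse_id = s$meta$mouse_id,
                          oblom_id = s$meta$oblom_id)
  d <- preprocess_session(ses$photometry)
  data.frame(session_id = s$meta$session_id, phase = s$meta$phase,
             alpha = d$control_fit$alpha, beta = d$control_fit$beta,
             corr_truth = cor(d$values,
                              moving_average(ses$truth$z_true, 0.5, 30)))
}))
write.csv(rows, "results/analysis/correction_fidelity.csv", row.names = FALSE)

cat(sprintf("Correction fidelity across %d sessions: corr(dFF, truth) = %.3f [%.3f, %.3f]\n",
            nrow(rows), mean(rows$corr_truth), min(rows$corr_truth),
            max(rows$corr_truth)))
cat("The residual shortfall reflects the quadratic detrend absorbing part of\n",
    "the slow latent structure (session-start transient, tone drift).\n")
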