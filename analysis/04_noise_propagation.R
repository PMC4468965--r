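#!/usr/bin/env Rscript
# Attribute promoter excess noise to regulators: fit the ridge
# noise-propagation model on a synthetic network with known strengths,
# select the prior by cross-validation, and rank regulators by
# significance. Writes results/propagation_fit.tsv and
# results/propagation_cv.tsv.

library(regnoise)
dir.create("results", showWarnings = FALSE)

message("Generating a 1000-promoter x 20-regulator network (edge prob 0.1,
residual noise at 2x signal SD) ...")
net <- gen_network(seed = 20260929L)

message("Cross-validating the prior strength and refitting ...")
fit <- fit_propagation(net$E, net$M, n_repeats = 50, seed = 20260930L)
print(fit)

rk <- rank_significant(fit)
rk$V_true <- net$V_true[rk$regulator]
write_tsv_table(rk, "results/propagation_fit.tsv")
write_tsv_table(fit$cv_curve, "results/propagation_cv.tsv")

cat(sprintf(
  "Recovered strengths correlate with the planted ones at r = %.3f; the fit
explains %.1f%% of the excess-noise variance (generating signal fraction
%.1f%%). %d of 20 regulators pass V_r > sigma(V_r).\n",
  cor(fit$V, net$V_true), 100 * fit$frac_var_explained,
  100 * net$signal_var / (net$signal_var + net$noise_sd^2), nrow(rk)))
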