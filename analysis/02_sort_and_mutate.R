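#!/usr/bin/env Rscript
# Simulate five rounds of FACS sort-and-mutate evolution towards a medium
# expression target (gate mu* = 8.1, tau = 0.03) starting from a library
# spanning +-2 log units, with floor-level noise. Writes
# results/evolution_trajectory.tsv and results/final_population.tsv.

library(regnoise)
dir.create("results", showWarnings = FALSE)

fp <- noise_floor_params(0.025, 450, 0)
gate <- selection_gate(8.1, 0.03)
set.seed(20260927L)
mu0 <- runif(200, 8.1 - 2, 8.1 + 2)
pop <- promoter_population(mu0, minimal_variance(exp(mu0), fp))

message("Evolving 5 rounds at 2e5 cells/round ...")
res <- evolve_population(pop, rep(list(gate), 5), mutation_kernel(),
                         cells_sampled = 2e5, cells_selected = 2e5,
                         seed = 20260928L, floor_params = fp)
print(res$summary, digits = 3)

write_tsv_table(res$summary, "results/evolution_trajectory.tsv")
write_tsv_table(res$population, "results/final_population.tsv")

sl <- confint(lm(mean_excess ~ round, data = res$summary))["round", ]
cat(sprintf(
  "Mean |mu - mu*| fell from %.2f to %.2f over 5 rounds, while the slope of
mean excess noise per round is [%.1e, %.1e] (95%% CI): selection grips the
mean hard and leaves noise at its default floor level.\n",
  res$summary$mean_abs_dev[1], res$summary$mean_abs_dev[6], sl[1], sl[2]))
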