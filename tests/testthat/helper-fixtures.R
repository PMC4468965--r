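# shared fixtures: typical FACS-era parameter values and small constructors

facs_floor <- function() noise_floor_params(0.025, 450, 0)
facs_gate <- function() selection_gate(8.1, 0.03)

# a random constructive scenario (environments + regulator + basal promoter)
# for identity checks between the reduced (X, Y, R, S) forms and the
# explicit environment-averaged log-fitness
random_scenario <- function(seed, n_env = 12) {
  set.seed(seed)
  gr <- gen_environment_and_regulator(
    n_environments = n_env,
    mu_e_mean = runif(1, 5, 10),
    mu_e_spread = runif(1, 0.2, 2),
    tau = runif(1, 0.05, 1),
    target_R = runif(1, -0.95, 0.95),
    target_S = runif(1, 0.3, 4),
    seed = seed + 1000L)
  list(env = gr$env, reg = gr$reg,
       sigma2 = runif(1, 0.01, 0.6),
       c = runif(1, -2, 2))
}
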