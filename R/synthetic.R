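#' Synthetic flow-cytometry populations with a planted noise floor
#'
#' Generates per-promoter expression distributions whose variance of
#' log-fluorescence sits on the theoretical minimal-variance curve plus a
#' planted non-negative excess. Mean log-expression is drawn uniformly over
#' a range spanning somewhat more than a decade around the medium-expression
#' regime of a typical sort experiment; per-cell log-fluorescence values are
#' Gaussian (fluorescence distributions across cells are well approximated
#' by log-normals). Ground truth is returned alongside the samples.
#'
#' @param n_promoters Number of promoters.
#' @param floor_params A [noise_floor_params()]; defaults to the fitted
#'   values of a typical FACS dataset, `(0.025, 450, 0)`.
#' @param mean_log_range Range of mean log-expression (natural-log
#'   GFP-molecule units), default `c(6.5, 9.5)` around the medium target
#'   `~8.1`.
#' @param excess_fraction Fraction of promoters receiving planted excess
#'   noise (default 0.5).
#' @param excess_mean Mean of the exponential planted-excess distribution
#'   (default 0.05, the study's headline excess threshold; the exponential
#'   family is a fixture choice emulating the long-tailed look of native
#'   excess distributions).
#' @param n_cells Cells per promoter sample (default 500).
#' @param outlier_fraction Fraction of per-cell values replaced by gross
#'   outliers at +-10 sample SD (default 0).
#' @param seed Integer seed.
#' @return List with `samples` (long data frame `promoter_id`, `log_value`)
#'   and `truth` (data frame `promoter_id`, `mean_log`, `var_log`,
#'   `floor_variance`, `excess_noise`, `n_cells`).
#' @export
gen_flow_populations <- function(n_promoters = 500,
                                 floor_params = noise_floor_params(0.025, 450, 0),
                                 mean_log_range = c(6.5, 9.5),
                                 excess_fraction = 0.5,
                                 excess_mean = 0.05,
                                 n_cells = 500,
                                 outlier_fraction = 0,
                                 seed = 1L) {
  stopifnot(n_promoters >= 1L, n_cells >= 2L,
            excess_fraction >= 0, excess_fraction <= 1)
  set.seed(seed)
  mean_log <- stats::runif(n_promoters, mean_log_range[1], mean_log_range[2])
  fl <- minimal_variance(exp(mean_log), floor_params)
  has_excess <- seq_len(n_promoters) %in%
    sample.int(n_promoters, round(excess_fraction * n_promoters))
  excess <- ifelse(has_excess, stats::rexp(n_promoters, 1 / excess_mean), 0)
  var_log <- fl + excess
  truth <- data.frame(promoter_id = sprintf("P%04d", seq_len(n_promoters)),
                      mean_log = mean_log, var_log = var_log,
                      floor_variance = fl, excess_noise = excess,
                      n_cells = n_cells)
  samples <- do.call(rbind, lapply(seq_len(n_promoters), function(i) {
    x <- stats::rnorm(n_cells, mean_log[i], sqrt(var_log[i]))
    if (outlier_fraction > 0) {
      n_out <- round(outlier_fraction * n_cells)
      if (n_out > 0) {
        pos <- sample.int(n_cells, n_out)
        x[pos] <- mean_log[i] +
          sample(c(-1, 1), n_out, replace = TRUE) * 10 * sqrt(var_log[i])
      }
    }
    data.frame(promoter_id = truth$promoter_id[i], log_value = x)
  }))
  list(samples = samples, truth = truth)
}

#' Synthetic environment ensemble and regulator hitting target (R, S)
#'
#' Constructs desired expression levels across environments and a regulator
#' whose mean activities achieve an exact target Pearson correlation with
#' them (by combining the standardized desired levels with an exactly
#' orthogonalized noise direction) and whose within-environment variance is
#' set from the target signal-to-noise, `sigma_r2 = var(r_e) / S^2`.
#'
#' @param n_environments Number of environments (>= 3 for a nontrivial
#'   correlation).
#' @param mu_e_mean,mu_e_spread Mean and SD of desired log-expression levels
#'   across environments.
#' @param tau Fitness-function width (default 0.03, a typical sorter gate
#'   width).
#' @param target_R Target correlation in `[-1, 1]`.
#' @param target_S Target signal-to-noise (> 0).
#' @param seed Integer seed.
#' @return List with `env` ([environment_ensemble()]), `reg`
#'   ([regulator_profile()]) and the realized `R` and `S`.
#' @export
gen_environment_and_regulator <- function(n_environments = 50,
                                          mu_e_mean = 8.1,
                                          mu_e_spread = 0.5,
                                          tau = 0.03,
                                          target_R = 0.64,
                                          target_S = 2,
                                          seed = 1L) {
  stopifnot(n_environments >= 3L, abs(target_R) <= 1, target_S > 0, tau > 0)
  set.seed(seed)
  mu_e <- stats::rnorm(n_environments, mu_e_mean, mu_e_spread)
  w <- rep(1 / n_environments, n_environments)
  z1 <- (mu_e - mean(mu_e)) / sqrt(wvar(mu_e, w))
  eta <- stats::rnorm(n_environments)
  eta <- eta - mean(eta) - z1 * wcov(z1, eta, w) / wvar(z1, w)
  r_e <- if (abs(target_R) == 1) {
    sign(target_R) * z1
  } else if (max(abs(eta)) == 0) {
    stop("degenerate noise direction; change the seed")
  } else {
    target_R * z1 + sqrt(1 - target_R^2) * eta / sqrt(wvar(eta, w))
  }
  sigma_r2 <- wvar(r_e, w) / target_S^2
  env <- environment_ensemble(mu_e, tau)
  reg <- regulator_profile(r_e, sigma_r2)
  rs <- regulator_RS(env, reg)
  list(env = env, reg = reg, R = rs$R, S = rs$S)
}

#' Synthetic regulatory network with planted noise-propagation strengths
#'
#' Samples a binary promoters x regulators incidence matrix at a given edge
#' probability, draws non-negative true propagation strengths, and emits
#' excess noise `E = M V_true + noise`.
#'
#' @param n_promoters,n_regulators Network dimensions (default 1000 x 20).
#' @param edge_prob Probability of each promoter-regulator edge
#'   (default 0.1, so promoters typically have a handful of inputs).
#' @param v_mean Mean of the exponential distribution of true strengths
#'   (default 0.05, on the excess-noise scale).
#' @param noise_sd Residual noise SD; `NULL` (default) sets it to
#'   `noise_to_signal` times the SD of the planted signal `M V_true`.
#' @param noise_to_signal Residual-to-signal SD ratio used when
#'   `noise_sd` is `NULL` (default 2).
#' @param seed Integer seed.
#' @return List with `M` (incidence matrix), `V_true`, `E`, `noise_sd` and
#'   `signal_var` (variance of `M V_true`).
#' @export
gen_network <- function(n_promoters = 1000, n_regulators = 20,
                        edge_prob = 0.1, v_mean = 0.05,
                        noise_sd = NULL, noise_to_signal = 2, seed = 1L) {
  stopifnot(n_promoters >= 1L, n_regulators >= 1L,
            edge_prob >= 0, edge_prob <= 1)
  set.seed(seed)
  M <- matrix(stats::rbinom(n_promoters * n_regulators, 1, edge_prob),
              n_promoters, n_regulators,
              dimnames = list(sprintf("P%04d", seq_len(n_promoters)),
                              sprintf("TF%02d", seq_len(n_regulators))))
  V_true <- stats::setNames(stats::rexp(n_regulators, 1 / v_mean),
                            colnames(M))
  signal <- drop(M %*% V_true)
  if (is.null(noise_sd)) noise_sd <- noise_to_signal * stats::sd(signal)
  E <- signal + stats::rnorm(n_promoters, 0, noise_sd)
  list(M = M, V_true = V_true, E = E, noise_sd = noise_sd,
       signal_var = stats::var(signal))
}

#' Synthetic condition-wise log fold-changes coupled to excess noise
#'
#' Draws per-gene log fold-changes across conditions with per-gene variance
#' `a * excess + b`, so the running-mean plasticity curve over excess-noise
#' cutoffs is increasing when the coupling `a > 0` and flat when `a = 0`.
#'
#' @param excess Excess noise per promoter (one gene per promoter).
#' @param coupling_to_excess Slope `a` of the per-gene logfc variance in
#'   excess noise.
#' @param base_var Baseline logfc variance `b` (default 0.1).
#' @param n_conditions Conditions per gene (default 240).
#' @param seed Integer seed.
#' @return Long data frame `gene_id`, `condition`, `logfc`.
#' @export
gen_plasticity <- function(excess, coupling_to_excess = 1, base_var = 0.1,
                           n_conditions = 240, seed = 1L) {
  stopifnot(n_conditions >= 2L, base_var >= 0)
  set.seed(seed)
  n <- length(excess)
  v <- pmax(coupling_to_excess * excess + base_var, 0)
  data.frame(gene_id = rep(sprintf("g%04d", seq_len(n)), each = n_conditions),
             condition = rep(seq_len(n_conditions), n),
             logfc = stats::rnorm(n * n_conditions,
                                  0, rep(sqrt(v), each = n_conditions)))
}
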