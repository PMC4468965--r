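#' Environment ensemble
#'
#' The selective environments a promoter experiences. In each environment `e`
#' fitness is a Gaussian function of log-expression centred on the desired
#' level `mu_e` with width `tau` (held constant across environments for
#' analytical transparency). Log-fitness across the ensemble is the weighted
#' average of per-environment log-fitness.
#'
#' @param mu_e Desired log-expression level per environment.
#' @param tau Width of the fitness function (log units, > 0).
#' @param weights Optional per-environment frequencies (default uniform);
#'   normalized to sum to 1.
#' @return An object of class `environment_ensemble`.
#' @examples
#' environment_ensemble(c(7, 8, 9), tau = 0.5)
#' @export
environment_ensemble <- function(mu_e, tau, weights = NULL) {
  stopifnot(length(mu_e) >= 1L, is.numeric(tau), length(tau) == 1L, tau > 0)
  if (is.null(weights)) weights <- rep(1 / length(mu_e), length(mu_e))
  stopifnot(length(weights) == length(mu_e), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  structure(list(mu_e = as.numeric(mu_e), tau = tau, weights = weights),
            class = "environment_ensemble")
}

#' Regulator activity profile
#'
#' A regulator's mean activity per environment, plus its within-environment
#' (noise) variance `sigma_r2`, assumed constant across environments.
#'
#' @param r_e Mean activity per environment (aligned with the ensemble).
#' @param sigma_r2 Within-environment activity variance (> 0).
#' @return An object of class `regulator_profile`.
#' @export
regulator_profile <- function(r_e, sigma_r2) {
  stopifnot(length(r_e) >= 1L, is.numeric(sigma_r2), length(sigma_r2) == 1L,
            sigma_r2 > 0)
  structure(list(r_e = as.numeric(r_e), sigma_r2 = sigma_r2),
            class = "regulator_profile")
}

# weighted population moments (the ensemble averages of the theory)
wmean <- function(x, w) sum(w * x)
wvar <- function(x, w) { m <- sum(w * x); sum(w * (x - m)^2) }
wcov <- function(x, y, w) sum(w * (x - sum(w * x)) * (y - sum(w * y)))

#' Expression mismatch Y
#'
#' The across-environment spread in desired expression levels, measured in
#' units of the combined width of the fitness function and the promoter's
#' own expression distribution: `Y^2 = var(mu_e) / (sigma2 + tau^2)`.
#' Promoters with `Y >> 1` are those selection requires to vary strongly
#' across environments.
#'
#' @param env An [environment_ensemble()].
#' @param sigma2 Promoter expression variance (log scale, >= 0).
#' @return `Y` (>= 0); zero iff all desired levels are equal.
#' @export
mismatch_Y <- function(env, sigma2) {
  stopifnot(inherits(env, "environment_ensemble"), sigma2 >= 0)
  sqrt(wvar(env$mu_e, env$weights) / (sigma2 + env$tau^2))
}

#' Correlation R and signal-to-noise S of a regulator
#'
#' `R` is the (weighted) Pearson correlation between the desired expression
#' levels `mu_e` and the regulator's mean activities `r_e`;
#' `S^2 = var(r_e) / sigma_r2` is the ratio of the regulator's
#' across-environment activity spread to its within-environment noise.
#'
#' @param env An [environment_ensemble()].
#' @param reg A [regulator_profile()] aligned with `env`.
#' @return Named list with `R` and `S`. When `r_e` has zero variance `R` is
#'   `NA` (undefined) and `S = 0`.
#' @export
regulator_RS <- function(env, reg) {
  stopifnot(inherits(env, "environment_ensemble"),
            inherits(reg, "regulator_profile"),
            length(reg$r_e) == length(env$mu_e))
  w <- env$weights
  vr <- wvar(reg$r_e, w)
  vm <- wvar(env$mu_e, w)
  S <- sqrt(vr / reg$sigma_r2)
  R <- if (vr == 0 || vm == 0) NA_real_ else
    wcov(env$mu_e, reg$r_e, w) / sqrt(vm * vr)
  list(R = R, S = S)
}

#' Average log-fitness of an unregulated promoter
#'
#' For a promoter with fixed mean `mu` and variance `sigma2`, the weighted
#' average over environments of the log of the Gaussian-gate fitness has the
#' closed form
#' \deqn{\log f = -\frac{(\mu - \langle\mu_e\rangle)^2 + \mathrm{var}(\mu_e)}
#'   {2(\tau^2+\sigma^2)} + \frac{1}{2}\log\frac{\tau^2}{\tau^2+\sigma^2}.}
#' It is maximized over `mu` at the mean desired level; maximized over
#' `sigma2` at 0 when `var(mu_e) < tau^2` and at `var(mu_e) - tau^2`
#' otherwise -- the bet-hedging optimum: when desired levels vary more than
#' the selection window is wide, fitness favours extra expression noise.
#'
#' @param mu Promoter mean log-expression.
#' @param sigma2 Promoter expression variance (>= 0).
#' @param env An [environment_ensemble()].
#' @return Average log-fitness (<= 0; 0 only for a perfectly matched,
#'   noise-free promoter in a constant environment).
#' @export
logfitness_unregulated <- function(mu, sigma2, env) {
  stopifnot(inherits(env, "environment_ensemble"), all(sigma2 >= 0))
  w <- env$weights
  t2 <- env$tau^2
  mbar <- wmean(env$mu_e, w)
  vm <- wvar(env$mu_e, w)
  -((mu - mbar)^2 + vm) / (2 * (t2 + sigma2)) + 0.5 * log(t2 / (t2 + sigma2))
}

#' Optimal unregulated noise level
#'
#' The bet-hedging optimum of [logfitness_unregulated()] over `sigma2`:
#' `max(0, var(mu_e) - tau^2)`.
#'
#' @param env An [environment_ensemble()].
#' @return Optimal expression variance.
#' @export
optimal_unregulated_noise <- function(env) {
  stopifnot(inherits(env, "environment_ensemble"))
  max(0, wvar(env$mu_e, env$weights) - env$tau^2)
}

#' Average log-fitness of a regulator-coupled promoter
#'
#' When the promoter's mean expression becomes `mu + c * r_e` in environment
#' `e` (linear coupling with gain `c`), regulator noise propagates into the
#' target and the total expression variance becomes
#' `sigma2 + c^2 * sigma_r2`. The weighted average log-fitness is
#' \deqn{\log f = -\frac{\langle(\mu + c r_e - \mu_e)^2\rangle}
#'   {2(\tau^2+\sigma^2+c^2\sigma_r^2)}
#'   + \frac{1}{2}\log\frac{\tau^2}{\tau^2+\sigma^2+c^2\sigma_r^2}.}
#'
#' @param mu Basal mean log-expression. Use `optimize_mu = TRUE` to set it to
#'   its optimum `<mu_e> - c <r_e>`.
#' @param sigma2 Basal expression variance (>= 0).
#' @param c Coupling constant (dimensionless linear gain; may be negative
#'   for repression).
#' @param env An [environment_ensemble()].
#' @param reg A [regulator_profile()].
#' @param optimize_mu Replace `mu` by the optimal basal mean? Default `FALSE`.
#' @return Average log-fitness.
#' @export
logfitness_coupled <- function(mu, sigma2, c, env, reg, optimize_mu = FALSE) {
  stopifnot(inherits(env, "environment_ensemble"),
            inherits(reg, "regulator_profile"),
            length(reg$r_e) == length(env$mu_e), sigma2 >= 0)
  w <- env$weights
  t2 <- env$tau^2
  if (optimize_mu) mu <- wmean(env$mu_e, w) - c * wmean(reg$r_e, w)
  s2tot <- sigma2 + c^2 * reg$sigma_r2
  dev2 <- wmean((mu + c * reg$r_e - env$mu_e)^2, w)
  -dev2 / (2 * (t2 + s2tot)) + 0.5 * log(t2 / (t2 + s2tot))
}

#' Log-fitness gain of a new regulatory interaction
#'
#' The closed-form change in average log-fitness from coupling a promoter
#' (with basal mean optimized) to a regulator, in terms of four dimensionless
#' parameters -- the renormalized coupling strength `X`, the expression
#' mismatch `Y`, the regulator's correlation with the desired levels `R` and
#' its signal-to-noise `S`:
#' \deqn{d\log f = \frac{1}{2}\,\frac{(X^2+R^2)Y^2 - (SX-RY)^2}{1+X^2}
#'   - \frac{1}{2}\log(1+X^2).}
#' `X` is non-negative by convention; a negative coupling constant
#' (repression) is absorbed into the sign of the effective correlation.
#'
#' @param X Coupling strength (>= 0; `X^2 = c^2 sigma_r2 / (sigma2 + tau^2)`).
#' @param Y Expression mismatch (>= 0).
#' @param R Correlation in `[-1, 1]`.
#' @param S Signal-to-noise (>= 0).
#' @return Change in log-fitness; 0 at `X = 0`.
#' @examples
#' dlogf(X = 1, Y = 4, R = 0.64, S = 2)
#' @export
dlogf <- function(X, Y, R, S) {
  stopifnot(all(X >= 0), all(abs(R) <= 1 + 1e-12))
  0.5 * ((X^2 + R^2) * Y^2 - (S * X - R * Y)^2) / (1 + X^2) -
    0.5 * log(1 + X^2)
}

#' Map a constructive coupling to the reduced parameters (X, Y, R, S)
#'
#' @param sigma2 Basal promoter variance.
#' @param c Coupling constant.
#' @param env An [environment_ensemble()].
#' @param reg A [regulator_profile()].
#' @return Named list `X`, `Y`, `R`, `S` with the sign of `c` absorbed into
#'   `R` (so `X >= 0`).
#' @export
coupling_state <- function(sigma2, c, env, reg) {
  rs <- regulator_RS(env, reg)
  denom <- sigma2 + env$tau^2
  list(X = sqrt(c^2 * reg$sigma_r2 / denom),
       Y = mismatch_Y(env, sigma2),
       R = sign(c) * rs$R,
       S = rs$S)
}

#' Optimal coupling strength
#'
#' With the regulator's signal-to-noise at its own optimum, the coupling
#' strength maximizing the log-fitness gain satisfies
#' `X*^2 = max(0, (1 - R^2) Y^2 - 1)`: coupling pays only when the part of
#' the expression mismatch not tracked by the regulator's condition response
#' exceeds 1 (the phase boundary).
#'
#' @param Y Expression mismatch.
#' @param R Correlation.
#' @return `X*` (>= 0).
#' @export
optimal_coupling <- function(Y, R) {
  sqrt(pmax(0, (1 - R^2) * Y^2 - 1))
}

#' Optimal regulator signal-to-noise
#'
#' At fixed coupling `X > 0`, the log-fitness gain is maximized over the
#' regulator's signal-to-noise at `S* = R Y / X`. An uncorrelated regulator
#' is optimally pure noise (`S* = 0`); `S*` diverges as `X` approaches 0 at
#' the phase boundary.
#'
#' @param R Correlation.
#' @param Y Expression mismatch.
#' @param X Coupling strength (> 0).
#' @return `S*`.
#' @export
optimal_signal_to_noise <- function(R, Y, X) {
  if (any(X <= 0)) stop("S* is undefined at X = 0 (it diverges at the phase boundary)")
  R * Y / X
}

#' Predicted total noise of an optimally regulated promoter
#'
#' With both coupling strength and regulator signal-to-noise optimized, the
#' promoter's total expression variance is its basal `sigma2` in the basal
#' noise regime `(1 - R^2) Y^2 <= 1`, and
#' `(1 - R^2) var(mu_e) - tau^2` in the environment-driven regime beyond the
#' phase boundary -- the amount of expression mismatch not accounted for by
#' the condition response. The two branches agree on the boundary.
#'
#' @param R Correlation between regulator activity and desired levels.
#' @param env An [environment_ensemble()].
#' @param sigma2 Basal promoter variance.
#' @return Total expression variance `sigma_tot^2`.
#' @export
predicted_total_noise <- function(R, env, sigma2) {
  stopifnot(inherits(env, "environment_ensemble"), sigma2 >= 0)
  vm <- wvar(env$mu_e, env$weights)
  Y2 <- vm / (sigma2 + env$tau^2)
  if ((1 - R^2) * Y2 <= 1) sigma2 else (1 - R^2) * vm - env$tau^2
}

#' Effective regulator for a linear combination of regulators
#'
#' Coupling a promoter to several regulators with gains `c_i` is equivalent
#' to coupling with a single gain `c` to an effective regulator with mean
#' activities `r_e = sum_i c_i r_e^i / c`. The effective noise variance
#' follows `sigma_r2 = sum_i c_i^2 sigma_i^2 + sum_{i != j} R_ij sigma_i
#' sigma_j` where `R_ij` is the correlation of the regulators' fluctuations;
#' `cross_weighted = TRUE` weights the cross term by `c_i c_j` as well (the
#' variance of the literal linear combination), divided by `c^2` to express
#' it as the effective regulator's own noise.
#'
#' @param regs List of [regulator_profile()]s over the same environments.
#' @param couplings Gains `c_i`, one per regulator.
#' @param cross_correlations Symmetric positive-semidefinite correlation
#'   matrix `R_ij` of the regulators' fluctuations (unit diagonal). Default
#'   identity (independent regulators).
#' @param c Effective coupling constant; default `sqrt(sum(c_i^2))`.
#' @param cross_weighted Use `c_i c_j`-weighted cross terms (and report the
#'   combination variance scaled by `1/c^2`)? Default `FALSE`.
#' @return List with the effective [regulator_profile()] (`profile`) and the
#'   effective coupling `c`.
#' @export
composite_regulator <- function(regs, couplings, cross_correlations = NULL,
                                c = NULL, cross_weighted = FALSE) {
  k <- length(regs)
  stopifnot(k >= 1L, length(couplings) == k,
            all(vapply(regs, inherits, logical(1), "regulator_profile")))
  n_e <- length(regs[[1]]$r_e)
  stopifnot(all(vapply(regs, function(r) length(r$r_e), integer(1)) == n_e))
  if (is.null(cross_correlations)) cross_correlations <- diag(k)
  Rij <- cross_correlations
  stopifnot(nrow(Rij) == k, ncol(Rij) == k)
  if (max(abs(Rij - t(Rij))) > 1e-10 || max(abs(diag(Rij) - 1)) > 1e-10)
    stop("cross_correlations must be symmetric with unit diagonal")
  if (min(eigen(Rij, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("cross_correlations must be positive semidefinite")
  if (is.null(c)) c <- sqrt(sum(couplings^2))
  stopifnot(c > 0)
  sig <- sqrt(vapply(regs, function(r) r$sigma_r2, numeric(1)))
  re_mat <- vapply(regs, function(r) r$r_e, numeric(n_e))
  r_eff <- drop(re_mat %*% couplings) / c
  off <- !diag(k)
  if (cross_weighted) {
    cw <- outer(couplings, couplings) * outer(sig, sig) * Rij
    s2 <- (sum(couplings^2 * sig^2) + sum(cw[off])) / c^2
  } else {
    s2 <- sum(couplings^2 * sig^2) + sum((outer(sig, sig) * Rij)[off])
  }
  list(profile = regulator_profile(r_eff, s2), c = c)
}

#' Iterate the regulation argument: residual mismatch after coupling
#'
#' Once a promoter is coupled to a regulator with gain `c`, the residual
#' deviations between desired and actual levels are
#' `mu_e_residual = mu_e - c * r_e` and the promoter's noise grows to
#' `sigma2 + c^2 sigma_r2`. The gain from a further regulatory interaction
#' follows the same closed forms with the mismatch recomputed on the
#' residuals.
#'
#' @param env An [environment_ensemble()].
#' @param reg A [regulator_profile()].
#' @param sigma2 Basal promoter variance.
#' @param c Coupling constant.
#' @return List with the residual [environment_ensemble()] (`env`, same tau
#'   and weights, desired levels replaced by residuals), `sigma2_new`, and
#'   the updated mismatch `Y_new`.
#' @export
iterate_regulation <- function(env, reg, sigma2, c) {
  stopifnot(inherits(env, "environment_ensemble"),
            inherits(reg, "regulator_profile"),
            length(reg$r_e) == length(env$mu_e))
  mu_res <- env$mu_e - c * reg$r_e
  s2_new <- sigma2 + c^2 * reg$sigma_r2
  env_new <- environment_ensemble(mu_res, env$tau, env$weights)
  list(env = env_new, sigma2_new = s2_new,
       Y_new = mismatch_Y(env_new, s2_new))
}
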