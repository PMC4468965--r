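#' Outlier-robust mean and variance of log-fluorescence
#'
#' Estimates the mean and variance of a promoter's per-cell log-fluorescence
#' sample while discounting a small fraction of gross outliers (debris,
#' doublets, acquisition artifacts). The default method models the sample as
#' a two-component mixture of a Gaussian signal and a broad uniform outlier
#' component spanning the data range, fitted by expectation-maximization;
#' points whose posterior probability of being outliers exceeds 1/2 are
#' discarded and plain moments are computed on the remainder. A simpler
#' trimmed estimator (symmetric tail trimming) is available as a fallback.
#'
#' @param log_values Numeric vector of per-cell log-fluorescence values
#'   (natural-log scale); at least 2 finite values.
#' @param outlier_fraction_prior Initial mixing weight of the outlier
#'   component (default 0.01); also the per-tail trim fraction (halved) for
#'   `method = "trim"`.
#' @param method `"em"` (default) or `"trim"`.
#' @param max_iter,tol EM iteration controls.
#' @return Named list with `mean_log`, `var_log`, `n_used` (points retained)
#'   and `n_total`.
#' @examples
#' x <- c(rnorm(1000, 8.1, 0.2), rnorm(5, 15, 0.1))
#' estimate_log_stats(x)
#' @export
estimate_log_stats <- function(log_values, outlier_fraction_prior = 0.01,
                               method = c("em", "trim"),
                               max_iter = 100, tol = 1e-8) {
  method <- match.arg(method)
  x <- log_values[is.finite(log_values)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite values to estimate mean and variance")
  if (stats::sd(x) == 0) {
    return(list(mean_log = x[1], var_log = 0, n_used = n, n_total = n))
  }
  if (method == "trim") {
    tr <- outlier_fraction_prior / 2
    qs <- stats::quantile(x, c(tr, 1 - tr), names = FALSE)
    keep <- x >= qs[1] & x <= qs[2]
    xk <- x[keep]
    # consistency correction: symmetric trimming of a Gaussian shrinks its
    # variance by 1 - 2 z phi(z) / (1 - 2 tr) with z the trim quantile
    z <- stats::qnorm(1 - tr)
    shrink <- 1 - 2 * z * stats::dnorm(z) / (1 - 2 * tr)
    return(list(mean_log = mean(xk), var_log = stats::var(xk) / shrink,
                n_used = length(xk), n_total = n))
  }
  # EM on Gaussian signal + uniform outlier component over the data range
  rng <- range(x)
  u_dens <- 1 / max(diff(rng), .Machine$double.eps)
  mu <- stats::median(x)
  sig <- stats::mad(x)
  if (sig == 0) sig <- stats::sd(x)
  pi_out <- min(max(outlier_fraction_prior, 1e-6), 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d_sig <- (1 - pi_out) * stats::dnorm(x, mu, sig)
    d_out <- pi_out * u_dens
    tot <- d_sig + d_out
    w <- d_sig / tot                       # responsibility of the signal
    mu <- sum(w * x) / sum(w)
    sig2 <- sum(w * (x - mu)^2) / sum(w)
    sig <- sqrt(max(sig2, .Machine$double.eps))
    pi_out <- min(max(mean(1 - w), 1e-9), 0.5)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  keep <- w >= 0.5
  if (sum(keep) < 2L) keep <- rep(TRUE, n)
  xk <- x[keep]
  list(mean_log = mean(xk), var_log = stats::var(xk),
       n_used = length(xk), n_total = n)
}

#' Summarize a set of flow samples into promoter records
#'
#' Applies [estimate_log_stats()] per promoter to a long-format table of
#' per-cell log-fluorescence values.
#'
#' @param samples Data frame with columns `promoter_id` and `log_value`.
#' @param ... Passed to [estimate_log_stats()].
#' @return Data frame with columns `promoter_id`, `mean_log`, `var_log`,
#'   `n_cells`.
#' @export
summarize_flow_samples <- function(samples, ...) {
  stopifnot(is.data.frame(samples),
            all(c("promoter_id", "log_value") %in% names(samples)))
  ids <- unique(samples$promoter_id)
  res <- lapply(ids, function(id) {
    est <- estimate_log_stats(samples$log_value[samples$promoter_id == id], ...)
    data.frame(promoter_id = id, mean_log = est$mean_log,
               var_log = est$var_log, n_cells = est$n_total)
  })
  do.call(rbind, res)
}
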