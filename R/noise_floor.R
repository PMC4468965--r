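#' Noise-floor parameters
#'
#' Container for the three parameters of the minimal-variance curve of
#' log-expression: in a simple constant-rate model of expression the protein
#' copy number is negative-binomially distributed with `var(n) = (b+1)<n>`;
#' cell-to-cell fluctuations of the transcription/translation/decay rates add
#' a term proportional to the squared mean, `var(n) = beta*<n> + sigma_ab2*<n>^2`,
#' where `beta` is a renormalized burst size and `sigma_ab2` the relative
#' variance of the product of the rates across cells. Together with a
#' background fluorescence `n_bg` these define the lower bound on the variance
#' of log-fluorescence as a function of mean fluorescence (see
#' [minimal_variance()]).
#'
#' @param sigma_ab2 Relative variance of the product of transcription,
#'   translation and decay rates across cells (dimensionless, >= 0). Sets the
#'   high-expression asymptote of the floor.
#' @param beta Renormalized burst size, in GFP-molecule units (>= 0).
#' @param n_bg Background fluorescence in GFP-molecule units (>= 0).
#' @return An object of class `noise_floor_params`.
#' @examples
#' noise_floor_params(0.025, 450, 100)
#' @export
noise_floor_params <- function(sigma_ab2, beta, n_bg = 0) {
  stopifnot(is.numeric(sigma_ab2), length(sigma_ab2) == 1L, sigma_ab2 >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(n_bg), length(n_bg) == 1L, n_bg >= 0)
  structure(list(sigma_ab2 = sigma_ab2, beta = beta, n_bg = n_bg),
            class = "noise_floor_params")
}

#' @export
print.noise_floor_params <- function(x, ...) {
  cat("Noise-floor parameters\n")
  cat(sprintf("  sigma_ab2 (extrinsic, asymptote): %.4g\n", x$sigma_ab2))
  cat(sprintf("  beta (renormalized burst size):   %.4g\n", x$beta))
  cat(sprintf("  n_bg (background fluorescence):   %.4g\n", x$n_bg))
  invisible(x)
}

#' Burst size of the unrenormalized simple model
#'
#' In the constant-rate model `var(n) = (b+1)<n>`; comparing with the
#' renormalized form `var(n) = beta*<n> + sigma_ab2*<n>^2` gives `b = beta - 1`
#' at `sigma_ab2 = 0`.
#'
#' @param params A [noise_floor_params()] object.
#' @return The simple-model burst size `b`.
#' @export
simple_burst_size <- function(params) {
  stopifnot(inherits(params, "noise_floor_params"))
  params$beta - 1
}

#' Minimal variance of log-expression as a function of mean expression
#'
#' Evaluates the theoretical lower bound on the variance of log-fluorescence
#' for a promoter with linear-scale mean measured fluorescence `mean_n`:
#' \deqn{\mathrm{var}(\log n_{meas}) = \sigma_{ab}^2 (1 - n_{bg}/\langle n_{meas}\rangle)^2
#'   + \frac{\beta}{\langle n_{meas}\rangle} (1 - n_{bg}/\langle n_{meas}\rangle).}
#' The curve decreases with mean expression and converges to `sigma_ab2` as
#' `mean_n` grows; near the background it vanishes.
#'
#' @param mean_n Linear-scale mean measured fluorescence (GFP-molecule units);
#'   must exceed `params$n_bg`. Vectorized.
#' @param params A [noise_floor_params()] object.
#' @return Minimal variance of log-fluorescence (dimensionless), same length
#'   as `mean_n`.
#' @examples
#' p <- noise_floor_params(0.025, 450, 100)
#' minimal_variance(c(500, 5000, 5e4), p)
#' @export
minimal_variance <- function(mean_n, params) {
  stopifnot(inherits(params, "noise_floor_params"), is.numeric(mean_n))
  if (any(!is.finite(mean_n) | mean_n <= params$n_bg)) {
    stop("mean_n must exceed the background fluorescence n_bg: ",
         "expression indistinguishable from background")
  }
  frac <- 1 - params$n_bg / mean_n
  params$sigma_ab2 * frac^2 + (params$beta / mean_n) * frac
}

#' Per-promoter excess noise above the fitted floor
#'
#' Excess noise is the difference between a promoter's measured variance of
#' log-fluorescence and the fitted minimal variance at its mean. Negative
#' values (promoters slightly below the fitted floor) are retained by default
#' since they carry information about the fit error; set `clip = TRUE` where a
#' downstream analysis requires non-negativity.
#'
#' @param records Data frame with columns `mean_log` and `var_log`
#'   (natural-log scale), e.g. the truth or estimated table from
#'   [gen_flow_populations()] or [estimate_log_stats()] output.
#' @param params A [noise_floor_params()] object (typically from
#'   [fit_noise_floor()]).
#' @param clip Clip negative excess values to zero? Default `FALSE`.
#' @return `records` with columns `floor_variance` and `excess_noise` added.
#' @export
excess_noise <- function(records, params, clip = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("mean_log", "var_log") %in% names(records)))
  fl <- minimal_variance(exp(records$mean_log), params)
  ex <- records$var_log - fl
  if (clip) ex <- pmax(ex, 0)
  records$floor_variance <- fl
  records$excess_noise <- ex
  records
}

#' Fit the noise floor to a population of promoters
#'
#' Estimates the minimal-variance curve from per-promoter summary statistics
#' by a lower-envelope fit: promoters are binned by `mean_log` into
#' equal-count bins, a low quantile of `var_log` is taken per bin, and the
#' closed-form floor is least-squares fitted to these envelope points. For a
#' fixed background `n_bg` the floor is linear in `(sigma_ab2, beta)`, so the
#' fit reduces to a (non-negativity-constrained) linear regression; when
#' `n_bg = NULL` the background is co-fitted by a 1-D search over `n_bg` of
#' the profiled residual sum of squares.
#'
#' @param records Data frame with columns `mean_log` and `var_log`.
#' @param n_bins Number of equal-count bins over `mean_log` (default 20).
#' @param quantile Envelope quantile of `var_log` per bin (default 0.05).
#' @param n_bg Background fluorescence: a fixed value (default 0), or `NULL`
#'   to co-fit it.
#' @return A [noise_floor_params()] object with attributes `envelope`
#'   (the fitted bin points) and `rss`.
#' @examples
#' set.seed(1)
#' ml <- runif(500, 6.5, 9.5)
#' truth <- noise_floor_params(0.025, 450, 0)
#' rec <- data.frame(mean_log = ml, var_log = minimal_variance(exp(ml), truth))
#' fit_noise_floor(rec)
#' @export
fit_noise_floor <- function(records, n_bins = 20, quantile = 0.05, n_bg = 0) {
  stopifnot(is.data.frame(records),
            all(c("mean_log", "var_log") %in% names(records)))
  ml <- records$mean_log
  vl <- records$var_log
  ok <- is.finite(ml) & is.finite(vl)
  ml <- ml[ok]; vl <- vl[ok]
  if (length(ml) < 20L)
    stop("need at least 20 promoters to fit the noise floor")
  # require ~a decade of dynamic range in mean expression (log10 units)
  if (diff(range(ml)) / log(10) < 0.8)
    stop("insufficient dynamic range: mean_log spans ",
         sprintf("%.2f", diff(range(ml)) / log(10)),
         " decades; need promoters spanning about a decade of mean expression")
  n_bins <- max(2L, min(n_bins, floor(length(ml) / 5)))
  brk <- stats::quantile(ml, probs = seq(0, 1, length.out = n_bins + 1L))
  brk <- unique(brk)
  bin <- cut(ml, breaks = brk, include.lowest = TRUE)
  # envelope point per bin: the record at the q-th percentile of var_log,
  # taken with its own mean so floor-exact data yield points on the curve
  env <- lapply(split(data.frame(ml, vl), bin), function(d) {
    if (nrow(d) == 0L) return(NULL)
    d[order(d$vl), ][max(1L, ceiling(quantile * nrow(d))), ]
  })
  env <- do.call(rbind, env)
  env_m <- env$ml; env_v <- env$vl
  mean_n <- exp(env_m)

  fit_at_bg <- function(bg) {
    if (bg >= min(mean_n)) return(list(rss = Inf))
    frac <- 1 - bg / mean_n
    X <- cbind(ext = frac^2, burst = frac / mean_n)
    co <- stats::coef(stats::lm.fit(X, env_v))
    # project onto the non-negative orthant: with 2 parameters the active-set
    # solution is one of {unconstrained, each axis, origin}
    cands <- list(co,
                  c(max(0, stats::coef(stats::lm.fit(X[, 1, drop = FALSE], env_v))), 0),
                  c(0, max(0, stats::coef(stats::lm.fit(X[, 2, drop = FALSE], env_v)))),
                  c(0, 0))
    cands <- Filter(function(z) all(z >= 0), cands)
    rss <- vapply(cands, function(z) sum((env_v - X %*% z)^2), numeric(1))
    best <- cands[[which.min(rss)]]
    list(coef = best, rss = min(rss))
  }

  if (is.null(n_bg)) {
    upper <- 0.9 * min(mean_n)
    opt <- stats::optimize(function(bg) fit_at_bg(bg)$rss,
                           interval = c(0, upper), tol = 1e-6 * upper)
    n_bg <- opt$minimum
  }
  sol <- fit_at_bg(n_bg)
  if (!is.finite(sol$rss)) stop("noise-floor fit failed: background exceeds data range")
  out <- noise_floor_params(unname(sol$coef[1]), unname(sol$coef[2]), n_bg)
  attr(out, "envelope") <- data.frame(mean_log = as.numeric(env_m),
                                      var_log = as.numeric(env_v))
  attr(out, "rss") <- sol$rss
  out
}
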