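#' Numerically maximize the log-fitness gain over coupling and signal-to-noise
#'
#' Joint numeric maximization of [dlogf()] over `(X, S)` at fixed `(Y, R)`,
#' by nested golden-section search: for each candidate `X` the gain is
#' maximized over `S` on `[0, S_max]`, and the profiled value is maximized
#' over `X` on `[0, X_max]`. Used to cross-check the closed-form optima
#' [optimal_coupling()] and [optimal_signal_to_noise()]; kept deliberately
#' free of the closed forms.
#'
#' @param Y Expression mismatch.
#' @param R Correlation.
#' @param X_max,S_max Search bounds (defaults generously above any optimum
#'   for `Y <= Y`-scale problems: `X_max = Y + 2`, `S_max = 10 * (Y + 1)`).
#' @param tol Search tolerance.
#' @return List with `X`, `S`, `value`.
#' @export
maximize_dlogf <- function(Y, R, X_max = Y + 2, S_max = 10 * (Y + 1),
                           tol = 1e-10) {
  profile_S <- function(X) {
    if (X == 0) return(list(S = NA_real_, value = dlogf(0, Y, R, 0)))
    # widen the search range near X -> 0 where the best S grows as 1/X
    hi <- max(S_max, 2 * abs(R) * Y / X + 1)
    o <- stats::optimize(function(S) dlogf(X, Y, R, S),
                         interval = c(0, hi), maximum = TRUE, tol = tol)
    list(S = o$maximum, value = o$objective)
  }
  oX <- stats::optimize(function(X) profile_S(X)$value,
                        interval = c(0, X_max), maximum = TRUE, tol = tol)
  # compare against the X = 0 boundary (optimize() never returns an endpoint)
  v0 <- dlogf(0, Y, R, 0)
  if (v0 >= oX$objective) return(list(X = 0, S = NA_real_, value = v0))
  pr <- profile_S(oX$maximum)
  list(X = oX$maximum, S = pr$S, value = oX$objective)
}

#' Landscape of achievable log-fitness gains over (R, S)
#'
#' For a promoter with expression mismatch `Y`, evaluates the maximal
#' log-fitness gain from optimally coupling (maximum of [dlogf()] over
#' `X >= 0` by 1-D numeric optimization) to a regulator with each
#' combination of correlation `R` and signal-to-noise `S` on the supplied
#' grids. Also returns the ridge curve of optimal signal-to-noise as a
#' function of `R`: `S*(R) = R Y / X*(R)` where the optimal coupling is
#' positive, along which condition response and noise propagation act
#' optimally in concert.
#'
#' @param Y Expression mismatch.
#' @param R_grid,S_grid Grid values.
#' @param X_max Upper bound of the coupling search (default `Y + 2`).
#' @return List with `landscape` (matrix, rows = `S_grid`, cols = `R_grid`),
#'   `optimal_X` (matrix of maximizing couplings) and `ridge` (data frame
#'   `R`, `S_star`, `NA` where the optimal coupling is 0).
#' @export
fitness_landscape <- function(Y, R_grid, S_grid, X_max = Y + 2) {
  stopifnot(length(R_grid) >= 1L, length(S_grid) >= 1L)
  val <- xopt <- matrix(NA_real_, length(S_grid), length(R_grid),
                        dimnames = list(S = signif(S_grid, 6),
                                        R = signif(R_grid, 6)))
  for (j in seq_along(R_grid)) {
    for (i in seq_along(S_grid)) {
      o <- stats::optimize(function(X) dlogf(X, Y, R_grid[j], S_grid[i]),
                           interval = c(0, X_max), maximum = TRUE, tol = 1e-9)
      if (dlogf(0, Y, R_grid[j], S_grid[i]) >= o$objective) {
        val[i, j] <- dlogf(0, Y, R_grid[j], S_grid[i]); xopt[i, j] <- 0
      } else {
        val[i, j] <- o$objective; xopt[i, j] <- o$maximum
      }
    }
  }
  xs <- optimal_coupling(Y, R_grid)
  ridge <- data.frame(R = R_grid,
                      S_star = ifelse(xs > 0, R_grid * Y / xs, NA_real_))
  list(landscape = val, optimal_X = xopt, ridge = ridge)
}

#' Phase diagram of optimal total noise over (Y, R)
#'
#' Tabulates [predicted_total_noise()] on a grid of expression mismatch `Y`
#' and regulator correlation `R`, for a promoter with basal variance
#' `sigma2` and fitness width `tau`. The phase boundary
#' `(1 - R^2) Y^2 = 1` separates the basal-noise regime (total noise stays
#' at `sigma2`) from the environment-driven regime where selection favours
#' extra noise matching the untracked mismatch.
#'
#' @param Y_grid,R_grid Grid values.
#' @param sigma2 Basal promoter variance.
#' @param tau Fitness-function width.
#' @return Matrix of `sigma_tot^2` (rows = `R_grid`, cols = `Y_grid`), with
#'   attribute `boundary_Y` giving the phase-boundary mismatch per `R`.
#' @export
phase_diagram <- function(Y_grid, R_grid, sigma2, tau) {
  out <- matrix(NA_real_, length(R_grid), length(Y_grid),
                dimnames = list(R = signif(R_grid, 6), Y = signif(Y_grid, 6)))
  for (i in seq_along(R_grid)) {
    for (j in seq_along(Y_grid)) {
      # realize var(mu_e) from Y at the given sigma2, tau
      vm <- Y_grid[j]^2 * (sigma2 + tau^2)
      env <- environment_ensemble(c(-1, 0, 1) * sqrt(vm * 3 / 2), tau)
      out[i, j] <- predicted_total_noise(R_grid[i], env, sigma2)
    }
  }
  attr(out, "boundary_Y") <- ifelse(abs(R_grid) < 1,
                                    1 / sqrt(1 - R_grid^2), Inf)
  out
}
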