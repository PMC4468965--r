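#' Binary regulatory incidence matrix
#'
#' Builds the promoters x regulators 0/1 matrix from an interaction list
#' (RegulonDB-export style): entry (p, r) is 1 iff regulator r is known to
#' target promoter p. Duplicate interaction rows are collapsed.
#'
#' @param interactions Data frame with columns `regulator_id` and
#'   `promoter_id`.
#' @param promoters Ordered promoter ids for the rows (default: sorted
#'   unique ids in the table). Promoters absent from the table get all-zero
#'   rows.
#' @param regulators Ordered regulator ids for the columns (default: sorted
#'   unique ids in the table).
#' @return Binary matrix with dimnames.
#' @export
regulatory_matrix <- function(interactions, promoters = NULL,
                              regulators = NULL) {
  stopifnot(is.data.frame(interactions),
            all(c("regulator_id", "promoter_id") %in% names(interactions)))
  ints <- unique(interactions[, c("regulator_id", "promoter_id")])
  if (is.null(promoters)) promoters <- sort(unique(ints$promoter_id))
  if (is.null(regulators)) regulators <- sort(unique(ints$regulator_id))
  stopifnot(!anyDuplicated(promoters), !anyDuplicated(regulators))
  M <- matrix(0, length(promoters), length(regulators),
              dimnames = list(promoters, regulators))
  keep <- ints$promoter_id %in% promoters & ints$regulator_id %in% regulators
  ints <- ints[keep, ]
  M[cbind(match(ints$promoter_id, promoters),
          match(ints$regulator_id, regulators))] <- 1
  M
}

# penalized least squares E ~ intercept + M V with ridge penalty lambda on V
# (intercept unpenalized); returns coefficients, fitted values, and the
# penalized-objective curvature for standard errors
ridge_solve <- function(E, M, lambda, se = FALSE) {
  n <- length(E)
  X <- cbind(`(intercept)` = 1, M)
  P <- diag(c(0, rep(lambda, ncol(M))))
  A <- crossprod(X) + P
  coefs <- solve(A, crossprod(X, E))
  fitted <- drop(X %*% coefs)
  out <- list(intercept = coefs[1], V = coefs[-1], fitted = fitted)
  if (se) {
    # plug-in residual variance from training residuals; V_se from the
    # curvature of the penalized objective: cov = s2 * A^-1 X'X A^-1
    df_eff <- sum(diag(solve(A, crossprod(X))))
    s2 <- sum((E - fitted)^2) / max(n - df_eff, 1)
    Ainv <- solve(A)
    covV <- s2 * Ainv %*% crossprod(X) %*% Ainv
    out$V_se <- sqrt(pmax(diag(covV)[-1], 0))
    out$s2 <- s2
  }
  out
}

#' Fit noise-propagation strengths by penalized regression
#'
#' Models each promoter's excess noise as the sum of noise-propagation
#' strengths of the regulators targeting it,
#' `E_p = intercept + sum_r R_pr V_r + noise`, with Gaussian noise of
#' unknown variance and a Gaussian (ridge) prior
#' `P(V_r) ~ exp(-lambda V_r^2 / 2)` on the strengths to avoid over-fitting.
#' The prior strength is chosen by repeated random-split cross-validation:
#' the `V_r` are fitted on a random fraction (default 80%) of promoters and
#' `lambda` maximizes the average fraction of held-out variance explained.
#' The model is then refit on all promoters at the selected `lambda`;
#' per-regulator uncertainties come from the curvature of the penalized
#' objective with a plug-in residual variance.
#'
#' @param E Excess noise per promoter, aligned with the rows of `M`.
#' @param M Binary incidence matrix from [regulatory_matrix()] (promoters x
#'   regulators).
#' @param lambda_grid Candidate prior strengths (>= 0).
#' @param holdout_fraction Fraction of promoters held out per split
#'   (default 0.2).
#' @param n_repeats Number of random splits averaged per lambda (default 50).
#' @param seed Integer seed for the splits.
#' @param nonneg Constrain fitted strengths to be non-negative? Default
#'   `FALSE` (noise propagation is physically non-negative but the model is
#'   unconstrained unless asked).
#' @return An object of class `propagation_fit`: list with `V`, `V_se`,
#'   `intercept`, `lambda`, `frac_var_explained` (on the full refit),
#'   `cv_curve` (data frame `lambda`, `heldout_R2`), `residual_var`.
#' @export
fit_propagation <- function(E, M, lambda_grid = 10^seq(-2, 3, length.out = 21),
                            holdout_fraction = 0.2, n_repeats = 50,
                            seed = 1L, nonneg = FALSE) {
  stopifnot(is.matrix(M), length(E) == nrow(M), all(M %in% c(0, 1)),
            length(lambda_grid) >= 1L, all(lambda_grid >= 0),
            holdout_fraction > 0, holdout_fraction < 1)
  if (all(M == 0)) stop("no interactions to attribute: incidence matrix is all zero")
  n <- length(E)
  if (stats::var(E) == 0) stop("degenerate response: excess noise has zero variance")
  set.seed(seed)
  n_hold <- max(1L, round(holdout_fraction * n))
  splits <- replicate(n_repeats, sample.int(n, n_hold), simplify = FALSE)

  heldout_R2 <- vapply(lambda_grid, function(lam) {
    mean(vapply(splits, function(hold) {
      tr <- setdiff(seq_len(n), hold)
      fit <- ridge_solve(E[tr], M[tr, , drop = FALSE], lam)
      pred <- fit$intercept + drop(M[hold, , drop = FALSE] %*% fit$V)
      1 - sum((E[hold] - pred)^2) / sum((E[hold] - mean(E[tr]))^2)
    }, numeric(1)))
  }, numeric(1))

  lam <- lambda_grid[which.max(heldout_R2)]
  full <- ridge_solve(E, M, lam, se = TRUE)
  if (nonneg && any(full$V < 0)) {
    # active-set: clamp negative strengths to zero and refit the rest
    act <- full$V > 0
    repeat {
      sub <- ridge_solve(E, M[, act, drop = FALSE], lam, se = TRUE)
      if (all(sub$V >= 0)) break
      act[act][sub$V < 0] <- FALSE
      if (!any(act)) { sub <- NULL; break }
    }
    V <- stats::setNames(numeric(ncol(M)), colnames(M))
    V_se <- V
    if (!is.null(sub)) { V[act] <- sub$V; V_se[act] <- sub$V_se }
    full$V <- V; full$V_se <- V_se
    full$fitted <- (if (is.null(sub)) mean(E) else sub$intercept) +
      drop(M %*% V)
    if (!is.null(sub)) full$intercept <- sub$intercept
  }
  r2 <- 1 - sum((E - full$fitted)^2) / sum((E - mean(E))^2)
  structure(list(V = stats::setNames(drop(full$V), colnames(M)),
                 V_se = stats::setNames(drop(full$V_se), colnames(M)),
                 intercept = unname(full$intercept),
                 lambda = lam,
                 frac_var_explained = r2,
                 cv_curve = data.frame(lambda = lambda_grid,
                                       heldout_R2 = heldout_R2),
                 residual_var = full$s2),
            class = "propagation_fit")
}

#' @export
print.propagation_fit <- function(x, ...) {
  cat("Noise-propagation fit\n")
  cat(sprintf("  regulators: %d   lambda: %.4g   variance explained: %.1f%%\n",
              length(x$V), x$lambda, 100 * x$frac_var_explained))
  top <- utils::head(rank_significant(x), 5)
  if (nrow(top)) {
    cat("  top regulators (V_r > se):\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Rank regulators by significance of their noise-propagation strength
#'
#' Filters to regulators whose fitted strength exceeds its uncertainty
#' (`V_r > sigma(V_r)`) and sorts them by decreasing significance
#' `V_r / sigma(V_r)`; ties break by regulator id for a stable order.
#'
#' @param fit A [fit_propagation()] result.
#' @return Data frame with columns `regulator`, `V`, `V_se`, `significance`.
#' @export
rank_significant <- function(fit) {
  stopifnot(inherits(fit, "propagation_fit"))
  sig <- ifelse(fit$V_se > 0, fit$V / fit$V_se, Inf * sign(fit$V))
  keep <- fit$V > fit$V_se
  out <- data.frame(regulator = names(fit$V)[keep],
                    V = unname(fit$V[keep]),
                    V_se = unname(fit$V_se[keep]),
                    significance = unname(sig[keep]))
  out[order(-out$significance, out$regulator), , drop = FALSE]
}
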