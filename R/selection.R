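#' FACS selection gate
#'
#' The probability that a cell with log-expression `x` survives a sort round
#' is well approximated by a Gaussian selection function centred on a target
#' level: `f(x | mu_star, tau) = exp(-(x - mu_star)^2 / (2 tau^2))`.
#'
#' @param mu_star Target log-expression (natural-log GFP-molecule units).
#' @param tau Selection width (log units, > 0).
#' @return An object of class `selection_gate`.
#' @examples
#' selection_gate(8.1, 0.03)
#' @export
selection_gate <- function(mu_star, tau) {
  stopifnot(is.numeric(mu_star), length(mu_star) == 1L,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(mu_star = mu_star, tau = tau), class = "selection_gate")
}

#' Per-cell selection probability
#'
#' @param x Log-expression value(s) of individual cells.
#' @param gate A [selection_gate()].
#' @return Probability in (0, 1] that each cell is selected; 1 exactly at
#'   `x = mu_star`.
#' @examples
#' selection_prob(8.2, selection_gate(8.1, 0.03))
#' @export
selection_prob <- function(x, gate) {
  stopifnot(inherits(gate, "selection_gate"))
  exp(-(x - gate$mu_star)^2 / (2 * gate$tau^2))
}

#' Fitness of a promoter genotype under a Gaussian selection gate
#'
#' A genotype whose expression is Gaussian with mean `mu` and variance
#' `sigma2` has fitness (expected fraction of its cells selected)
#' \deqn{f(\mu,\sigma \mid \mu_*, \tau) = \sqrt{\frac{\tau^2}{\tau^2+\sigma^2}}
#'   \exp\!\left[-\frac{(\mu-\mu_*)^2}{2(\tau^2+\sigma^2)}\right],}
#' the exact Gaussian integral of [selection_prob()] against the genotype's
#' expression distribution. Fitness falls off with distance of the mean from
#' the target; at the target it decreases only through the prefactor in
#' `sigma2`, which for `sigma >> tau` is a weak (square-root) dependence --
#' the sense in which mean-targeted sorting leaves expression noise largely
#' unselected.
#'
#' @param mu Mean log-expression (vectorized).
#' @param sigma2 Expression variance on the log scale (>= 0, vectorized).
#' @param gate A [selection_gate()].
#' @return Fitness in (0, 1].
#' @examples
#' genotype_fitness(8.1, 0.04, selection_gate(8.1, 0.03))
#' @export
genotype_fitness <- function(mu, sigma2, gate) {
  stopifnot(inherits(gate, "selection_gate"), all(sigma2 >= 0))
  t2 <- gate$tau^2
  sqrt(t2 / (t2 + sigma2)) * exp(-(mu - gate$mu_star)^2 / (2 * (t2 + sigma2)))
}

#' Mutation kernel for phenotype-level promoter evolution
#'
#' Mutagenesis is modelled at the phenotype level: with probability
#' `p_mutate` per lineage per round, the genotype's mean log-expression
#' receives a Gaussian perturbation of SD `rate_mu` and its log-variance a
#' Gaussian perturbation of SD `rate_sigma`. The default `p_mutate`
#' corresponds to the probability that a Poisson process with mean 2
#' effective mutation events per round hits a lineage at least once, so most
#' lineages carry between zero and a few mutations per round. The default
#' perturbation to the variance is substantially smaller than that to the
#' mean: promoter point mutations chiefly shift mean expression (mutant
#' libraries span the full expression range while single-genotype noise
#' stays near the floor), so per-mutation variance effects are minor.
#'
#' @param rate_mu SD of the per-round perturbation to `mu` (log units).
#' @param rate_sigma SD of the per-round perturbation to `log(sigma2)`.
#' @param p_mutate Probability a lineage mutates in a round.
#' @return An object of class `mutation_kernel`.
#' @export
mutation_kernel <- function(rate_mu = 0.2, rate_sigma = 0.05,
                            p_mutate = 1 - exp(-2)) {
  stopifnot(rate_mu >= 0, rate_sigma >= 0, p_mutate >= 0, p_mutate <= 1)
  structure(list(rate_mu = rate_mu, rate_sigma = rate_sigma,
                 p_mutate = p_mutate), class = "mutation_kernel")
}

#' Construct a phenotype-level promoter population
#'
#' @param mu Mean log-expression per genotype.
#' @param sigma2 Expression variance per genotype (>= 0).
#' @param counts Abundance per genotype (positive integers; default 1 each).
#' @return A data frame of class `promoter_population` with columns `mu`,
#'   `sigma2`, `count`.
#' @export
promoter_population <- function(mu, sigma2, counts = rep(1L, length(mu))) {
  stopifnot(length(mu) == length(sigma2), length(mu) == length(counts),
            all(sigma2 >= 0), all(counts >= 0), sum(counts) > 0)
  structure(data.frame(mu = mu, sigma2 = sigma2, count = as.numeric(counts)),
            class = c("promoter_population", "data.frame"))
}

#' Simulate rounds of FACS sort-and-mutate evolution
#'
#' Each round: (i) `cells_sampled` cells are drawn from the population, each
#' cell's log-expression sampled from its genotype's Gaussian expression
#' distribution; (ii) cells are selected either probabilistically (each
#' accepted with its [selection_prob()], the mechanism from which the
#' closed-form genotype fitness derives) or by rank (the `cells_selected`
#' cells nearest the gate centre); (iii) the next round's population is
#' founded by the selected cells (subsampled to at most `cells_selected`
#' lineages), so no genotype can appear that was absent before selection;
#' (iv) the mutation kernel perturbs a fraction of lineages. Per-round
#' summaries track the mean and spread of `mu`, mean `sigma2`, mean excess
#' noise relative to a supplied noise floor, and the realized selected
#' fraction.
#'
#' @param pop Initial [promoter_population()].
#' @param gates A single [selection_gate()] or a list of per-round gates
#'   (the gate centre may drift between rounds).
#' @param kernel A [mutation_kernel()].
#' @param cells_sampled Cells drawn per round (default 2e5).
#' @param cells_selected Maximum lineages carried to the next round
#'   (default 2e5, i.e. no cap beyond the accepted cells).
#' @param seed Integer seed; the trajectory is reproducible given the seed.
#' @param mode `"probabilistic"` (default) or `"rank"`.
#' @param floor_params Optional [noise_floor_params()]; when supplied, the
#'   summary reports mean excess noise `sigma2 - floor(exp(mu))` per round,
#'   and (with `track_floor = TRUE`) mutations that move the mean carry the
#'   genotype's excess noise with them while the floor component of the
#'   variance follows the new mean.
#' @param track_floor Re-anchor the variance to the floor at the mutated
#'   mean (default `TRUE` when `floor_params` is supplied)? Without
#'   tracking, `sigma2` is inherited in absolute terms across mean changes,
#'   which mislabels floor differences between the old and new mean as
#'   excess noise.
#' @return List with `summary` (one row per round 0..n: `round`, `mean_mu`,
#'   `var_mu`, `mean_abs_dev` = mean |mu - mu_star|, `mean_sigma2`,
#'   `mean_excess`, `selected_fraction`) and `population` (final
#'   [promoter_population()]), plus `populations` (full trajectory).
#' @export
evolve_population <- function(pop, gates, kernel = mutation_kernel(),
                              cells_sampled = 2e5, cells_selected = 2e5,
                              seed = 1L, mode = c("probabilistic", "rank"),
                              floor_params = NULL,
                              track_floor = !is.null(floor_params)) {
  mode <- match.arg(mode)
  if (track_floor && is.null(floor_params))
    stop("track_floor requires floor_params")
  stopifnot(inherits(pop, "promoter_population"),
            inherits(kernel, "mutation_kernel"),
            cells_selected <= cells_sampled)
  if (inherits(gates, "selection_gate")) gates <- list(gates)
  stopifnot(length(gates) >= 1L,
            all(vapply(gates, inherits, logical(1), "selection_gate")))
  set.seed(seed)

  summarize <- function(p, gate, frac) {
    w <- p$count / sum(p$count)
    ex <- if (!is.null(floor_params)) {
      p$sigma2 - minimal_variance(exp(p$mu), floor_params)
    } else rep(NA_real_, nrow(p))
    data.frame(mean_mu = sum(w * p$mu),
               var_mu = sum(w * (p$mu - sum(w * p$mu))^2),
               mean_abs_dev = sum(w * abs(p$mu - gate$mu_star)),
               mean_sigma2 = sum(w * p$sigma2),
               mean_excess = sum(w * ex),
               selected_fraction = frac)
  }

  traj <- list(pop)
  summ <- cbind(round = 0, summarize(pop, gates[[1]], NA_real_))

  for (r in seq_along(gates)) {
    gate <- gates[[r]]
    # sample cells from genotypes proportionally to abundance
    idx <- sample.int(nrow(pop), cells_sampled, replace = TRUE,
                      prob = pop$count)
    x <- stats::rnorm(cells_sampled, pop$mu[idx], sqrt(pop$sigma2[idx]))
    if (mode == "probabilistic") {
      acc <- stats::runif(cells_sampled) < selection_prob(x, gate)
      sel <- idx[acc]
      frac <- mean(acc)
    } else {
      ord <- order(abs(x - gate$mu_star))
      sel <- idx[ord[seq_len(min(cells_selected, cells_sampled))]]
      frac <- length(sel) / cells_sampled
    }
    if (length(sel) == 0L)
      stop("no cells accepted in round ", r,
           ": widen the gate (larger tau) or sample more cells")
    if (length(sel) > cells_selected)
      sel <- sel[sample.int(length(sel), cells_selected)]
    # founders of the next round: each selected cell is a lineage
    mu_new <- pop$mu[sel]
    s2_new <- pop$sigma2[sel]
    # mutation: the only source of genotype novelty
    hit <- stats::runif(length(sel)) < kernel$p_mutate
    n_hit <- sum(hit)
    if (n_hit > 0L) {
      mu_old <- mu_new[hit]
      mu_new[hit] <- mu_old + stats::rnorm(n_hit, 0, kernel$rate_mu)
      if (track_floor) {
        # the floor component of the variance is burst noise set by the
        # current mean, not an independently inherited trait: carry the
        # excess over and re-anchor to the floor at the mutated mean
        ex_old <- s2_new[hit] - minimal_variance(exp(mu_old), floor_params)
        base <- minimal_variance(exp(mu_new[hit]), floor_params) + ex_old
        s2_new[hit] <- pmax(base, 1e-12) *
          exp(stats::rnorm(n_hit, 0, kernel$rate_sigma))
      } else {
        s2_new[hit] <- exp(log(pmax(s2_new[hit], 1e-12)) +
                             stats::rnorm(n_hit, 0, kernel$rate_sigma))
      }
    }
    pop <- promoter_population(mu_new, s2_new)
    traj[[r + 1L]] <- pop
    summ <- rbind(summ, cbind(round = r, summarize(pop, gate, frac)))
  }
  rownames(summ) <- NULL
  list(summary = summ, population = pop, populations = traj)
}
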