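test_that("running means over cutoffs reduce correctly in edge cases", {
  excess <- c(0.01, 0.03, 0.08, 0.2)
  vals <- c(1, 2, 3, 4)
  rm <- running_mean_by_cutoff(excess, vals, cutoffs = c(-1, 0.05))
  # cutoff below the minimum reproduces the grand mean and its SE
  expect_equal(rm$mean[1], mean(vals))
  expect_equal(rm$se[1], sd(vals) / 2)
  expect_equal(rm$n[1], 4)
  expect_equal(rm$mean[2], 3.5)

  # identical covariate: constant mean, zero SE; n non-increasing
  rm2 <- running_mean_by_cutoff(excess, rep(7, 4))
  expect_true(all(rm2$mean == 7))
  expect_true(all(rm2$se[!is.na(rm2$se)] == 0))
  expect_true(all(diff(rm2$n) <= 0))

  # empty-selection cutoffs are omitted with a note
  expect_message(out <- running_mean_by_cutoff(excess, vals, cutoffs = c(0, 1)),
                 "omitted")
  expect_equal(nrow(out), 1)
})

test_that("a planted monotone association yields an increasing running mean", {
  set.seed(61)
  excess <- rexp(400, 1 / 0.05)
  vals <- 2 * excess + rnorm(400, 0, 0.02)
  rm <- running_mean_by_cutoff(excess, vals,
                               cutoffs = quantile(excess, seq(0, 0.9, 0.1)))
  expect_true(all(diff(rm$mean) > 0))
})

test_that("plasticity is the mean squared log fold-change", {
  tab <- data.frame(gene_id = rep(c("a", "b"), each = 2),
                    logfc = c(0, 0, 1, -1))
  pl <- plasticity_from_logfc(tab)
  expect_equal(pl$plasticity[pl$gene_id == "a"], 0)
  expect_equal(pl$plasticity[pl$gene_id == "b"], 1)

  # invariant to sign flips and condition order
  tab2 <- tab[c(4, 3, 2, 1), ]; tab2$logfc <- -tab2$logfc
  expect_equal(plasticity_from_logfc(tab2)$plasticity, pl$plasticity)

  # missing conditions excluded with count reported
  tab3 <- data.frame(gene_id = c("a", "a", "a"), logfc = c(1, NA, 3))
  pl3 <- plasticity_from_logfc(tab3)
  expect_equal(pl3$n_conditions, 2L)
  expect_equal(pl3$plasticity, 5)

  # Monte-Carlo: 240 Gaussian conditions with variance 0.5
  set.seed(62)
  x <- rnorm(240, 0, sqrt(0.5))
  pl4 <- plasticity_from_logfc(data.frame(gene_id = "g", logfc = x))
  se <- sqrt(2 * 0.5^2 / 240)  # SE of a chi-squared mean
  expect_lt(abs(pl4$plasticity - 0.5), 3 * se)
})

test_that("regulatory inputs are operon-averaged TF counts", {
  promoter_map <- data.frame(promoter_id = c("p1", "p2", "p3"),
                             gene_id = c("g1", "g2", "gX"))
  operon_map <- data.frame(operon_id = c("o1", "o2", "o2"),
                           gene_id = c("g1", "g2", "g3"))
  interactions <- data.frame(
    regulator_id = c("tfA", "tfB", "tfC", "tfA", "tfB", "tfC", "tfD", "tfA"),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g3", "g3", "g2"))

  expect_message(ann <- count_regulatory_inputs(promoter_map, operon_map,
                                                interactions),
                 "unmapped")
  # single-gene operon with 3 TFs
  expect_equal(ann$n_inputs[ann$promoter_id == "p1"], 3)
  # two-gene operon: g2 has 2 distinct TFs (duplicate tfA row collapsed),
  # g3 has 2, so the operon average is 2
  expect_equal(ann$n_inputs[ann$promoter_id == "p2"], 2)
  expect_false("p3" %in% ann$promoter_id)

  # duplicated interaction rows do not change counts
  ann2 <- suppressMessages(
    count_regulatory_inputs(promoter_map, operon_map,
                            rbind(interactions, interactions)))
  expect_equal(ann2$n_inputs, ann$n_inputs)

  # genes with no interactions count zero
  ints0 <- data.frame(regulator_id = "tfA", gene_id = "g9")
  ann0 <- suppressMessages(
    count_regulatory_inputs(promoter_map, operon_map, ints0))
  expect_true(all(ann0$n_inputs == 0))
})

test_that("threshold enrichment matches exact combinatorial enumeration", {
  # extremes
  a <- c(0.01, 0.02, 0.03); b <- c(0.1, 0.2)
  en <- threshold_enrichment(a, b, 0.05)
  expect_equal(en$fraction_a, 0)
  expect_equal(en$fraction_b, 1)
  # exact tail: choosing which of the 5 promoters are the 2 above-threshold
  p_exact <- choose(2, 2) * choose(3, 0) / choose(5, 2)
  expect_equal(en$p_value, p_exact)

  # identical groups give equal fractions and an unremarkable p
  en2 <- threshold_enrichment(a, a, 0.015)
  expect_equal(en2$fraction_a, en2$fraction_b)
  expect_gt(en2$p_value, 0.5)

  # threshold below all values
  en3 <- threshold_enrichment(a, b, 0)
  expect_equal(c(en3$fraction_a, en3$fraction_b), c(1, 1))

  # brute-force enumeration oracle on random small tables
  set.seed(63)
  for (i in 1:10) {
    na <- sample(3:15, 1); nb <- sample(3:15, 1)
    xa <- runif(na); xb <- runif(nb, 0.2, 1.2)
    th <- runif(1, 0.3, 0.9)
    en <- threshold_enrichment(xa, xb, th)
    K <- sum(c(xa, xb) > th); N <- na + nb; kb <- sum(xb > th)
    p_brute <- sum(vapply(kb:min(K, nb), function(k)
      choose(K, k) * choose(N - K, nb - k) / choose(N, nb), numeric(1)))
    expect_equal(en$p_value, p_brute, tolerance = 1e-12)
  }
})

test_that("cumulative distributions shift with their group and report the gap", {
  g <- list(low = c(0.01, 0.02, 0.05), high = c(0.01, 0.02, 0.05) + 0.1)
  cd <- cumulative_excess_distributions(g)
  # translation equivariance: the high group's CDF is the low one shifted
  low <- cd$cdf[cd$cdf$group == "low", ]
  high <- cd$cdf[cd$cdf$group == "high", ]
  expect_equal(approx(high$x, high$cdf, xout = low$x + 0.1,
                      method = "constant", rule = 2)$y,
               low$cdf)
  expect_equal(cd$max_gap$max_gap, 1)  # disjoint supports

  # single-value group is a unit step
  cd1 <- cumulative_excess_distributions(list(a = 0.3))
  expect_equal(cd1$cdf$cdf, 1)

  # planted group difference exceeds a permutation null band
  set.seed(64)
  x <- rexp(150, 1 / 0.03); y <- rexp(150, 1 / 0.08)
  gap_obs <- cumulative_excess_distributions(list(x = x, y = y))$max_gap$max_gap
  pool <- c(x, y)
  null_gaps <- replicate(200, {
    pi <- sample(300)
    cumulative_excess_distributions(list(a = pool[pi[1:150]],
                                         b = pool[pi[151:300]]))$max_gap$max_gap
  })
  expect_gt(gap_obs, quantile(null_gaps, 0.99))
})
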