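#' Running mean of a covariate over excess-noise cutoffs
#'
#' Sorts promoters by excess noise and, as a function of a cutoff, reports
#' the mean and standard error of a covariate (expression plasticity, number
#' of regulatory inputs, ...) over all promoters with excess noise strictly
#' above the cutoff.
#'
#' @param excess Excess noise per promoter.
#' @param values Covariate per promoter, aligned with `excess`.
#' @param cutoffs Cutoff grid; default is a cutoff below the minimum (the
#'   grand mean) followed by the sorted unique excess values. Cutoffs with
#'   no promoters above them are omitted (with a message).
#' @return Data frame with columns `cutoff`, `mean`, `se` (sample SD /
#'   sqrt(n); `NA` when n = 1) and `n`.
#' @export
running_mean_by_cutoff <- function(excess, values, cutoffs = NULL) {
  stopifnot(length(excess) == length(values), length(excess) >= 2L)
  ok <- is.finite(excess) & is.finite(values)
  excess <- excess[ok]; values <- values[ok]
  if (is.null(cutoffs)) cutoffs <- c(min(excess) - 1, sort(unique(excess)))
  rows <- lapply(cutoffs, function(ct) {
    sel <- values[excess > ct]
    n <- length(sel)
    if (n == 0L) return(NULL)
    data.frame(cutoff = ct, mean = mean(sel),
               se = if (n > 1L) stats::sd(sel) / sqrt(n) else NA_real_,
               n = n)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) message(dropped, " cutoff(s) with no promoters above them omitted")
  do.call(rbind, rows)
}

#' Expression plasticity from condition-wise log fold-changes
#'
#' A gene's expression plasticity across conditions is the mean of its
#' squared log fold-changes (nominally over 240 perturbation-vs-reference
#' experiments). Missing values are excluded from the mean, with the number
#' of conditions used reported.
#'
#' @param logfc Long-format data frame with columns `gene_id` and `logfc`
#'   (one row per gene x condition), or a genes x conditions numeric matrix
#'   with gene ids as row names.
#' @return Data frame with columns `gene_id`, `plasticity`, `n_conditions`.
#'   Genes with no finite values are excluded (with a message).
#' @export
plasticity_from_logfc <- function(logfc) {
  if (is.matrix(logfc)) {
    logfc <- data.frame(gene_id = rep(rownames(logfc), ncol(logfc)),
                        logfc = as.vector(logfc))
  }
  stopifnot(is.data.frame(logfc),
            all(c("gene_id", "logfc") %in% names(logfc)))
  logfc <- logfc[is.finite(logfc$logfc), ]
  if (nrow(logfc) == 0L) stop("no finite log fold-change values")
  sp <- split(logfc$logfc, logfc$gene_id)
  out <- data.frame(gene_id = names(sp),
                    plasticity = vapply(sp, function(x) mean(x^2), numeric(1)),
                    n_conditions = vapply(sp, length, integer(1)))
  rownames(out) <- NULL
  out
}

#' Operon-averaged regulatory input counts per promoter
#'
#' Counts, for each gene, the number of distinct transcription factors known
#' to regulate it, then assigns each promoter the average count over all
#' genes in the operon downstream of it.
#'
#' @param promoter_map Data frame `promoter_id`, `gene_id` mapping each
#'   promoter to its first downstream gene.
#' @param operon_map Data frame `operon_id`, `gene_id` giving operon
#'   membership.
#' @param interactions Data frame `regulator_id`, `gene_id` of known
#'   TF-to-gene regulatory interactions (duplicates collapsed).
#' @return Data frame `promoter_id`, `gene_id`, `n_genes` (operon size
#'   used), `n_inputs`. Promoters whose downstream gene is absent from the
#'   operon map are excluded with a message.
#' @export
count_regulatory_inputs <- function(promoter_map, operon_map, interactions) {
  stopifnot(all(c("promoter_id", "gene_id") %in% names(promoter_map)),
            all(c("operon_id", "gene_id") %in% names(operon_map)),
            all(c("regulator_id", "gene_id") %in% names(interactions)))
  ints <- unique(interactions[, c("regulator_id", "gene_id")])
  counts <- table(ints$gene_id)
  n_inputs_gene <- function(g) {
    v <- counts[g]
    ifelse(is.na(v), 0, as.numeric(v))
  }
  mapped <- promoter_map$gene_id %in% operon_map$gene_id
  if (any(!mapped))
    message(sum(!mapped), " promoter(s) with unmapped downstream gene excluded")
  pm <- promoter_map[mapped, ]
  operon_of <- stats::setNames(operon_map$operon_id, operon_map$gene_id)
  genes_in <- split(operon_map$gene_id, operon_map$operon_id)
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    genes <- genes_in[[as.character(operon_of[pm$gene_id[i]])]]
    data.frame(promoter_id = pm$promoter_id[i], gene_id = pm$gene_id[i],
               n_genes = length(genes),
               n_inputs = mean(n_inputs_gene(genes)))
  })
  do.call(rbind, rows)
}

#' Enrichment of high-excess-noise promoters between two groups
#'
#' Compares the fractions of two promoter groups whose excess noise exceeds
#' a threshold, and tests enrichment of above-threshold promoters in group B
#' by a one-sided hypergeometric test (group membership vs. threshold
#' exceedance).
#'
#' @param excess_a,excess_b Excess-noise values of groups A and B.
#' @param threshold Excess-noise threshold (the study's headline comparison
#'   uses 0.05).
#' @return Named list with `fraction_a`, `fraction_b`, `p_value` (one-sided,
#'   enrichment in group B) and the 2x2 `counts` matrix.
#' @export
threshold_enrichment <- function(excess_a, excess_b, threshold = 0.05) {
  stopifnot(length(excess_a) >= 1L, length(excess_b) >= 1L,
            is.finite(threshold))
  ka <- sum(excess_a > threshold)
  kb <- sum(excess_b > threshold)
  na <- length(excess_a); nb <- length(excess_b)
  # P(X >= kb) drawing nb from na+nb with ka+kb total above-threshold
  p <- stats::phyper(kb - 1, ka + kb, na + nb - ka - kb, nb,
                     lower.tail = FALSE)
  list(fraction_a = ka / na, fraction_b = kb / nb, p_value = p,
       counts = matrix(c(ka, na - ka, kb, nb - kb), 2, 2,
                       dimnames = list(c("above", "below"), c("A", "B"))))
}

#' Empirical cumulative distributions of excess noise per group
#'
#' Step-function CDFs of excess noise for labelled promoter groups on a
#' shared grid, plus the maximal CDF gap between each pair of groups as a
#' stochastic-dominance summary.
#'
#' @param groups Named list of numeric vectors of excess-noise values.
#' @return List with `cdf` (long data frame `group`, `x`, `cdf`) and
#'   `max_gap` (data frame `group_a`, `group_b`, `max_gap`).
#' @export
cumulative_excess_distributions <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)),
            all(vapply(groups, length, integer(1)) >= 1L))
  grid <- sort(unique(unlist(groups)))
  cdfs <- lapply(groups, function(g) stats::ecdf(g)(grid))
  cdf <- do.call(rbind, lapply(names(groups), function(nm) {
    data.frame(group = nm, x = grid, cdf = cdfs[[nm]])
  }))
  pairs <- if (length(groups) >= 2L) utils::combn(names(groups), 2) else
    matrix(character(0), 2, 0)
  max_gap <- if (ncol(pairs)) {
    data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
               max_gap = apply(pairs, 2, function(pr)
                 max(abs(cdfs[[pr[1]]] - cdfs[[pr[2]]]))))
  } else data.frame(group_a = character(0), group_b = character(0),
                    max_gap = numeric(0))
  list(cdf = cdf, max_gap = max_gap)
}
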