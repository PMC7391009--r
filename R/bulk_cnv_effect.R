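#' Per-gene copy-number alteration proportions
#'
#' For every gene and tumor type, the fraction of tumors with a thresholded
#' call below zero (loss) or above zero (gain); the reported proportion is
#' the unweighted mean of these fractions across tumor types.
#'
#' @param cohort a [bulk_cohort()].
#' @return A list with `by_type` (list of per-type data frames) and `mean`
#'   (data frame: gene, loss, gain averaged across types). Tumor types with
#'   zero tumors are excluded with a warning.
#' @export
cnv_alteration_proportions <- function(cohort) {
  types <- unique(cohort$tumor_type)
  by_type <- list()
  for (ty in types) {
    idx <- cohort$tumor_type == ty
    if (!any(idx)) {
      warning("tumor type with zero tumors excluded: ", ty)
      next
    }
    sub <- cohort$cnv[idx, , drop = FALSE]
    by_type[[ty]] <- data.frame(
      gene = colnames(sub),
      loss = colMeans(sub < 0),
      gain = colMeans(sub > 0),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  loss <- rowMeans(vapply(by_type, `[[`, numeric(ncol(cohort$cnv)), "loss"))
  gain <- rowMeans(vapply(by_type, `[[`, numeric(ncol(cohort$cnv)), "gain"))
  list(
    by_type = by_type,
    mean = data.frame(gene = colnames(cohort$cnv), loss = loss, gain = gain,
                      row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Effect of a gene's copy-number loss on a signature score
#'
#' Splits tumors into loss (thresholded call below zero) and stable (call
#' exactly zero) groups — tumors with gains are excluded from both — and
#' reports the mean signature score of the stable group minus the mean of
#' the loss group. A positive effect means the signature is lower when the
#' gene is lost.
#'
#' @param cohort a [bulk_cohort()].
#' @param gene gene whose copy-number status defines the groups.
#' @param signature_scores named numeric vector of per-tumor scores (e.g.
#'   the `scores` of a [module_score()] on the cohort expression).
#' @return A list with `gene`, `n_loss`, `n_stable`, `loss_effect` (`NA` and
#'   `defined = FALSE` when either group is empty).
#' @export
cnv_loss_effect <- function(cohort, gene, signature_scores) {
  calls <- cohort$cnv[, gene]
  scores <- signature_scores[rownames(cohort$cnv)]
  loss <- calls < 0
  stable <- calls == 0
  defined <- any(loss) && any(stable)
  list(
    gene = gene,
    n_loss = sum(loss),
    n_stable = sum(stable),
    loss_effect = if (defined)
      mean(scores[stable]) - mean(scores[loss]) else NA_real_,
    defined = defined
  )
}

#' Correlation between a gene's expression and a signature score
#'
#' Pearson correlation of a gene's expression with the signature score
#' across tumors; undefined (returned as `NA` with `defined = FALSE`) when
#' either vector is constant.
#'
#' @inheritParams cnv_loss_effect
#' @return A list with `gene`, `correlation` and `defined`.
#' @export
expression_signature_correlation <- function(cohort, gene, signature_scores) {
  expr <- cohort$expression[, gene]
  scores <- signature_scores[rownames(cohort$expression)]
  defined <- stats::sd(expr) > 0 && stats::sd(scores) > 0
  list(
    gene = gene,
    correlation = if (defined) stats::cor(expr, scores) else NA_real_,
    defined = defined
  )
}

#' Permutation significance of CNV-loss effects and correlations
#'
#' Computes, per gene, the CNV-loss effect and the expression-score
#' correlation, then permutes the tumor identifiers (decoupling the score
#' vector from the CNV/expression rows) `n_perm_cnv` times. The significance
#' threshold per statistic is the 95th percentile of the absolute permuted
#' values pooled across genes; a gene is flagged when its absolute observed
#' value exceeds the threshold. Shuffling is within tumor type by default.
#'
#' @param cohort a [bulk_cohort()].
#' @param genes genes to test.
#' @param signature_scores named per-tumor score vector.
#' @param cfg an [analysis_config()].
#' @param seed RNG seed.
#' @param within_type shuffle tumor identifiers within tumor type (default)
#'   or globally.
#' @param level quantile of the pooled absolute null used as threshold
#'   (default 0.95, a 5 percent false discovery rate).
#' @return A data frame per gene: `gene`, `n_loss`, `n_stable`,
#'   `loss_effect`, `expr_corr`, `sig_effect`, `sig_corr`, `significant`
#'   (either statistic), plus attributes `thresholds` and `seed`. With fewer
#'   than 20 permutations a coarse-threshold warning is raised.
#' @export
permutation_significance <- function(cohort, genes, signature_scores,
                                     cfg = analysis_config(), seed = cfg$seed,
                                     within_type = TRUE, level = 0.95) {
  if (cfg$n_perm_cnv < 20)
    warning("fewer than 20 permutations; significance threshold is coarse")
  observed <- lapply(genes, function(g) {
    eff <- cnv_loss_effect(cohort, g, signature_scores)
    corr <- expression_signature_correlation(cohort, g, signature_scores)
    data.frame(gene = g, n_loss = eff$n_loss, n_stable = eff$n_stable,
               loss_effect = eff$loss_effect, expr_corr = corr$correlation,
               stringsAsFactors = FALSE)
  })
  observed <- do.call(rbind, observed)
  tumors <- rownames(cohort$cnv)
  groups <- if (within_type) split(seq_along(tumors), cohort$tumor_type)
            else list(seq_along(tumors))
  null_eff <- matrix(NA_real_, cfg$n_perm_cnv, length(genes))
  null_cor <- matrix(NA_real_, cfg$n_perm_cnv, length(genes))
  with_seed(seed, {
    for (p in seq_len(cfg$n_perm_cnv)) {
      perm <- seq_along(tumors)
      for (gidx in groups) perm[gidx] <- gidx[sample.int(length(gidx))]
      shuffled <- stats::setNames(signature_scores[tumors][perm], tumors)
      for (j in seq_along(genes)) {
        null_eff[p, j] <- cnv_loss_effect(cohort, genes[j], shuffled)$loss_effect
        null_cor[p, j] <-
          expression_signature_correlation(cohort, genes[j], shuffled)$correlation
      }
    }
  })
  thr_eff <- stats::quantile(abs(null_eff), level, na.rm = TRUE, names = FALSE)
  thr_cor <- stats::quantile(abs(null_cor), level, na.rm = TRUE, names = FALSE)
  if (!is.finite(thr_eff)) thr_eff <- Inf
  if (!is.finite(thr_cor)) thr_cor <- Inf
  degenerate <- stats::sd(signature_scores) == 0
  if (degenerate)
    warning("zero-variance signature scores; no gene can be flagged")
  observed$sig_effect <- !degenerate & !is.na(observed$loss_effect) &
    abs(observed$loss_effect) > thr_eff
  observed$sig_corr <- !degenerate & !is.na(observed$expr_corr) &
    abs(observed$expr_corr) > thr_cor
  observed$significant <- observed$sig_effect | observed$sig_corr
  attr(observed, "thresholds") <- c(loss_effect = thr_eff, expr_corr = thr_cor)
  attr(observed, "seed") <- as.integer(seed)
  observed
}

#' Tumor-type-by-signature correlation with an anchor signature
#'
#' Scores the anchor signature and every comparison signature on the cohort
#' expression (shared binning), then reports, per tumor type, the Pearson
#' correlation between the anchor score and each signature's score across
#' that type's tumors. Types with fewer than three tumors are undefined.
#'
#' @param cohort a [bulk_cohort()].
#' @param anchor_sig a [gene_set()] (e.g. the TSK markers MMP10, PTHLH,
#'   LAMC2, SLITRK6).
#' @param other_sigs list of [gene_set()] objects.
#' @param cfg an [analysis_config()].
#' @param seed RNG seed for background sampling.
#' @return A tumor-type-by-signature matrix of correlations (`NA` where
#'   undefined).
#' @export
signature_correlation_matrix <- function(cohort, anchor_sig, other_sigs,
                                         cfg = analysis_config(),
                                         seed = cfg$seed) {
  sc <- score_signatures(t(cohort$expression), c(list(anchor_sig), other_sigs),
                         cfg, seed = seed)
  anchor <- sc$scores[, 1]
  others <- sc$scores[, -1, drop = FALSE]
  types <- sort(unique(cohort$tumor_type))
  out <- matrix(NA_real_, length(types), ncol(others),
                dimnames = list(types, colnames(others)))
  for (ty in types) {
    idx <- cohort$tumor_type == ty
    if (sum(idx) < 3) next
    for (j in seq_len(ncol(others))) {
      if (stats::sd(anchor[idx]) == 0 || stats::sd(others[idx, j]) == 0) next
      out[ty, j] <- stats::cor(anchor[idx], others[idx, j])
    }
  }
  out
}
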