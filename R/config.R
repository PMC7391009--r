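#' Analysis configuration
#'
#' Collects every tunable constant used across the package, with defaults set
#' to the values the implemented procedures assume: permutation counts,
#' expression thresholds for ligand-receptor reporting, single-cell QC cutoffs,
#' imaging normalization parameters, infiltration classification edges, module
#' score binning, screen sequencing depth, and co-essentiality FDR.
#'
#' @param n_perm_spatial permutations for the spot-adjacency test.
#' @param n_perm_lr permutations for ligand-receptor tests.
#' @param n_perm_screen permutations for the screen arm-difference FDR.
#' @param n_perm_cnv permutations for bulk CNV-effect significance.
#' @param lr_min_fraction minimum expressing-cell fraction (strictly exceeded)
#'   for a ligand or receptor to be considered in its cell type.
#' @param lr_expr_threshold mean log-expression cutoff (strictly exceeded) for
#'   reporting a significant ligand-receptor pair.
#' @param lr_p_threshold permutation p-value cutoff for significance.
#' @param qc_min_genes minimum detected genes per cell (kept when `>=`).
#' @param qc_max_mito maximum mitochondrial read fraction (removed when `>`).
#' @param arcsinh_cofactor cofactor for the imaging arcsinh transform.
#' @param dsdna_cutoff minimum post-normalization dsDNA value (kept when `>`).
#' @param percentile_lo,percentile_hi percentile anchors (0-100) for marker
#'   min-max scaling.
#' @param infiltration_k neighbors used to classify non-tumor cells.
#' @param infiltration_edges integer vector `(stromal_max, edge_lo, edge_hi,
#'   infiltrated_gt)`: 0 tumor neighbors is stromal, `[edge_lo, edge_hi]` is
#'   leading edge, more than `infiltrated_gt` is infiltrated.
#' @param score_bins number of equal-width average-expression bins for module
#'   score backgrounds.
#' @param score_background background genes sampled per signature gene.
#' @param depth_total target per-sample read total for depth normalization.
#' @param coessential_fdr FDR cutoff for seeds and edges of the
#'   co-essentiality network.
#' @param signature_hi,signature_lo mean-expression cutoffs defining a
#'   cell-type-specific gene (above `signature_hi` in the target type, below
#'   `signature_lo` in every other type).
#' @param min_coloc_cells minimum cells of each type per field of view for the
#'   co-localization test.
#' @param pseudocount added before log2 in screen fold-change computation.
#' @param seed default seed recorded with stochastic results.
#'
#' @return A list of class `nichestat_config`.
#' @export
analysis_config <- function(n_perm_spatial = 1000L,
                            n_perm_lr = 1000L,
                            n_perm_screen = 1000L,
                            n_perm_cnv = 100L,
                            lr_min_fraction = 0.10,
                            lr_expr_threshold = 0.2,
                            lr_p_threshold = 0.001,
                            qc_min_genes = 200L,
                            qc_max_mito = 0.10,
                            arcsinh_cofactor = 1,
                            dsdna_cutoff = 0.1,
                            percentile_lo = 10,
                            percentile_hi = 90,
                            infiltration_k = 30L,
                            infiltration_edges = c(0L, 5L, 13L, 19L),
                            score_bins = 20L,
                            score_background = 100L,
                            depth_total = 1e7,
                            coessential_fdr = 0.10,
                            signature_hi = 0.8,
                            signature_lo = 0.2,
                            min_coloc_cells = 10L,
                            pseudocount = 1,
                            seed = 1L) {
  cfg <- list(
    n_perm_spatial = as.integer(n_perm_spatial),
    n_perm_lr = as.integer(n_perm_lr),
    n_perm_screen = as.integer(n_perm_screen),
    n_perm_cnv = as.integer(n_perm_cnv),
    lr_min_fraction = lr_min_fraction,
    lr_expr_threshold = lr_expr_threshold,
    lr_p_threshold = lr_p_threshold,
    qc_min_genes = as.integer(qc_min_genes),
    qc_max_mito = qc_max_mito,
    arcsinh_cofactor = arcsinh_cofactor,
    dsdna_cutoff = dsdna_cutoff,
    percentile_lo = percentile_lo,
    percentile_hi = percentile_hi,
    infiltration_k = as.integer(infiltration_k),
    infiltration_edges = as.integer(infiltration_edges),
    score_bins = as.integer(score_bins),
    score_background = as.integer(score_background),
    depth_total = depth_total,
    coessential_fdr = coessential_fdr,
    signature_hi = signature_hi,
    signature_lo = signature_lo,
    min_coloc_cells = as.integer(min_coloc_cells),
    pseudocount = pseudocount,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_perm_spatial >= 1, cfg$n_perm_lr >= 1, cfg$n_perm_screen >= 1,
    cfg$n_perm_cnv >= 1,
    cfg$lr_min_fraction >= 0, cfg$lr_min_fraction <= 1,
    cfg$qc_max_mito >= 0, cfg$qc_max_mito <= 1,
    cfg$percentile_lo >= 0, cfg$percentile_hi <= 100,
    cfg$percentile_lo < cfg$percentile_hi,
    length(cfg$infiltration_edges) == 4L,
    cfg$score_bins >= 1, cfg$score_background >= 1,
    cfg$depth_total > 0, cfg$coessential_fdr > 0,
    cfg$min_coloc_cells >= 1, cfg$pseudocount >= 0
  )
  class(cfg) <- "nichestat_config"
  cfg
}

#' Permutation test result container
#'
#' Stores an observed statistic, its permutation null, and the empirical
#' p-value (or FDR) computed as the fraction of permuted statistics strictly
#' more extreme than the observed value, with the extremity direction given by
#' `tail`.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of permuted statistics.
#' @param tail one of `"greater"` (null strictly above observed is extreme),
#'   `"less"` (null at or below observed is extreme; used for distance-based
#'   co-localization where closer than random is the signal), or
#'   `"two_sided_abs"` (absolute null strictly above absolute observed).
#' @param seed seed used for the permutations.
#'
#' @return A list of class `permutation_result` with fields `observed`,
#'   `null_values`, `n_permutations`, `p_value`, `seed`, `tail`, and
#'   `degenerate` (TRUE when the null distribution is constant and equal to
#'   the observed statistic, in which case the strict-exceed p of 0 must not
#'   be read as significance).
#' @export
permutation_result <- function(observed, null_values, tail, seed = NA_integer_) {
  tail <- match.arg(tail, c("greater", "less", "two_sided_abs"))
  n <- length(null_values)
  stopifnot(n >= 1, is.finite(observed))
  extreme <- switch(tail,
    greater = sum(null_values > observed),
    less = sum(null_values <= observed),
    two_sided_abs = sum(abs(null_values) > abs(observed))
  )
  degenerate <- all(null_values == observed) && tail != "less"
  structure(
    list(
      observed = observed,
      null_values = null_values,
      n_permutations = n,
      p_value = extreme / n,
      seed = seed,
      tail = tail,
      degenerate = degenerate
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed=%.6g, p=%.4g (%s, %d permutations%s)\n",
    x$observed, x$p_value, x$tail, x$n_permutations,
    if (isTRUE(x$degenerate)) ", DEGENERATE null" else ""
  ))
  invisible(x)
}

# Run code under a fixed RNG seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
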