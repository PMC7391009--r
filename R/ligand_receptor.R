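#' Score ligand-receptor pairs across cell-type pairs
#'
#' For every ligand-receptor pair and every ordered (sender, receiver)
#' cell-type combination, the interaction score is the arithmetic mean of the
#' ligand's mean log-expression in the sender type and the receptor's mean
#' log-expression in the receiver type. Combinations where the ligand's (in
#' the sender) or receptor's (in the receiver) expressing-cell fraction does
#' not strictly exceed `lr_min_fraction` are excluded and recorded, as are
#' pairs whose genes are absent from the matrix.
#'
#' @param m log-normalized `ExpressionMatrix`.
#' @param annotations annotation data frame (`obs_id`, `cell_type`).
#' @param pairs data frame with columns `ligand` and `receptor`.
#' @param cfg an [analysis_config()].
#' @return A list with `scores` (data frame: ligand, receptor, sender,
#'   receiver, ligand_mean, receptor_mean, ligand_fraction,
#'   receptor_fraction, score) and `excluded` (same shape plus `reason`).
#'   Scored and excluded rows partition the pair-by-type-pair combinations.
#' @export
lr_pair_score <- function(m, annotations, pairs, cfg = analysis_config()) {
  prof <- celltype_mean_profile(m, annotations)
  types <- colnames(prof$means)
  missing_genes <- pairs[!(pairs$ligand %in% rownames(m)) |
                           !(pairs$receptor %in% rownames(m)), , drop = FALSE]
  pairs_ok <- pairs[pairs$ligand %in% rownames(m) &
                      pairs$receptor %in% rownames(m), , drop = FALSE]
  combos <- merge(pairs_ok,
                  expand.grid(sender = types, receiver = types,
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  if (nrow(combos) > 0) {
    combos$ligand_mean <- prof$means[cbind(combos$ligand, combos$sender)]
    combos$receptor_mean <- prof$means[cbind(combos$receptor, combos$receiver)]
    combos$ligand_fraction <- prof$fractions[cbind(combos$ligand, combos$sender)]
    combos$receptor_fraction <- prof$fractions[cbind(combos$receptor, combos$receiver)]
    combos$score <- (combos$ligand_mean + combos$receptor_mean) / 2
  }
  pass <- combos$ligand_fraction > cfg$lr_min_fraction &
    combos$receptor_fraction > cfg$lr_min_fraction
  excluded <- combos[!pass, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- "expressing fraction below minimum"
  if (nrow(missing_genes) > 0) {
    mg <- data.frame(missing_genes, sender = NA, receiver = NA,
                     ligand_mean = NA, receptor_mean = NA,
                     ligand_fraction = NA, receptor_fraction = NA, score = NA,
                     reason = "gene absent from matrix")
    excluded <- rbind(excluded, mg)
  }
  list(scores = combos[pass, , drop = FALSE], excluded = excluded)
}

#' Ligand-receptor permutation test on single cells
#'
#' Builds the null by shuffling cell-type identities over all aggregated
#' cells and recomputing each combination's interaction score; the p-value is
#' the fraction of permuted scores strictly exceeding the observed score. A
#' combination is called significant when `p < lr_p_threshold` and both the
#' ligand and receptor mean log-expression strictly exceed
#' `lr_expr_threshold`.
#'
#' @inheritParams lr_pair_score
#' @param seed RNG seed.
#' @param stratify_by optional annotation column (e.g. `sample_id`) within
#'   which labels are shuffled; default shuffles over all cells.
#' @return A list with `results` (scores table plus `p_value`, `significant`,
#'   `degenerate`), `excluded`, `n_permutations` and `seed`.
#' @export
lr_permutation_test <- function(m, annotations, pairs, cfg = analysis_config(),
                                seed = cfg$seed, stratify_by = NULL) {
  ann <- annotations[match(colnames(m), annotations$obs_id), , drop = FALSE]
  if (length(unique(ann$cell_type)) < 2)
    stop("at least 2 cell types are required")
  scored <- lr_pair_score(m, annotations, pairs, cfg)
  res <- scored$scores
  if (nrow(res) == 0)
    return(list(results = res, excluded = scored$excluded,
                n_permutations = cfg$n_perm_lr, seed = as.integer(seed)))
  vals <- unclass_matrix(m)
  genes_used <- unique(c(res$ligand, res$receptor))
  sub <- t(vals[genes_used, , drop = FALSE])   # cells x genes
  types <- sort(unique(ann$cell_type))
  strata <- if (is.null(stratify_by)) rep(1L, nrow(ann)) else ann[[stratify_by]]
  li <- cbind(match(res$ligand, genes_used), match(res$sender, types))
  ri <- cbind(match(res$receptor, genes_used), match(res$receiver, types))
  null_scores <- with_seed(seed, {
    vapply(seq_len(cfg$n_perm_lr), function(p) {
      labels <- ann$cell_type
      for (s in split(seq_along(labels), strata))
        labels[s] <- sample(labels[s])
      grp <- rowsum(sub, factor(labels, levels = types))
      n_by <- tabulate(factor(labels, levels = types), length(types))
      means <- grp / n_by                       # types x genes
      (means[cbind(li[, 2], li[, 1])] + means[cbind(ri[, 2], ri[, 1])]) / 2
    }, numeric(nrow(res)))
  })
  if (nrow(res) == 1) null_scores <- matrix(null_scores, nrow = 1)
  perm <- lapply(seq_len(nrow(res)), function(i) {
    permutation_result(res$score[i], null_scores[i, ], tail = "greater",
                       seed = seed)
  })
  res$p_value <- vapply(perm, `[[`, numeric(1), "p_value")
  res$degenerate <- vapply(perm, `[[`, logical(1), "degenerate")
  res$significant <- res$p_value < cfg$lr_p_threshold &
    res$ligand_mean > cfg$lr_expr_threshold &
    res$receptor_mean > cfg$lr_expr_threshold &
    !res$degenerate
  list(results = res, excluded = scored$excluded,
       n_permutations = cfg$n_perm_lr, seed = as.integer(seed))
}

#' Spatial proximity test for ligand-receptor pairs at the leading edge
#'
#' The observed statistic of a pair is the mean, over leading-edge spots, of
#' the mean ligand/receptor expression across the spot group (the edge spot
#' plus its graph neighbors). The null permutes the expression-to-spot
#' assignment within each replicate section, preserving each section's spot
#' count, while the edge spot positions stay fixed; the p-value is the
#' fraction of permutations whose statistic strictly exceeds the observed
#' one.
#'
#' @param spot_expr log-normalized `ExpressionMatrix` over spots.
#' @param lattice spot-lattice data frame covering the matrix spots.
#' @param edge_spot_ids identifiers of the annotated leading-edge spots.
#' @param graph a [build_spot_graph()] result (platform-appropriate k).
#' @param pairs data frame with columns `ligand` and `receptor`.
#' @param cfg an [analysis_config()].
#' @param seed RNG seed.
#' @return A data frame (ligand, receptor, observed, p_value, degenerate)
#'   with the per-pair [permutation_result()] objects as attribute
#'   `"permutations"`.
#' @export
lr_spatial_proximity_test <- function(spot_expr, lattice, edge_spot_ids,
                                      graph, pairs, cfg = analysis_config(),
                                      seed = cfg$seed) {
  if (length(edge_spot_ids) == 0) stop("empty leading-edge spot set")
  if (length(setdiff(edge_spot_ids, lattice$spot_id)) > 0)
    stop("edge spots not in the lattice")
  spots <- colnames(spot_expr)
  lattice <- lattice[match(spots, lattice$spot_id), , drop = FALSE]
  if (anyNA(lattice$spot_id)) stop("lattice does not cover all matrix spots")
  vals <- unclass_matrix(spot_expr)
  groups <- lapply(edge_spot_ids, function(s)
    match(c(s, intersect(graph$neighbors[[s]], spots)), spots))
  sections <- split(seq_along(spots), lattice$section_id)
  edge_stat <- function(v) {
    mean(vapply(groups, function(g) mean(v[g]), numeric(1)))
  }
  out <- pairs
  out$observed <- NA_real_
  out$p_value <- NA_real_
  out$degenerate <- NA
  perms <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$ligand[i]; r <- pairs$receptor[i]
    if (!(l %in% rownames(vals)) || !(r %in% rownames(vals))) next
    v <- (vals[l, ] + vals[r, ]) / 2
    observed <- edge_stat(v)
    null_vals <- with_seed(seed + i - 1L, {
      vapply(seq_len(cfg$n_perm_lr), function(p) {
        vp <- v
        for (s in sections) vp[s] <- v[sample(s)]
        edge_stat(vp)
      }, numeric(1))
    })
    pr <- permutation_result(observed, null_vals, tail = "greater",
                             seed = seed + i - 1L)
    perms[[i]] <- pr
    out$observed[i] <- observed
    out$p_value[i] <- pr$p_value
    out$degenerate[i] <- pr$degenerate
  }
  attr(out, "permutations") <- perms
  out
}
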