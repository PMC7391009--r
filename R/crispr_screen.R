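#' Depth-normalize screen counts
#'
#' Scales every sample column so it sums to `depth_total` reads (ten million
#' by default), preserving within-sample guide proportions exactly.
#'
#' @param screen a [screen_counts()] object.
#' @param cfg an [analysis_config()].
#' @return The guide-by-sample matrix of depth-normalized counts.
#' @export
depth_normalize <- function(screen, cfg = analysis_config()) {
  totals <- colSums(screen$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0)
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  sweep(screen$counts, 2, cfg$depth_total / totals, `*`)
}

#' Guide-level log2 fold-changes with non-targeting centering
#'
#' Log2-transforms the depth-normalized counts (with a pseudocount),
#' subtracts each guide's t0 value from its matched t1 value within every
#' replicate, then subtracts the replicate's median non-targeting value from
#' all gene-targeting guides. Non-targeting guides keep their uncentered
#' values and are flagged.
#'
#' @param normalized depth-normalized guide-by-sample matrix from
#'   [depth_normalize()].
#' @param screen the originating [screen_counts()] (for the guide map).
#' @param meta sample metadata data frame (sample_id, timepoint, arm,
#'   replicate, cell_line) with a matched t0 for every t1 sample within its
#'   cell line and replicate.
#' @param cfg an [analysis_config()] (`pseudocount`).
#' @return A list with `log2fc` (guide-by-replicate matrix of centered
#'   values), `arm` (named arm per replicate column), `guide_map`, and
#'   `nontargeting_median` (the per-replicate median subtracted).
#' @export
guide_log2fc <- function(normalized, screen, meta, cfg = analysis_config()) {
  gm <- screen$guide_map
  if (!any(gm$is_nontargeting)) stop("no non-targeting guides")
  lg <- log2(normalized + cfg$pseudocount)
  t1 <- meta[meta$timepoint == "t1", , drop = FALSE]
  cols <- character(0)
  arms <- character(0)
  fc <- NULL
  ntc_med <- numeric(0)
  for (i in seq_len(nrow(t1))) {
    match_t0 <- meta$timepoint == "t0" &
      meta$cell_line == t1$cell_line[i] &
      meta$arm == t1$arm[i] &
      meta$replicate == t1$replicate[i]
    if (sum(match_t0) == 0) {
      # fall back to a shared t0 within the cell line
      match_t0 <- meta$timepoint == "t0" & meta$cell_line == t1$cell_line[i]
    }
    if (sum(match_t0) == 0)
      stop("no matched t0 sample for ", t1$sample_id[i])
    t0_col <- meta$sample_id[which(match_t0)[1]]
    delta <- lg[, t1$sample_id[i]] - lg[, t0_col]
    med <- stats::median(delta[gm$is_nontargeting])
    delta[!gm$is_nontargeting] <- delta[!gm$is_nontargeting] - med
    rep_id <- sprintf("%s_%s", t1$arm[i], t1$replicate[i])
    fc <- cbind(fc, delta)
    cols <- c(cols, rep_id)
    arms <- c(arms, t1$arm[i])
    ntc_med <- c(ntc_med, med)
  }
  colnames(fc) <- cols
  names(arms) <- cols
  names(ntc_med) <- cols
  list(log2fc = fc, arm = arms, guide_map = gm, nontargeting_median = ntc_med)
}

#' Gene-level log2 fold-changes
#'
#' Unweighted mean over each gene's guides, per replicate. Non-targeting
#' guides are excluded.
#'
#' @param fc a [guide_log2fc()] result.
#' @return A gene-by-replicate matrix.
#' @export
gene_log2fc <- function(fc) {
  gm <- fc$guide_map
  keep <- !gm$is_nontargeting
  rs <- rowsum(fc$log2fc[keep, , drop = FALSE], gm$gene[keep])
  rs / as.vector(table(gm$gene[keep])[rownames(rs)])
}

#' Arm-difference permutation FDR
#'
#' For every gene, the observed statistic is the mean gene-level log2
#' fold-change across in-vivo replicates minus the mean across in-vitro
#' replicates. The null permutes the arm labels over the replicate values
#' `n_perm_screen` times; the FDR is the fraction of permutations whose
#' absolute difference strictly exceeds the absolute observed difference
#' (two-sided). A one-sided variant (null difference strictly below the
#' observed, for depletion) is reported alongside.
#'
#' @param gene_fc gene-by-replicate matrix from [gene_log2fc()].
#' @param arm named arm label per replicate column (from [guide_log2fc()]).
#' @param cfg an [analysis_config()].
#' @param seed RNG seed.
#' @return A data frame with columns `gene`, `observed_difference`, `fdr`
#'   (two-sided), `fdr_less` (one-sided, depletion in vivo), and `degenerate`
#'   (all permuted differences equal to the observed one).
#' @export
arm_difference_fdr <- function(gene_fc, arm, cfg = analysis_config(),
                               seed = cfg$seed) {
  arm <- arm[colnames(gene_fc)]
  if (length(unique(arm)) < 2)
    stop("both screen arms are required")
  is_vivo <- arm == "in_vivo"
  observed <- rowMeans(gene_fc[, is_vivo, drop = FALSE]) -
    rowMeans(gene_fc[, !is_vivo, drop = FALSE])
  n_rep <- ncol(gene_fc)
  n_vivo <- sum(is_vivo)
  null_diff <- with_seed(seed, {
    vapply(seq_len(cfg$n_perm_screen), function(p) {
      sel <- sample.int(n_rep, n_vivo)
      rowMeans(gene_fc[, sel, drop = FALSE]) -
        rowMeans(gene_fc[, -sel, drop = FALSE])
    }, numeric(nrow(gene_fc)))
  })
  if (nrow(gene_fc) == 1) null_diff <- matrix(null_diff, nrow = 1)
  fdr <- rowMeans(abs(null_diff) > abs(observed))
  fdr_less <- rowMeans(null_diff < observed)
  degenerate <- apply(null_diff == observed, 1, all)
  data.frame(
    gene = rownames(gene_fc),
    observed_difference = unname(observed),
    fdr = unname(fdr), fdr_less = unname(fdr_less),
    degenerate = unname(degenerate),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Build a co-essentiality network around screen hits
#'
#' Seeds are screen hits depleted at an FDR below `coessential_fdr`; the edge
#' universe is the non-syntenic co-essential pairs below the same FDR;
#' connectors are non-seed genes co-essential with at least two seeds. The
#' network contains seeds and connectors with all qualifying edges among
#' them. When synteny flags are absent all pairs are treated as non-syntenic,
#' with a warning.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `fdr` and
#'   optionally `syntenic` (logical).
#' @param screen_hits named numeric vector of per-gene screen FDRs.
#' @param cfg an [analysis_config()].
#' @return A list of class `CoessentialNetwork` with `nodes` (data frame:
#'   gene, role in seed/connector) and `edges` (qualifying edges whose both
#'   ends are in the network). An empty seed set yields an empty network.
#' @export
build_coessential_network <- function(edges, screen_hits,
                                      cfg = analysis_config()) {
  if (is.null(edges$syntenic)) {
    warning("no synteny flags; treating all pairs as non-syntenic")
    edges$syntenic <- FALSE
  }
  universe <- edges[edges$fdr < cfg$coessential_fdr & !edges$syntenic, ,
                    drop = FALSE]
  seeds <- names(screen_hits)[screen_hits < cfg$coessential_fdr]
  if (length(seeds) == 0)
    return(structure(list(nodes = data.frame(gene = character(0),
                                             role = character(0)),
                          edges = universe[0, , drop = FALSE]),
                     class = "CoessentialNetwork"))
  seed_touch <- rbind(
    data.frame(gene = universe$gene_a, seed = universe$gene_b),
    data.frame(gene = universe$gene_b, seed = universe$gene_a)
  )
  seed_touch <- seed_touch[seed_touch$seed %in% seeds &
                             !(seed_touch$gene %in% seeds), , drop = FALSE]
  n_seed_neighbors <- table(seed_touch$gene[!duplicated(seed_touch)])
  connectors <- names(n_seed_neighbors)[n_seed_neighbors >= 2]
  members <- c(seeds, connectors)
  net_edges <- universe[universe$gene_a %in% members &
                          universe$gene_b %in% members, , drop = FALSE]
  structure(
    list(
      nodes = data.frame(
        gene = members,
        role = c(rep("seed", length(seeds)),
                 rep("connector", length(connectors))),
        stringsAsFactors = FALSE
      ),
      edges = net_edges
    ),
    class = "CoessentialNetwork"
  )
}
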