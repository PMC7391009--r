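#' Normalize segmented-cell marker counts
#'
#' Applies the post-segmentation normalization pipeline, in order: (1) divide
#' raw marker counts by cell size, (2) arcsinh transform with the configured
#' cofactor, (3) divide every marker by the field-of-view's median dsDNA
#' value, (4) drop cells whose normalized dsDNA does not strictly exceed
#' `dsdna_cutoff`, and (5) per marker, clip values at the configured
#' percentiles across retained cells and min-max rescale to [0, 1].
#' Percentile anchors are computed across the whole dataset by default; set
#' `per_fov_scaling` for per-field anchors.
#'
#' @param cells segmented-cell data frame with `raw_<marker>` columns.
#' @param dsdna_marker name of the dsDNA channel (without the `raw_` prefix).
#' @param cfg an [analysis_config()].
#' @param per_fov_scaling compute percentile anchors within each field of
#'   view instead of across the dataset.
#' @return A list with `cells` (retained cells with added `norm_<marker>`
#'   columns in [0,1]) and `dropped` (cells removed by the dsDNA cutoff);
#'   fields of view with zero median dsDNA are excluded and listed in
#'   `failed_fovs`.
#' @export
normalize_markers <- function(cells, dsdna_marker = "dsDNA",
                              cfg = analysis_config(),
                              per_fov_scaling = FALSE) {
  raw_cols <- marker_columns(cells, "raw_")
  markers <- sub("^raw_", "", raw_cols)
  if (!dsdna_marker %in% markers)
    stop("dsDNA marker column missing: raw_", dsdna_marker)
  vals <- as.matrix(cells[, raw_cols, drop = FALSE])
  colnames(vals) <- markers
  vals <- vals / cells$size
  vals <- asinh(vals / cfg$arcsinh_cofactor)
  failed_fovs <- character(0)
  for (f in unique(cells$fov_id)) {
    idx <- cells$fov_id == f
    med <- stats::median(vals[idx, dsdna_marker])
    if (med == 0) {
      failed_fovs <- c(failed_fovs, f)
      next
    }
    vals[idx, ] <- vals[idx, ] / med
  }
  in_failed <- cells$fov_id %in% failed_fovs
  if (length(failed_fovs) > 0)
    warning("FOV(s) with zero median dsDNA excluded: ",
            paste(failed_fovs, collapse = ", "))
  keep <- !in_failed & vals[, dsdna_marker] > cfg$dsdna_cutoff
  dropped <- cells[!keep & !in_failed, , drop = FALSE]
  cells_kept <- cells[keep, , drop = FALSE]
  vals_kept <- vals[keep, , drop = FALSE]
  scale_block <- function(block) {
    apply(block, 2, function(v) {
      lo <- stats::quantile(v, cfg$percentile_lo / 100, names = FALSE)
      hi <- stats::quantile(v, cfg$percentile_hi / 100, names = FALSE)
      if (hi == lo) return(rep(0, length(v)))
      pmin(pmax((v - lo) / (hi - lo), 0), 1)
    })
  }
  if (nrow(vals_kept) > 0) {
    if (per_fov_scaling) {
      for (f in unique(cells_kept$fov_id)) {
        idx <- cells_kept$fov_id == f
        vals_kept[idx, ] <- scale_block(vals_kept[idx, , drop = FALSE])
      }
    } else {
      vals_kept <- scale_block(vals_kept)
    }
  }
  for (mk in markers) cells_kept[[paste0("norm_", mk)]] <- vals_kept[, mk]
  list(cells = cells_kept, dropped = dropped, failed_fovs = failed_fovs)
}

#' Cell-type co-localization test within a field of view
#'
#' For each type-A cell the mean distance to all type-B cells is computed;
#' the observed statistic is the median of these per-cell means. The null
#' replaces the type-B set with an equally sized random subset of non-tumor
#' cells that are neither type A nor type B, sampled without replacement
#' within each draw. The FDR is the fraction of draws whose null median is at
#' or below the observed median (closer than random signals co-localization).
#'
#' @param cells segmented-cell data frame (all fields of view).
#' @param type_a,type_b the two cell types.
#' @param cfg an [analysis_config()]; `n_perm_spatial` random draws are used
#'   and fields with fewer than `min_coloc_cells` of either type are skipped.
#' @param seed RNG seed.
#' @return A list over fields of view; each entry has `fov_id`,
#'   `per_cell_mean_distances`, `observed_median`, and `permutation` (a
#'   [permutation_result()] with `tail = "less"`), or a `skipped` record with
#'   the reason.
#' @export
colocalization_test <- function(cells, type_a, type_b,
                                cfg = analysis_config(), seed = cfg$seed) {
  out <- list()
  for (f in unique(cells$fov_id)) {
    fc <- cells[cells$fov_id == f, , drop = FALSE]
    ia <- which(fc$cell_type == type_a)
    ib <- which(fc$cell_type == type_b)
    pool <- which(!fc$is_tumor & !(fc$cell_type %in% c(type_a, type_b)))
    if (length(ia) < cfg$min_coloc_cells || length(ib) < cfg$min_coloc_cells) {
      out[[f]] <- list(fov_id = f, skipped = "insufficient cells of the tested types")
      next
    }
    if (length(pool) < length(ib)) {
      out[[f]] <- list(fov_id = f, skipped = "insufficient eligible cells for null draws")
      next
    }
    # distances from each A cell to every B cell and to every pool cell
    dxa <- outer(fc$x[ia], fc$x[c(ib, pool)], `-`)
    dya <- outer(fc$y[ia], fc$y[c(ib, pool)], `-`)
    dmat <- sqrt(dxa^2 + dya^2)
    d_ab <- dmat[, seq_along(ib), drop = FALSE]
    d_pool <- dmat[, length(ib) + seq_along(pool), drop = FALSE]
    per_cell <- rowMeans(d_ab)
    observed <- stats::median(per_cell)
    nb <- length(ib)
    null_medians <- with_seed(seed, {
      vapply(seq_len(cfg$n_perm_spatial), function(p) {
        sel <- sample.int(length(pool), nb)
        stats::median(rowMeans(d_pool[, sel, drop = FALSE]))
      }, numeric(1))
    })
    out[[f]] <- list(
      fov_id = f, type_a = type_a, type_b = type_b,
      per_cell_mean_distances = per_cell,
      observed_median = observed,
      permutation = permutation_result(observed, null_medians, tail = "less",
                                       seed = seed)
    )
  }
  out
}

#' Classify non-tumor cells into tumor compartments
#'
#' Counts tumor cells among each non-tumor cell's `infiltration_k` nearest
#' neighbors (all cell types eligible as neighbors, ties broken by cell id)
#' and assigns: zero tumor neighbors is `stromal`, a count within the
#' leading-edge band (inclusive) is `leading_edge`, a count strictly above
#' the infiltrated threshold is `infiltrated`, and anything else —
#' the gaps the printed rule leaves — is `unassigned`.
#'
#' @param cells segmented-cell data frame with `is_tumor` flags.
#' @param cfg an [analysis_config()] (`infiltration_k`, `infiltration_edges`).
#' @return A list with `labels` (data frame: cell_id, fov_id, compartment,
#'   tumor_neighbor_count, one row per non-tumor cell) and `skipped_fovs`
#'   (fields with fewer than `infiltration_k + 1` cells).
#' @export
classify_infiltration <- function(cells, cfg = analysis_config()) {
  edges <- cfg$infiltration_edges
  labels <- list()
  skipped <- character(0)
  for (f in unique(cells$fov_id)) {
    fc <- cells[cells$fov_id == f, , drop = FALSE]
    if (nrow(fc) < cfg$infiltration_k + 1L) {
      skipped <- c(skipped, f)
      next
    }
    d <- as.matrix(stats::dist(cbind(fc$x, fc$y)))
    nontumor <- which(!fc$is_tumor)
    cnt <- vapply(nontumor, function(i) {
      ord <- order(d[i, -i], fc$cell_id[-i])[seq_len(cfg$infiltration_k)]
      sum(fc$is_tumor[-i][ord])
    }, integer(1))
    compartment <- ifelse(
      cnt == edges[1], "stromal",
      ifelse(cnt >= edges[2] & cnt <= edges[3], "leading_edge",
             ifelse(cnt > edges[4], "infiltrated", "unassigned"))
    )
    labels[[f]] <- data.frame(
      cell_id = fc$cell_id[nontumor], fov_id = f,
      compartment = compartment, tumor_neighbor_count = cnt,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0)
    warning("FOV(s) skipped (fewer than ", cfg$infiltration_k + 1L,
            " cells): ", paste(skipped, collapse = ", "))
  list(labels = do.call(rbind, c(labels, list(make.row.names = FALSE))),
       skipped_fovs = skipped)
}

#' Compartment composition by cell type
#'
#' Proportion of the non-tumor cells in each compartment contributed by each
#' cell type. Unassigned cells are reported as their own row but excluded
#' from the three named compartments' denominators.
#'
#' @param labels the `labels` data frame from [classify_infiltration()].
#' @param cells the segmented-cell data frame the labels were computed from.
#' @return A list with `proportions` (compartment-by-cell-type matrix; each
#'   populated row sums to 1), `counts` (same shape, cell counts) and
#'   `empty_compartments` (names of compartments with no cells, whose rows
#'   are zero).
#' @export
compartment_composition <- function(labels, cells) {
  key <- paste(cells$fov_id, cells$cell_id)
  ct <- cells$cell_type[match(paste(labels$fov_id, labels$cell_id), key)]
  compartments <- c("stromal", "leading_edge", "infiltrated", "unassigned")
  types <- sort(unique(ct))
  counts <- matrix(0L, length(compartments), length(types),
                   dimnames = list(compartments, types))
  tab <- table(factor(labels$compartment, levels = compartments), ct)
  counts[, colnames(tab)] <- tab
  totals <- rowSums(counts)
  proportions <- counts / ifelse(totals > 0, totals, 1)
  list(proportions = proportions, counts = counts,
       empty_compartments = compartments[totals == 0])
}
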