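#' Generate a spatial-transcriptomics spot lattice
#'
#' Builds the spot geometry of the two supported platforms. `"ST"` produces a
#' square grid (default pitch 150 micrometres) in which every interior spot
#' has exactly four nearest neighbors at exactly the pitch distance. `"Visium"`
#' produces a hexagonal (triangular) lattice (default pitch 100 micrometres)
#' in which every interior spot has six equidistant nearest neighbors. A
#' centered-rectangular mode adds the rectangle-center spots of a rectangular
#' grid with user-set pitches.
#'
#' @param platform `"ST"` or `"Visium"`.
#' @param extent_x_mm,extent_y_mm capture-area extent in millimetres.
#' @param pitch_um center-to-center spot distance in micrometres; defaults to
#'   150 for ST and 100 for Visium.
#' @param section_id,replicate_id identifiers stamped on every spot.
#' @param centered for ST only: also place spots at the centers of the grid
#'   rectangles (centered-rectangular lattice).
#' @param pitch_y_um vertical pitch for the centered-rectangular mode
#'   (defaults to `pitch_um`).
#' @return A spot-lattice data frame (spot_id, x, y, section_id,
#'   replicate_id, cluster, platform) with coordinates in micrometres.
#' @export
generate_st_lattice <- function(platform = c("ST", "Visium"),
                                extent_x_mm = 6.3, extent_y_mm = 6.7,
                                pitch_um = NULL,
                                section_id = "S1", replicate_id = "R1",
                                centered = FALSE, pitch_y_um = NULL) {
  platform <- match.arg(platform)
  stopifnot(extent_x_mm > 0, extent_y_mm > 0)
  if (is.null(pitch_um)) pitch_um <- if (platform == "ST") 150 else 100
  stopifnot(pitch_um > 0)
  ex <- extent_x_mm * 1000
  ey <- extent_y_mm * 1000
  if (ex < pitch_um || ey < pitch_um)
    warning("extent smaller than one pitch; single-spot lattice")
  if (platform == "ST") {
    xs <- seq(0, ex, by = pitch_um)
    ys <- seq(0, ey, by = pitch_um)
    grid <- expand.grid(x = xs, y = ys)
    if (centered) {
      py <- if (is.null(pitch_y_um)) pitch_um else pitch_y_um
      cx <- xs[-length(xs)] + pitch_um / 2
      cy <- seq(0, ey, by = py)
      cy <- cy[-length(cy)] + py / 2
      if (length(cx) > 0 && length(cy) > 0)
        grid <- rbind(grid, expand.grid(x = cx, y = cy))
    }
  } else {
    # triangular lattice: rows offset by pitch/2, spaced pitch * sqrt(3)/2
    dy <- pitch_um * sqrt(3) / 2
    ys <- seq(0, ey, by = dy)
    rows <- lapply(seq_along(ys), function(i) {
      off <- if (i %% 2 == 0) pitch_um / 2 else 0
      xs <- seq(off, ex, by = pitch_um)
      data.frame(x = xs, y = ys[i])
    })
    grid <- do.call(rbind, rows)
  }
  grid <- grid[order(grid$y, grid$x), , drop = FALSE]
  data.frame(
    spot_id = sprintf("spot_%04d", seq_len(nrow(grid))),
    x = grid$x, y = grid$y,
    section_id = section_id, replicate_id = replicate_id,
    cluster = NA_character_, platform = platform,
    stringsAsFactors = FALSE
  )
}

#' Simulate spot expression with spatial domain programs
#'
#' Draws negative-binomial counts per gene and spot, raising the log-mean of
#' each program's member genes by `mean_shift` inside the program's region.
#' Spots inside a region receive that program's domain label as their cluster
#' (later programs overwrite earlier ones on overlap); spots in no region are
#' labelled `"background"`.
#'
#' @param lattice a spot-lattice data frame.
#' @param programs list of spatial programs, each a list with `domain_label`,
#'   `genes` (character vector), `mean_shift` (log-scale effect) and `region`,
#'   a predicate `function(x, y)` returning a logical vector.
#' @param gene_universe character vector of all simulated genes.
#' @param baseline_mean negative-binomial mean outside any program region.
#' @param dispersion negative-binomial size parameter (larger is closer to
#'   Poisson); must be positive.
#' @param seed RNG seed.
#' @return A list with `expression` (raw-counts `ExpressionMatrix`, spots as
#'   observations), `lattice` (cluster column filled with domain labels) and
#'   `programs`.
#' @export
simulate_spot_expression <- function(lattice, programs, gene_universe,
                                     baseline_mean = 5, dispersion = 10,
                                     seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be positive")
  for (p in programs) {
    if (length(setdiff(p$genes, gene_universe)) > 0)
      stop("program genes outside the gene universe")
  }
  n_spots <- nrow(lattice)
  mu <- matrix(baseline_mean, length(gene_universe), n_spots,
               dimnames = list(gene_universe, lattice$spot_id))
  labels <- rep("background", n_spots)
  for (p in programs) {
    inside <- p$region(lattice$x, lattice$y)
    labels[inside] <- p$domain_label
    mu[p$genes, inside] <- mu[p$genes, inside] * exp(p$mean_shift)
  }
  counts <- with_seed(seed, {
    matrix(stats::rnbinom(length(mu), size = dispersion, mu = as.vector(mu)),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  })
  lattice$cluster <- labels
  list(
    expression = expression_matrix(counts, layer = "raw_counts"),
    lattice = lattice,
    programs = programs
  )
}

#' Simulate a typed single-cell expression matrix with implanted programs
#'
#' Negative-binomial counts with per-type marker elevation and declared
#' ligand/receptor programs: each implanted pair elevates the ligand in its
#' sender type and the receptor in its receiver type by the pair's log-scale
#' effect.
#'
#' @param cell_types character vector of cell-type names (at least two for
#'   ligand-receptor testing downstream).
#' @param n_cells_per_type cells simulated per type (scalar or per-type).
#' @param gene_universe all simulated genes.
#' @param markers named list mapping cell type to its marker genes.
#' @param marker_shift log-scale elevation of a type's markers in that type.
#' @param lr_truth data frame with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `effect` (log-scale); may be empty.
#' @param baseline_mean,dispersion negative-binomial parameters.
#' @param seed RNG seed.
#' @return A list with `expression` (raw counts), `annotations` (obs_id,
#'   sample_id, tissue, cell_type) and `lr_truth`.
#' @export
simulate_scrnaseq <- function(cell_types, n_cells_per_type, gene_universe,
                              markers = list(), marker_shift = 2,
                              lr_truth = NULL,
                              baseline_mean = 0.5, dispersion = 2, seed = 1L) {
  if (any(n_cells_per_type < 1)) stop("n_cells_per_type must be at least 1")
  n_per <- rep_len(n_cells_per_type, length(cell_types))
  type_of <- rep(cell_types, n_per)
  n_cells <- length(type_of)
  obs_id <- sprintf("cell_%05d", seq_len(n_cells))
  mu <- matrix(baseline_mean, length(gene_universe), n_cells,
               dimnames = list(gene_universe, obs_id))
  for (ty in names(markers)) {
    idx <- type_of == ty
    mu[markers[[ty]], idx] <- mu[markers[[ty]], idx] * exp(marker_shift)
  }
  if (!is.null(lr_truth) && nrow(lr_truth) > 0) {
    for (i in seq_len(nrow(lr_truth))) {
      mu[lr_truth$ligand[i], type_of == lr_truth$sender[i]] <-
        baseline_mean * exp(lr_truth$effect[i])
      mu[lr_truth$receptor[i], type_of == lr_truth$receiver[i]] <-
        baseline_mean * exp(lr_truth$effect[i])
    }
  }
  counts <- with_seed(seed, {
    matrix(stats::rnbinom(length(mu), size = dispersion, mu = as.vector(mu)),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  })
  list(
    expression = expression_matrix(counts, layer = "raw_counts"),
    annotations = data.frame(
      obs_id = obs_id, sample_id = "sim1", tissue = "tumor",
      cell_type = type_of, stringsAsFactors = FALSE
    ),
    lr_truth = lr_truth
  )
}

#' Simulate a multiplexed-imaging field of view
#'
#' Places cells in a square field. Cell types without an attraction spec are
#' placed by complete spatial randomness; each attracted pair is placed by a
#' shared-parent (Neyman-Scott) process: common parent points are drawn
#' uniformly and both types' cells scatter around parents within
#' `cluster_radius`, so higher `attraction` concentrates both types near
#' fewer shared parents. A circular tumor blob assigns `is_tumor`; tumor
#' cells get the type `"tumor"`. Raw marker counts are drawn per type as
#' log-normal noise around type-specific means, with a dsDNA channel for all
#' cells.
#'
#' @param n_cells total cells in the field.
#' @param type_proportions named numeric vector over non-tumor cell types,
#'   summing to 1.
#' @param attraction_specs list of specs, each a list with `type_a`, `type_b`,
#'   `attraction` (>= 0; 0 means independent placement) and `cluster_radius`
#'   in micrometres.
#' @param fov_size_um side of the square field (default 800).
#' @param tumor_blob list with `center` (x, y) and `radius`; cells inside are
#'   tumor. `NULL` for no tumor region.
#' @param tumor_fraction fraction of cells placed inside the tumor blob when
#'   one is given.
#' @param markers character vector of marker names (a `dsDNA` channel is
#'   always added).
#' @param marker_noise log-normal sd of marker counts.
#' @param seed RNG seed.
#' @return A segmented-cell data frame with raw marker columns (`raw_<name>`).
#' @export
simulate_mibi_fov <- function(n_cells, type_proportions,
                              attraction_specs = list(),
                              fov_size_um = 800,
                              tumor_blob = NULL, tumor_fraction = 0.4,
                              markers = c("CD8", "FOXP3", "CD4"),
                              marker_noise = 0.3,
                              fov_id = "fov1", seed = 1L) {
  if (n_cells == 0) {
    out <- data.frame(cell_id = character(0), fov_id = character(0),
                      x = numeric(0), y = numeric(0), size = numeric(0),
                      cell_type = character(0), is_tumor = logical(0))
    for (mk in c("dsDNA", markers)) out[[paste0("raw_", mk)]] <- numeric(0)
    return(out)
  }
  if (abs(sum(type_proportions) - 1) > 1e-8 || any(type_proportions < 0))
    stop("type_proportions must be non-negative and sum to 1")
  with_seed(seed, {
    n_tumor <- if (is.null(tumor_blob)) 0L else round(n_cells * tumor_fraction)
    n_rest <- n_cells - n_tumor
    type_of <- sample(rep(names(type_proportions),
                          diff(round(cumsum(c(0, type_proportions)) * n_rest))))
    xy <- matrix(stats::runif(2 * n_rest, 0, fov_size_um), ncol = 2)
    for (spec in attraction_specs) {
      if (spec$attraction <= 0) next
      idx <- which(type_of %in% c(spec$type_a, spec$type_b))
      if (length(idx) == 0) next
      # fewer parents = stronger clustering; at least one parent
      n_parents <- max(1L, ceiling(length(idx) / (1 + spec$attraction)))
      parents <- matrix(stats::runif(2 * n_parents, 0, fov_size_um), ncol = 2)
      assign_p <- sample.int(n_parents, length(idx), replace = TRUE)
      ang <- stats::runif(length(idx), 0, 2 * pi)
      rad <- spec$cluster_radius * sqrt(stats::runif(length(idx)))
      xy[idx, 1] <- pmin(pmax(parents[assign_p, 1] + rad * cos(ang), 0), fov_size_um)
      xy[idx, 2] <- pmin(pmax(parents[assign_p, 2] + rad * sin(ang), 0), fov_size_um)
    }
    is_tumor <- rep(FALSE, n_rest)
    if (n_tumor > 0) {
      ang <- stats::runif(n_tumor, 0, 2 * pi)
      rad <- tumor_blob$radius * sqrt(stats::runif(n_tumor))
      txy <- cbind(
        pmin(pmax(tumor_blob$center[1] + rad * cos(ang), 0), fov_size_um),
        pmin(pmax(tumor_blob$center[2] + rad * sin(ang), 0), fov_size_um)
      )
      xy <- rbind(xy, txy)
      type_of <- c(type_of, rep("tumor", n_tumor))
      is_tumor <- c(is_tumor, rep(TRUE, n_tumor))
    }
    n <- nrow(xy)
    size <- round(stats::runif(n, 80, 250))
    cells <- data.frame(
      cell_id = sprintf("c%05d", seq_len(n)), fov_id = fov_id,
      x = xy[, 1], y = xy[, 2], size = size,
      cell_type = type_of, is_tumor = is_tumor,
      stringsAsFactors = FALSE
    )
    all_markers <- c("dsDNA", markers)
    # type-specific base intensity per non-dsDNA marker, scaled by cell size
    for (mk in all_markers) {
      base <- if (mk == "dsDNA") {
        rep(5, n)
      } else {
        ifelse(type_of == mk, 8, 0.5)  # markers named after the type they mark
      }
      cells[[paste0("raw_", mk)]] <-
        round(base * size * stats::rlnorm(n, 0, marker_noise))
    }
    validate_cell_table(cells)
    cells
  })
}

#' Simulate a pooled CRISPR screen
#'
#' Draws negative-binomial counts around equal guide representation at t0 and
#' shifts each effect gene's guides at t1 by the designated log2 fold-change,
#' in the designated arm only. Non-targeting guides are never shifted.
#'
#' @param n_genes,guides_per_gene,n_nontargeting library composition; defaults
#'   match a 334-gene, 8-guides-per-gene library with 136 non-targeting
#'   controls.
#' @param effect_genes data frame with columns `gene` (e.g. `"gene_001"`),
#'   `arm` (`"in_vivo"` or `"in_vitro"`) and `log2fc`; may be empty.
#' @param n_replicates replicates per arm.
#' @param depth mean total reads per sample.
#' @param overdispersion negative-binomial size parameter.
#' @param cell_line cell-line label for all samples.
#' @param seed RNG seed.
#' @return A list with `screen` (a [screen_counts()]), `meta` (sample
#'   metadata: sample_id, timepoint, arm, replicate, cell_line) and
#'   `effect_genes`.
#' @export
simulate_screen <- function(n_genes = 334L, guides_per_gene = 8L,
                            n_nontargeting = 136L,
                            effect_genes = NULL, n_replicates = 3L,
                            depth = 1e6, overdispersion = 50,
                            cell_line = "line1", seed = 1L) {
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  guide_map <- data.frame(
    guide_id = c(
      sprintf("%s_g%d", rep(genes, each = guides_per_gene),
              rep(seq_len(guides_per_gene), n_genes)),
      sprintf("NTC_g%03d", seq_len(n_nontargeting))
    ),
    gene = c(rep(genes, each = guides_per_gene),
             rep("NON_TARGETING", n_nontargeting)),
    stringsAsFactors = FALSE
  )
  n_guides <- nrow(guide_map)
  if (depth < n_guides) warning("depth below number of guides; counts will be sparse")
  if (!is.null(effect_genes) && nrow(effect_genes) > 0 &&
      length(setdiff(effect_genes$gene, genes)) > 0)
    stop("effect genes outside the library")
  arms <- c("in_vivo", "in_vitro")
  meta <- do.call(rbind, lapply(arms, function(a) {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(
        sample_id = sprintf("%s_r%d_%s", a, r, c("t0", "t1")),
        timepoint = c("t0", "t1"), arm = a, replicate = sprintf("r%d", r),
        cell_line = cell_line, stringsAsFactors = FALSE
      )
    }))
  }))
  base_mu <- depth / n_guides
  counts <- with_seed(seed, {
    out <- matrix(0, n_guides, nrow(meta),
                  dimnames = list(guide_map$guide_id, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      mu <- rep(base_mu, n_guides)
      if (meta$timepoint[j] == "t1" && !is.null(effect_genes) &&
          nrow(effect_genes) > 0) {
        for (i in seq_len(nrow(effect_genes))) {
          if (effect_genes$arm[i] == meta$arm[j]) {
            hit <- guide_map$gene == effect_genes$gene[i]
            mu[hit] <- mu[hit] * 2^effect_genes$log2fc[i]
          }
        }
      }
      out[, j] <- stats::rnbinom(n_guides, size = overdispersion, mu = mu)
    }
    out
  })
  list(screen = screen_counts(counts, guide_map), meta = meta,
       effect_genes = effect_genes)
}

#' Simulate a bulk tumor cohort with implanted CNV-loss effects
#'
#' Draws per-gene copy-number losses by the given probabilities and normal
#' log-expression; tumors carrying a loss of an effect gene have their
#' CAF-signature genes shifted down by the gene's effect size, and the lost
#' gene's own expression reduced.
#'
#' @param n_tumors cohort size.
#' @param tumor_types character vector of type labels to cycle over tumors.
#' @param genes all cohort genes.
#' @param caf_genes genes making up the stromal (CAF) signature.
#' @param cnv_loss_prob named per-gene loss probability (unnamed scalar is
#'   recycled).
#' @param effect_genes data frame with columns `gene` and `shift`: tumors
#'   with a loss of `gene` have CAF-signature expression reduced by `shift`.
#' @param base_mean,noise_sd normal log-expression parameters.
#' @param own_loss_shift reduction of a lost gene's own expression.
#' @param seed RNG seed.
#' @return A list with `cohort` (a [bulk_cohort()]), `caf_genes`,
#'   `effect_genes`, and `flagged_no_stable` (effect genes with no stable
#'   tumors, for which the downstream effect is undefined).
#' @export
simulate_bulk_cohort <- function(n_tumors = 300L,
                                 tumor_types = c("typeA", "typeB"),
                                 genes, caf_genes,
                                 cnv_loss_prob = 0.2,
                                 effect_genes = NULL,
                                 base_mean = 2, noise_sd = 0.5,
                                 own_loss_shift = 1, seed = 1L) {
  stopifnot(all(cnv_loss_prob >= 0), all(cnv_loss_prob <= 1))
  stopifnot(all(caf_genes %in% genes))
  loss_p <- if (is.null(names(cnv_loss_prob)))
    stats::setNames(rep_len(cnv_loss_prob, length(genes)), genes)
  else cnv_loss_prob[genes]
  tumor_id <- sprintf("tumor_%04d", seq_len(n_tumors))
  tumor_type <- stats::setNames(rep_len(tumor_types, n_tumors), tumor_id)
  with_seed(seed, {
    cnv <- matrix(
      -as.integer(stats::runif(n_tumors * length(genes)) <
                    rep(loss_p, each = n_tumors)),
      n_tumors, length(genes), dimnames = list(tumor_id, genes)
    )
    expression <- matrix(
      stats::rnorm(n_tumors * length(genes), base_mean, noise_sd),
      n_tumors, length(genes), dimnames = list(tumor_id, genes)
    )
    expression[cnv < 0] <- expression[cnv < 0] - own_loss_shift
    flagged <- character(0)
    if (!is.null(effect_genes) && nrow(effect_genes) > 0) {
      for (i in seq_len(nrow(effect_genes))) {
        g <- effect_genes$gene[i]
        lost <- cnv[, g] < 0
        if (all(lost)) flagged <- c(flagged, g)
        expression[lost, caf_genes] <-
          expression[lost, caf_genes] - effect_genes$shift[i]
      }
    }
    expression <- pmax(expression, 0)
    list(
      cohort = bulk_cohort(expression, cnv, tumor_type),
      caf_genes = caf_genes, effect_genes = effect_genes,
      flagged_no_stable = flagged
    )
  })
}
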