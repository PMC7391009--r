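#' Build a k-nearest-neighbor graph over spots
#'
#' For every spot, finds the `k` nearest other spots within the same section
#' by Euclidean distance, with ties broken by spot identifier. No radius gate
#' is applied: boundary spots simply have farther neighbors. Sections with at
#' most `k` spots yield truncated neighbor lists with a warning.
#'
#' @param lattice spot-lattice data frame.
#' @param k neighbors per spot; defaults to 4 for ST and 6 for Visium.
#' @return An object of class `NeighborGraph`: a list with `neighbors` and
#'   `distances`, each a named list over spot ids (neighbor ids / distances in
#'   micrometres, ascending by distance), plus the `k` used.
#' @export
build_spot_graph <- function(lattice, k = NULL) {
  validate_lattice(lattice)
  if (is.null(k)) k <- if (lattice$platform[1] == "ST") 4L else 6L
  stopifnot(k >= 1)
  if (nrow(lattice) < 2) stop("at least 2 spots are required")
  neighbors <- vector("list", nrow(lattice))
  distances <- vector("list", nrow(lattice))
  names(neighbors) <- names(distances) <- lattice$spot_id
  for (sec in unique(lattice$section_id)) {
    idx <- which(lattice$section_id == sec)
    n_sec <- length(idx)
    if (n_sec <= k)
      warning(sprintf("section %s has %d spots; neighbor lists truncated to %d",
                      sec, n_sec, n_sec - 1L))
    kk <- min(k, n_sec - 1L)
    sub <- lattice[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(cbind(sub$x, sub$y)))
    for (i in seq_len(n_sec)) {
      ord <- order(d[i, -i], sub$spot_id[-i])
      sel <- seq_len(kk)
      nb <- sub$spot_id[-i][ord][sel]
      neighbors[[sub$spot_id[i]]] <- nb
      distances[[sub$spot_id[i]]] <- unname(d[i, -i][ord][sel])
    }
  }
  structure(list(neighbors = neighbors, distances = distances, k = k),
            class = "NeighborGraph")
}

#' Sliding-window average expression over spot groups
#'
#' Replaces each spot's expression by the mean over its spot group: the spot
#' itself plus its graph neighbors. The output has the same genes-by-spots
#' shape as the input.
#'
#' @param spot_expr log-normalized `ExpressionMatrix` over spots.
#' @param graph a [build_spot_graph()] result covering every spot of
#'   `spot_expr`.
#' @return A list of class `WindowedMatrix` with `values` (gene-by-spot
#'   matrix of group means), `groups` (named list of group member ids) and
#'   `n_neighbors`.
#' @export
sliding_window_average <- function(spot_expr, graph) {
  spots <- colnames(spot_expr)
  missing <- setdiff(spots, names(graph$neighbors))
  if (length(missing) > 0)
    stop("spots missing from the neighbor graph: ",
         paste(utils::head(missing, 5), collapse = ", "))
  vals <- unclass_matrix(spot_expr)
  out <- vals
  groups <- vector("list", length(spots))
  names(groups) <- spots
  for (s in spots) {
    grp <- c(s, intersect(graph$neighbors[[s]], spots))
    groups[[s]] <- grp
    out[, s] <- rowMeans(vals[, grp, drop = FALSE])
  }
  structure(list(values = out, groups = groups, n_neighbors = graph$k),
            class = "WindowedMatrix")
}

#' Spatial gene correlation against an anchor gene
#'
#' Pearson correlation between the anchor gene's per-spot expression vector
#' and every gene's sliding-window (spot-group) average vector. Genes whose
#' windowed vector is constant are returned as `NA` and flagged, never as 0.
#'
#' @param spot_expr log-normalized `ExpressionMatrix` over spots.
#' @param windowed the matching [sliding_window_average()] result.
#' @param anchor_gene gene whose raw per-spot vector anchors the correlation.
#' @return A data frame with columns `gene`, `correlation` and `defined`.
#' @export
spatial_gene_correlation <- function(spot_expr, windowed, anchor_gene) {
  if (!anchor_gene %in% rownames(spot_expr))
    stop("anchor gene not in matrix: ", anchor_gene)
  anchor <- unclass_matrix(spot_expr)[anchor_gene, ]
  if (stats::sd(anchor) == 0)
    stop("anchor gene has zero variance across spots: ", anchor_gene)
  w <- windowed$values[, names(anchor), drop = FALSE]
  sds <- apply(w, 1, stats::sd)
  defined <- sds > 0
  correlation <- rep(NA_real_, nrow(w))
  correlation[defined] <- as.vector(stats::cor(anchor, t(w[defined, , drop = FALSE])))
  data.frame(gene = rownames(w), correlation = correlation, defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Observed cluster-adjacency counts for a lattice + graph: entry (a, b) is
# the number of (spot of cluster a, neighbor of cluster b) incidences.
adjacency_counts <- function(lattice, graph, clusters = NULL) {
  labels <- if (is.null(clusters)) lattice$cluster else clusters
  names(labels) <- lattice$spot_id
  lv <- sort(unique(labels))
  ci <- match(labels[rep(lattice$spot_id,
                         lengths(graph$neighbors[lattice$spot_id]))], lv)
  cj <- match(labels[unlist(graph$neighbors[lattice$spot_id], use.names = FALSE)], lv)
  k <- length(lv)
  counts <- matrix(tabulate(ci + k * (cj - 1L), nbins = k * k), k, k,
                   dimnames = list(lv, lv))
  counts
}

#' Cluster-adjacency permutation test
#'
#' Counts the cluster identities of each spot's nearest neighbors and
#' compares every cluster-pair count against a null built by shuffling
#' cluster labels within each tissue section (preserving the number of spots
#' and the cluster composition per section). The p-value of a pair is the
#' fraction of permutations whose count strictly exceeds the observed count.
#'
#' @param lattice spot-lattice data frame with a `cluster` column.
#' @param k neighbors per spot (default platform-appropriate).
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param pooled if `TRUE` (default), counts are pooled across sections
#'   before the comparison; otherwise a per-section result list is returned.
#' @return For pooled mode, a list with `observed` (cluster-by-cluster count
#'   matrix), `results` (data frame: cluster_a, cluster_b, observed, p_value,
#'   degenerate) and `permutation` (per-pair null matrices folded into an
#'   n_perm-by-pairs matrix). A single cluster yields a degenerate flag on
#'   every pair with a warning.
#' @export
adjacency_permutation_test <- function(lattice, k = NULL,
                                       n_perm = 1000L, seed = 1L,
                                       pooled = TRUE) {
  if (any(is.na(lattice$cluster)))
    stop("every spot needs a cluster label")
  graph <- build_spot_graph(lattice, k)
  if (!pooled) {
    secs <- unique(lattice$section_id)
    out <- lapply(secs, function(sec) {
      adjacency_permutation_test(lattice[lattice$section_id == sec, ,
                                         drop = FALSE],
                                 k = k, n_perm = n_perm, seed = seed,
                                 pooled = TRUE)
    })
    names(out) <- secs
    return(out)
  }
  single_cluster <- length(unique(lattice$cluster)) < 2
  if (single_cluster)
    warning("single cluster; adjacency p-values are degenerate")
  observed <- adjacency_counts(lattice, graph)
  lv <- rownames(observed)
  sections <- split(seq_len(nrow(lattice)), lattice$section_id)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      labels <- lattice$cluster
      for (idx in sections) labels[idx] <- sample(labels[idx])
      as.vector(adjacency_counts(lattice, graph, clusters = labels))
    }, numeric(length(observed)))
  })
  if (length(observed) == 1) null_counts <- matrix(null_counts, nrow = 1)
  pairs <- expand.grid(cluster_a = lv, cluster_b = lv,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    permutation_result(as.vector(observed)[i], null_counts[i, ],
                       tail = "greater", seed = seed)
  })
  results <- data.frame(
    pairs,
    observed = as.vector(observed),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate") | single_cluster,
    stringsAsFactors = FALSE
  )
  list(observed = observed, results = results, null_counts = t(null_counts),
       n_permutations = as.integer(n_perm), seed = as.integer(seed))
}

#' Correlation matrix of differentially-expressed-gene overlaps
#'
#' Builds the binary gene-membership matrix of a list of cluster gene sets
#' over a gene universe and returns the pairwise Pearson correlation of its
#' columns (the phi coefficient of set overlap). Columns whose membership
#' indicator is constant (empty or full-universe sets) are undefined and
#' returned as `NA`.
#'
#' @param sets list of [gene_set()] objects.
#' @param universe a [gene_set()] with the full gene universe.
#' @return A list with `membership` (genes-by-sets 0/1 matrix), `correlation`
#'   (sets-by-sets matrix, `NA` where undefined) and `defined` (logical per
#'   set).
#' @export
deg_overlap_matrix <- function(sets, universe) {
  genes <- universe$genes
  if (length(genes) == 0) stop("empty gene universe")
  member <- vapply(sets, function(s) {
    extra <- setdiff(s$genes, genes)
    if (length(extra) > 0)
      stop("set ", s$name, " has genes outside the universe")
    as.numeric(genes %in% s$genes)
  }, numeric(length(genes)))
  colnames(member) <- vapply(sets, `[[`, character(1), "name")
  rownames(member) <- genes
  defined <- apply(member, 2, stats::sd) > 0
  correlation <- matrix(NA_real_, ncol(member), ncol(member),
                        dimnames = list(colnames(member), colnames(member)))
  if (any(defined))
    correlation[defined, defined] <- stats::cor(member[, defined, drop = FALSE])
  list(membership = member, correlation = correlation, defined = defined)
}
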