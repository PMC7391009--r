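# Independent brute-force oracles used to verify the package's vectorized
# implementations on small instances. Each is written as the most naive
# possible loop over the definition.

# O(n^2) k-nearest-neighbor search by exhaustive pairwise distances,
# ties broken by id.
oracle_knn <- function(x, y, ids, k) {
  out <- list()
  for (i in seq_along(ids)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    ord <- order(d, ids)
    ord <- ord[ord != i]
    out[[ids[i]]] <- list(ids = ids[ord][seq_len(k)],
                          d = d[ord][seq_len(k)])
  }
  out
}

# Direct per-spot averaging over a group membership list.
oracle_window <- function(vals, groups) {
  out <- vals
  for (s in names(groups)) {
    acc <- rep(0, nrow(vals))
    for (g in groups[[s]]) acc <- acc + vals[, g]
    out[, s] <- acc / length(groups[[s]])
  }
  out
}

# Textbook Pearson correlation.
oracle_pearson <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Phi coefficient of two gene sets over a universe, from the 2x2 table.
oracle_phi <- function(set_a, set_b, universe) {
  a <- universe %in% set_a
  b <- universe %in% set_b
  n11 <- sum(a & b); n10 <- sum(a & !b)
  n01 <- sum(!a & b); n00 <- sum(!a & !b)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# Spreadsheet-style recomputation of centered guide log2 fold-changes for a
# single replicate: depth scaling, log2(x + pc), t1 - t0, non-targeting
# median centering.
oracle_log2fc_one_rep <- function(counts_t0, counts_t1, is_ntc, depth, pc) {
  n0 <- counts_t0 * depth / sum(counts_t0)
  n1 <- counts_t1 * depth / sum(counts_t1)
  delta <- log2(n1 + pc) - log2(n0 + pc)
  med <- median(delta[is_ntc])
  ifelse(is_ntc, delta, delta - med)
}

# Loop recomputation of cluster-adjacency counts from a neighbor graph.
oracle_adjacency_counts <- function(lattice, graph) {
  lv <- sort(unique(lattice$cluster))
  counts <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  lab <- setNames(lattice$cluster, lattice$spot_id)
  for (s in lattice$spot_id) {
    for (nb in graph$neighbors[[s]]) {
      counts[lab[s], lab[nb]] <- counts[lab[s], lab[nb]] + 1L
    }
  }
  counts
}

# A tiny deterministic raw-counts matrix used across data-model tests.
toy_counts <- function() {
  m <- matrix(
    c(9, 1, 0,
      0, 5, 5,
      2, 0, 8,
      1, 1, 1),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC", "mito1"),
                    c("cell1", "cell2", "cell3"))
  )
  expression_matrix(m, layer = "raw_counts")
}
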