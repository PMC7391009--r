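#' Derive a cell-type-specific gene signature
#'
#' A gene is specific to the target type when its mean log-expression
#' strictly exceeds `signature_hi` in the target type and is strictly below
#' `signature_lo` in every other type.
#'
#' @param profiles gene-by-cell-type matrix of mean log-expression (the
#'   `means` element of [celltype_mean_profile()]).
#' @param target_type column to derive the signature for.
#' @param cfg an [analysis_config()].
#' @return A [gene_set()] named after the target type; empty with a warning
#'   when no gene qualifies.
#' @export
derive_specific_signature <- function(profiles, target_type,
                                      cfg = analysis_config()) {
  if (!target_type %in% colnames(profiles))
    stop("unknown cell type: ", target_type)
  others <- profiles[, setdiff(colnames(profiles), target_type), drop = FALSE]
  hit <- profiles[, target_type] > cfg$signature_hi &
    apply(others < cfg$signature_lo, 1, all)
  if (!any(hit)) warning("no genes specific to ", target_type)
  gene_set(target_type, rownames(profiles)[hit])
}

# Assign genes to equal-width bins of average expression. Returns an integer
# bin index per gene; a zero-range profile puts everything in bin 1.
expression_bins <- function(avg, n_bins) {
  rng <- range(avg)
  if (diff(rng) == 0) return(stats::setNames(rep(1L, length(avg)), names(avg)))
  bin <- as.integer(cut(avg, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                        include.lowest = TRUE))
  stats::setNames(bin, names(avg))
}

# Sample n background genes for one signature gene from its expression bin,
# excluding signature genes; bins short of eligible genes borrow from the
# nearest neighboring bins until the pool suffices.
sample_background <- function(gene_bin, bins, eligible, n) {
  pool <- names(bins)[bins == gene_bin & eligible]
  width <- 1L
  max_bin <- max(bins)
  while (length(pool) < n && width <= max_bin) {
    near <- abs(bins - gene_bin) <= width
    pool <- names(bins)[near & eligible]
    width <- width + 1L
  }
  if (length(pool) <= n) return(pool)
  sample(pool, n)
}

#' Binned-background module score
#'
#' Scores each observation as the mean expression of the signature genes
#' minus the mean expression of a pooled background control set. Background
#' genes are drawn per signature gene from the gene's average-expression bin
#' (the range of all genes' average expression divided into `score_bins`
#' equal-width bins), `score_background` genes per signature gene, sampled
#' without replacement and excluding signature genes; bins with too few
#' eligible genes borrow from the nearest neighboring bins.
#'
#' @param m log-normalized `ExpressionMatrix` (or any gene-by-observation
#'   numeric matrix, e.g. bulk tumor expression with tumors as observations).
#' @param signature a [gene_set()]; genes absent from the matrix are dropped
#'   with a warning.
#' @param cfg an [analysis_config()] (`score_bins`, `score_background`).
#' @param seed RNG seed for the background sampling.
#' @param bins optional precomputed bin assignment (named integer per gene)
#'   shared across signatures.
#' @return A list of class `ScoreVector` with `scores` (named per
#'   observation), `signature`, `background` (sampled control genes, with
#'   multiplicity), `n_bins`, `n_background` and `seed`.
#' @export
module_score <- function(m, signature, cfg = analysis_config(),
                         seed = cfg$seed, bins = NULL) {
  vals <- if (inherits(m, "ExpressionMatrix")) unclass_matrix(m) else as.matrix(m)
  genes <- signature$genes
  absent <- setdiff(genes, rownames(vals))
  if (length(absent) > 0) {
    warning("signature genes absent from matrix dropped: ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  if (length(genes) == 0) stop("no signature genes present in the matrix")
  if (is.null(bins)) {
    avg <- rowMeans(vals)
    bins <- expression_bins(avg, cfg$score_bins)
  }
  eligible <- !(names(bins) %in% genes)
  background <- with_seed(seed, {
    unlist(lapply(genes, function(g)
      sample_background(bins[g], bins, eligible, cfg$score_background)),
      use.names = FALSE)
  })
  sig_mean <- colMeans(vals[genes, , drop = FALSE])
  bg_mean <- colMeans(vals[background, , drop = FALSE])
  structure(
    list(
      scores = sig_mean - bg_mean,
      signature = signature$name,
      background = background,
      n_bins = cfg$score_bins,
      n_background = cfg$score_background,
      seed = as.integer(seed)
    ),
    class = "ScoreVector"
  )
}

#' Score several signatures with shared binning
#'
#' Computes [module_score()] for each signature with the expression binning
#' computed once over the matrix.
#'
#' @inheritParams module_score
#' @param signatures list of [gene_set()] objects.
#' @return A list with `scores` (observation-by-signature matrix) and
#'   `vectors` (the per-signature `ScoreVector` objects). An empty signature
#'   list yields an empty table.
#' @export
score_signatures <- function(m, signatures, cfg = analysis_config(),
                             seed = cfg$seed) {
  vals <- if (inherits(m, "ExpressionMatrix")) unclass_matrix(m) else as.matrix(m)
  if (length(signatures) == 0)
    return(list(scores = matrix(0, ncol(vals), 0,
                                dimnames = list(colnames(vals), NULL)),
                vectors = list()))
  bins <- expression_bins(rowMeans(vals), cfg$score_bins)
  vectors <- lapply(signatures, function(s)
    module_score(m, s, cfg, seed = seed, bins = bins))
  scores <- vapply(vectors, `[[`, numeric(ncol(vals)), "scores")
  colnames(scores) <- vapply(signatures, `[[`, character(1), "name")
  rownames(scores) <- colnames(vals)
  list(scores = scores, vectors = vectors)
}
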