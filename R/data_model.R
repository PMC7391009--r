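#' Expression matrix container
#'
#' A gene-by-observation numeric matrix with a layer tag distinguishing raw
#' counts from log-normalized values. Row names are gene identifiers, column
#' names are observation (cell, spot or tumor) identifiers; both must be
#' unique. Raw counts must be non-negative integers; log-normalized values
#' must be non-negative.
#'
#' @param values numeric matrix, genes in rows, observations in columns, with
#'   unique dimnames.
#' @param layer `"raw_counts"` or `"log_normalized"`.
#'
#' @return An object of class `ExpressionMatrix`: the matrix with a `layer`
#'   attribute.
#' @export
expression_matrix <- function(values, layer = c("raw_counts", "log_normalized")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("gene identifiers (rownames) are required")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("observation identifiers (colnames) are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate observation identifiers")
  if (any(!is.finite(values)))
    stop("non-finite expression values")
  if (any(values < 0))
    stop("negative expression values")
  if (layer == "raw_counts" && any(values != round(values)))
    stop("raw counts must be integers")
  attr(values, "layer") <- layer
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @rdname expression_matrix
#' @param m an `ExpressionMatrix`.
#' @export
expr_layer <- function(m) attr(m, "layer")

#' Gene set
#'
#' @param name set name.
#' @param genes character vector of unique gene identifiers.
#' @return A list of class `GeneSet` with fields `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("genes must be unique within a set")
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' Read a gene-by-barcode counts matrix from Matrix Market files
#'
#' Reads the conventional triplet of a Matrix Market sparse matrix plus
#' gene and barcode lists (one identifier per line, or first column of a
#' TSV) and returns a dense raw-counts [expression_matrix()].
#'
#' @param matrix_path path to the `.mtx` file.
#' @param genes_path path to the gene list (TSV, first column used).
#' @param barcodes_path path to the barcode list.
#' @return An `ExpressionMatrix` with `layer = "raw_counts"`.
#' @export
read_expression <- function(matrix_path, genes_path, barcodes_path) {
  mm <- Matrix::readMM(matrix_path)
  genes <- read_id_column(genes_path)
  barcodes <- read_id_column(barcodes_path)
  if (nrow(mm) != length(genes) || ncol(mm) != length(barcodes))
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d genes and %d barcodes supplied",
      nrow(mm), ncol(mm), length(genes), length(barcodes)
    ))
  values <- as.matrix(mm)
  dimnames(values) <- list(genes, barcodes)
  expression_matrix(values, layer = "raw_counts")
}

#' Write an expression matrix as Matrix Market plus identifier lists
#'
#' @param m an `ExpressionMatrix`.
#' @param matrix_path,genes_path,barcodes_path output paths.
#' @return Invisibly, the three paths.
#' @export
write_expression <- function(m, matrix_path, genes_path, barcodes_path) {
  sp <- Matrix::Matrix(unclass_matrix(m), sparse = TRUE)
  Matrix::writeMM(sp, matrix_path)
  writeLines(rownames(m), genes_path)
  writeLines(colnames(m), barcodes_path)
  invisible(c(matrix_path, genes_path, barcodes_path))
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

unclass_matrix <- function(m) {
  attr(m, "layer") <- NULL
  class(m) <- setdiff(class(m), "ExpressionMatrix")
  unclass(m)
}

#' QC-filter cells of a raw counts matrix
#'
#' Retains cells with at least `qc_min_genes` detected (nonzero) genes and a
#' mitochondrial read fraction of at most `qc_max_mito`; cells below the gene
#' cutoff or strictly above the mitochondrial cutoff are removed. The gene
#' axis is unchanged.
#'
#' @param m raw-counts `ExpressionMatrix`.
#' @param mito_genes a [gene_set()] of mitochondrial gene identifiers (must be
#'   a subset of the matrix genes); an empty set makes the mitochondrial
#'   criterion vacuously pass, with a warning.
#' @param cfg an [analysis_config()].
#' @return The filtered `ExpressionMatrix`.
#' @export
qc_filter_cells <- function(m, mito_genes, cfg = analysis_config()) {
  stopifnot(expr_layer(m) == "raw_counts")
  mito <- if (inherits(mito_genes, "GeneSet")) mito_genes$genes else as.character(mito_genes)
  if (length(setdiff(mito, rownames(m))) > 0)
    stop("mitochondrial genes absent from the matrix: ",
         paste(setdiff(mito, rownames(m)), collapse = ", "))
  detected <- colSums(m > 0)
  totals <- colSums(m)
  if (length(mito) == 0) {
    warning("empty mitochondrial gene set; mitochondrial criterion not applied")
    mito_frac <- rep(0, ncol(m))
  } else {
    mito_counts <- colSums(m[mito, , drop = FALSE])
    mito_frac <- ifelse(totals > 0, mito_counts / totals, 0)
  }
  keep <- detected >= cfg$qc_min_genes & mito_frac <= cfg$qc_max_mito
  expression_matrix(unclass_matrix(m)[, keep, drop = FALSE], layer = "raw_counts")
}

#' Log-normalize a raw counts matrix
#'
#' Scales each cell to `scale_total` counts and applies a natural log1p
#' transform, the convention downstream log-space expression thresholds
#' assume. All-zero cells are left as zeros with a warning.
#'
#' @param m raw-counts `ExpressionMatrix`.
#' @param scale_total per-cell total after scaling (default 10,000).
#' @return An `ExpressionMatrix` with `layer = "log_normalized"`.
#' @export
log_normalize <- function(m, scale_total = 1e4) {
  stopifnot(expr_layer(m) == "raw_counts")
  totals <- colSums(m)
  if (any(totals == 0) && ncol(m) > 0)
    warning(sum(totals == 0), " cell(s) with zero total counts left as zeros")
  scale <- ifelse(totals > 0, scale_total / totals, 0)
  out <- log1p(sweep(unclass_matrix(m), 2, scale, `*`))
  expression_matrix(out, layer = "log_normalized")
}

#' Per-cell-type mean expression profiles
#'
#' Arithmetic mean of log-normalized expression per cell type, plus the
#' per-type expressing-cell fraction (share of cells with value > 0).
#'
#' @param m log-normalized `ExpressionMatrix`.
#' @param annotations data frame with columns `obs_id` and `cell_type`
#'   covering every observation in `m`.
#' @return A list with `means` and `fractions`, both gene-by-cell-type
#'   matrices, and `n_cells`, a named count per type.
#' @export
celltype_mean_profile <- function(m, annotations) {
  stopifnot(expr_layer(m) == "log_normalized")
  ann <- annotations[match(colnames(m), annotations$obs_id), , drop = FALSE]
  if (anyNA(ann$obs_id))
    stop("unannotated observations: ",
         paste(utils::head(setdiff(colnames(m), annotations$obs_id), 5), collapse = ", "))
  types <- sort(unique(ann$cell_type))
  means <- matrix(0, nrow(m), length(types), dimnames = list(rownames(m), types))
  fractions <- means
  n_cells <- integer(length(types))
  names(n_cells) <- types
  vals <- unclass_matrix(m)
  for (ty in types) {
    idx <- which(ann$cell_type == ty)
    n_cells[ty] <- length(idx)
    means[, ty] <- rowMeans(vals[, idx, drop = FALSE])
    fractions[, ty] <- rowMeans(vals[, idx, drop = FALSE] > 0)
  }
  list(means = means, fractions = fractions, n_cells = n_cells)
}

#' Read and write tabular inputs
#'
#' Readers/writers for the package's plain-text tables: spot lattices
#' (TSV: spot_id, x, y, section_id, replicate_id, cluster, platform),
#' observation annotations (CSV: obs_id, sample_id, tissue, cell_type),
#' segmented-cell tables (CSV: cell_id, fov_id, x, y, size, cell_type,
#' is_tumor, one column per marker), screen counts (TSV: guide_id, gene,
#' one column per sample) and bulk cohorts (expression and CNV TSVs with a
#' tumor_id column plus a tumor_type column in the expression table).
#' All text I/O is UTF-8 with a header row; coordinates are micrometres.
#'
#' @param path input or output path.
#' @name tabular_io
NULL

#' @rdname tabular_io
#' @export
read_spot_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("spot_id", "x", "y", "section_id", "replicate_id", "platform")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("spot table missing columns: ", paste(missing, collapse = ", "))
  validate_lattice(df)
  df
}

#' @rdname tabular_io
#' @param lattice a spot lattice data frame.
#' @export
write_spot_table <- function(lattice, path) {
  utils::write.table(lattice, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_lattice <- function(lattice) {
  stopifnot(all(is.finite(lattice$x)), all(is.finite(lattice$y)))
  if (!all(lattice$platform %in% c("ST", "Visium")))
    stop("platform must be ST or Visium for every spot")
  key <- paste(lattice$section_id, lattice$x, lattice$y)
  if (anyDuplicated(key)) stop("duplicate (x, y) within a section")
  if (anyDuplicated(lattice$spot_id)) stop("duplicate spot_id")
  invisible(lattice)
}

#' @rdname tabular_io
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("obs_id", "sample_id", "tissue", "cell_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("annotation table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$obs_id)) stop("duplicate obs_id in annotations")
  df
}

#' @rdname tabular_io
#' @param annotations an annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "fov_id", "x", "y", "size", "cell_type", "is_tumor")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("cell table missing columns: ", paste(missing, collapse = ", "))
  df$is_tumor <- as.logical(df$is_tumor)
  validate_cell_table(df)
  df
}

#' @rdname tabular_io
#' @param cells a segmented-cell data frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

validate_cell_table <- function(cells) {
  stopifnot(all(cells$size > 0))
  if (anyDuplicated(paste(cells$fov_id, cells$cell_id)))
    stop("duplicate (fov_id, cell_id)")
  invisible(cells)
}

# Marker columns of a cell table: everything that is not metadata, with an
# optional prefix distinguishing raw from normalized values.
marker_columns <- function(cells, prefix = "raw_") {
  cols <- grep(paste0("^", prefix), names(cells), value = TRUE)
  if (length(cols) == 0) stop("no marker columns with prefix '", prefix, "'")
  cols
}

#' @rdname tabular_io
#' @export
read_screen_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("guide_id", "gene")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("screen counts missing columns: ", paste(missing, collapse = ", "))
  samples <- setdiff(names(df), required)
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$guide_id
  screen_counts(counts, data.frame(guide_id = df$guide_id, gene = df$gene,
                                   stringsAsFactors = FALSE))
}

#' @rdname tabular_io
#' @param screen a [screen_counts()] object.
#' @export
write_screen_counts <- function(screen, path) {
  df <- cbind(
    data.frame(guide_id = screen$guide_map$guide_id, gene = screen$guide_map$gene,
               stringsAsFactors = FALSE),
    as.data.frame(screen$counts)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Screen counts container
#'
#' @param counts guide-by-sample matrix of non-negative integers with guide
#'   identifiers as rownames.
#' @param guide_map data frame with columns `guide_id` and `gene`; the gene
#'   value `"NON_TARGETING"` flags a non-targeting control guide.
#' @return A list of class `ScreenCounts` with fields `counts` and
#'   `guide_map` (gains an `is_nontargeting` column).
#' @export
screen_counts <- function(counts, guide_map) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  stopifnot(nrow(counts) == nrow(guide_map))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("screen counts must be non-negative integers")
  if (anyDuplicated(guide_map$guide_id)) stop("duplicate guide_id")
  guide_map$is_nontargeting <- guide_map$gene == "NON_TARGETING"
  if (!any(guide_map$is_nontargeting))
    stop("at least one non-targeting guide is required for centering")
  rownames(counts) <- guide_map$guide_id
  structure(list(counts = counts, guide_map = guide_map), class = "ScreenCounts")
}

#' Bulk tumor cohort container
#'
#' @param expression tumor-by-gene numeric matrix.
#' @param cnv tumor-by-gene integer matrix of GISTIC-style thresholded calls
#'   in -2..2, with the same dimnames as `expression`.
#' @param tumor_type named character vector of tumor-type labels, one per
#'   tumor.
#' @return A list of class `BulkCohort`.
#' @export
bulk_cohort <- function(expression, cnv, tumor_type) {
  expression <- as.matrix(expression)
  cnv <- as.matrix(cnv)
  stopifnot(identical(dimnames(expression), dimnames(cnv)))
  if (any(cnv != round(cnv)) || any(cnv < -2) || any(cnv > 2))
    stop("cnv values must be integers in [-2, 2]")
  stopifnot(identical(sort(names(tumor_type)), sort(rownames(expression))))
  tumor_type <- tumor_type[rownames(expression)]
  structure(list(expression = expression, cnv = cnv, tumor_type = tumor_type),
            class = "BulkCohort")
}

#' @rdname tabular_io
#' @param cohort a [bulk_cohort()].
#' @param expr_path,cnv_path paths for the expression and CNV TSVs.
#' @export
write_bulk_cohort <- function(cohort, expr_path, cnv_path) {
  expr_df <- data.frame(tumor_id = rownames(cohort$expression),
                        tumor_type = unname(cohort$tumor_type),
                        cohort$expression, check.names = FALSE)
  cnv_df <- data.frame(tumor_id = rownames(cohort$cnv), cohort$cnv,
                       check.names = FALSE)
  utils::write.table(expr_df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(cnv_df, cnv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(expr_path, cnv_path))
}

#' @rdname tabular_io
#' @export
read_bulk_cohort <- function(expr_path, cnv_path) {
  expr_df <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                               check.names = FALSE)
  cnv_df <- utils::read.delim(cnv_path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  expression <- as.matrix(expr_df[, setdiff(names(expr_df), c("tumor_id", "tumor_type"))])
  rownames(expression) <- expr_df$tumor_id
  cnv <- as.matrix(cnv_df[, setdiff(names(cnv_df), "tumor_id")])
  rownames(cnv) <- cnv_df$tumor_id
  cnv <- cnv[rownames(expression), colnames(expression), drop = FALSE]
  tumor_type <- stats::setNames(expr_df$tumor_type, expr_df$tumor_id)
  bulk_cohort(expression, cnv, tumor_type)
}
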