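# Six hand-set cells in one FOV for tracing the normalization pipeline.
mibi_toy_cells <- function() {
  data.frame(
    cell_id = sprintf("c%d", 1:6), fov_id = "f1",
    x = c(0, 10, 20, 30, 40, 50), y = 0,
    size = c(100, 200, 100, 50, 100, 100),
    cell_type = "A", is_tumor = FALSE,
    raw_dsDNA = c(500, 1000, 400, 300, 600, 2),
    raw_CD8 = c(100, 400, 0, 50, 900, 10),
    stringsAsFactors = FALSE
  )
}

test_that("marker normalization matches a step-by-step hand computation", {
  cells <- mibi_toy_cells()
  cfg <- analysis_config()
  res <- normalize_markers(cells, cfg = cfg)

  # hand pipeline: size -> arcsinh -> FOV dsDNA median -> cutoff -> percentile
  v_ds <- asinh(cells$raw_dsDNA / cells$size)
  v_cd8 <- asinh(cells$raw_CD8 / cells$size)
  med <- median(v_ds)
  v_ds <- v_ds / med
  v_cd8 <- v_cd8 / med
  keep <- v_ds > 0.1
  expect_identical(res$cells$cell_id, cells$cell_id[keep])
  expect_identical(res$dropped$cell_id, cells$cell_id[!keep])
  scale01 <- function(v) {
    lo <- quantile(v, 0.10, names = FALSE)
    hi <- quantile(v, 0.90, names = FALSE)
    pmin(pmax((v - lo) / (hi - lo), 0), 1)
  }
  expect_equal(res$cells$norm_dsDNA, scale01(v_ds[keep]), tolerance = 1e-12)
  expect_equal(res$cells$norm_CD8, scale01(v_cd8[keep]), tolerance = 1e-12)
  expect_true(all(res$cells$norm_CD8 >= 0 & res$cells$norm_CD8 <= 1))

  # values at the percentile anchors map to exactly 0 and 1
  v <- v_cd8[keep]
  at_hi <- which(abs(v - quantile(v, 0.9, names = FALSE)) < 1e-12)
  if (length(at_hi) > 0) expect_equal(res$cells$norm_CD8[at_hi], rep(1, length(at_hi)))
})

test_that("normalization is invariant to uniform rescaling of raw counts", {
  set.seed(4)
  cells <- simulate_mibi_fov(120, c(CD8 = 0.5, CD4 = 0.5), seed = 4)
  a <- normalize_markers(cells)
  # joint rescaling of raw counts and sizes leaves counts-per-pixel, and so
  # the whole pipeline, exactly unchanged
  scaled <- cells
  for (col in grep("^raw_", names(cells), value = TRUE))
    scaled[[col]] <- scaled[[col]] * 7
  scaled$size <- scaled$size * 7
  b <- normalize_markers(scaled)
  expect_equal(a$cells$norm_CD8, b$cells$norm_CD8, tolerance = 1e-12)
  expect_identical(a$cells$cell_id, b$cells$cell_id)

  # zero-median dsDNA FOV is excluded with an error record
  bad <- cells
  bad$raw_dsDNA <- 0
  expect_warning(r <- normalize_markers(bad), "zero median dsDNA")
  expect_identical(r$failed_fovs, unique(cells$fov_id))
  expect_identical(nrow(r$cells), 0L)
})

test_that("co-localization distances match a manual Euclidean computation", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:10), fov_id = "f1",
    x = c(0, 3, 0, 4, 3, 10, 20, 30, 40, 50),
    y = c(0, 0, 4, 0, 4, 0, 0, 0, 0, 0),
    size = 100, is_tumor = FALSE,
    cell_type = c("A", "A", "B", "B", "B", rep("other", 5)),
    stringsAsFactors = FALSE
  )
  cfg <- analysis_config(min_coloc_cells = 2, n_perm_spatial = 50)
  res <- colocalization_test(cells, "A", "B", cfg, seed = 1)[["f1"]]
  # per-cell means by hand
  d_c1 <- mean(c(4, 4, 5))                # c1 -> (0,4), (4,0), (3,4)
  d_c2 <- mean(c(5, 1, 4))                # c2=(3,0) -> same three
  expect_equal(res$per_cell_mean_distances, c(d_c1, d_c2), tolerance = 1e-10)
  expect_equal(res$observed_median, median(c(d_c1, d_c2)), tolerance = 1e-10)

  # all A and B cells at the same coordinate: every mean distance is 0
  co <- cells
  co$x[co$cell_type %in% c("A", "B")] <- 0
  co$y[co$cell_type %in% c("A", "B")] <- 0
  res0 <- colocalization_test(co, "A", "B", cfg, seed = 1)[["f1"]]
  expect_equal(res0$per_cell_mean_distances, c(0, 0))
  expect_equal(res0$observed_median, 0)
})

test_that("mean A->B distance is symmetric as a matrix operation", {
  set.seed(9)
  cells <- simulate_mibi_fov(200, c(A = 0.4, B = 0.3, C = 0.3), seed = 9)
  ia <- cells$cell_type == "A"
  ib <- cells$cell_type == "B"
  d <- sqrt(outer(cells$x[ia], cells$x[ib], `-`)^2 +
              outer(cells$y[ia], cells$y[ib], `-`)^2)
  expect_equal(mean(rowMeans(d)), mean(colMeans(d)), tolerance = 1e-10)
})

test_that("implanted attraction is significant and sparse FOVs are skipped", {
  cells <- simulate_mibi_fov(
    300, c(A = 0.25, B = 0.25, C = 0.5),
    attraction_specs = list(list(type_a = "A", type_b = "B",
                                 attraction = 12, cluster_radius = 30)),
    seed = 5
  )
  cfg <- analysis_config(n_perm_spatial = 500)
  res <- colocalization_test(cells, "A", "B", cfg, seed = 5)[[1]]
  expect_lt(res$permutation$p_value, 0.05)
  expect_identical(res$permutation$tail, "less")

  few <- cells[cells$cell_type != "B" | seq_len(nrow(cells)) %in% 1:3, ]
  skip_res <- colocalization_test(few, "A", "B", cfg, seed = 5)[[1]]
  expect_match(skip_res$skipped, "insufficient")
})

test_that("infiltration classification follows the printed neighbor rule", {
  # geometry: one non-tumor probe cell at the origin; its 30 nearest
  # neighbors are a ring at r=10 with a controlled tumor count; 40 far
  # bystanders guarantee at least 31 cells per FOV.
  probe_fov <- function(n_tumor_near, fov) {
    ang <- seq(0, 2 * pi, length.out = 31)[1:30]
    near <- data.frame(
      cell_id = sprintf("n%02d", 1:30), fov_id = fov,
      x = 10 * cos(ang), y = 10 * sin(ang), size = 100,
      cell_type = "filler", is_tumor = rep(c(TRUE, FALSE),
                                           c(n_tumor_near, 30 - n_tumor_near)),
      stringsAsFactors = FALSE
    )
    far <- data.frame(
      cell_id = sprintf("f%02d", 1:40), fov_id = fov,
      x = 500 + runif(40, 0, 100), y = 500 + runif(40, 0, 100), size = 100,
      cell_type = "filler", is_tumor = FALSE, stringsAsFactors = FALSE
    )
    probe <- data.frame(cell_id = "probe", fov_id = fov, x = 0, y = 0,
                        size = 100, cell_type = "probe", is_tumor = FALSE,
                        stringsAsFactors = FALSE)
    rbind(probe, near, far)
  }
  set.seed(2)
  counts <- c(0, 3, 5, 13, 15, 30)
  expected <- c("stromal", "unassigned", "leading_edge", "leading_edge",
                "unassigned", "infiltrated")
  for (i in seq_along(counts)) {
    cells <- probe_fov(counts[i], sprintf("f%d", i))
    lab <- classify_infiltration(cells)$labels
    got <- lab$compartment[lab$cell_id == "probe"]
    expect_identical(got, expected[i], label = sprintf("count=%d", counts[i]))
    expect_identical(lab$tumor_neighbor_count[lab$cell_id == "probe"],
                     as.integer(counts[i]))
  }

  # deterministic and invariant to cell ordering
  cells <- probe_fov(7, "fx")
  a <- classify_infiltration(cells)$labels
  b <- classify_infiltration(cells[sample(nrow(cells)), ])$labels
  b <- b[match(a$cell_id, b$cell_id), ]
  expect_identical(a$compartment, b$compartment)

  # FOVs below 31 cells are skipped with a record
  small <- cells[1:20, ]
  expect_warning(r <- classify_infiltration(small), "skipped")
  expect_identical(r$skipped_fovs, "fx")
})

test_that("compartment composition rows are proportions that sum to one", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:10), fov_id = "f1", x = 1:10, y = 0, size = 100,
    cell_type = rep(c("T", "U"), 5), is_tumor = FALSE,
    stringsAsFactors = FALSE
  )
  labels <- data.frame(
    cell_id = cells$cell_id, fov_id = "f1",
    compartment = c(rep("stromal", 4), rep("leading_edge", 3),
                    rep("infiltrated", 2), "unassigned"),
    tumor_neighbor_count = 0L, stringsAsFactors = FALSE
  )
  comp <- compartment_composition(labels, cells)
  expect_equal(unname(rowSums(comp$proportions)[1:3]), rep(1, 3),
               tolerance = 1e-12)
  # hand count: stromal cells c1..c4 alternate T,U,T,U
  expect_equal(comp$proportions["stromal", "T"], 0.5)
  expect_equal(comp$counts["leading_edge", "T"], 2)
  expect_identical(comp$empty_compartments, character(0))

  # an empty compartment yields a zero row and a flag
  lab2 <- labels[labels$compartment != "infiltrated", ]
  comp2 <- compartment_composition(lab2, cells)
  expect_true("infiltrated" %in% comp2$empty_compartments)
  expect_true(all(comp2$proportions["infiltrated", ] == 0))

  # single cell type: populated rows are 1 for that type
  cells_one <- cells; cells_one$cell_type <- "T"
  comp3 <- compartment_composition(labels, cells_one)
  expect_true(all(comp3$proportions[rowSums(comp3$counts) > 0, "T"] == 1))
})
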