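# Minimal 2-gene + non-targeting screen with hand-settable counts.
toy_screen <- function(counts) {
  guide_map <- data.frame(
    guide_id = c("gA_1", "gA_2", "gB_1", "NTC_1", "NTC_2"),
    gene = c("geneA", "geneA", "geneB", "NON_TARGETING", "NON_TARGETING"),
    stringsAsFactors = FALSE
  )
  screen_counts(counts, guide_map)
}

toy_meta <- function(samples) {
  data.frame(
    sample_id = samples,
    timepoint = rep(c("t0", "t1"), length(samples) / 2),
    arm = "in_vivo",
    replicate = rep(sprintf("r%d", seq_len(length(samples) / 2)), each = 2),
    cell_line = "line1", stringsAsFactors = FALSE
  )
}

test_that("depth normalization hits the target total and preserves proportions", {
  counts <- matrix(c(10, 20, 30, 20, 20,
                     5, 5, 5, 5, 80), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  screen <- toy_screen(counts)
  cfg <- analysis_config(depth_total = 1e7)
  norm <- depth_normalize(screen, cfg)
  expect_equal(unname(colSums(norm)), c(1e7, 1e7), tolerance = 1e-6)
  for (j in 1:2)
    expect_equal(norm[, j] / sum(norm[, j]), counts[, j] / sum(counts[, j]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  # hand scaling of the 3-guide top block
  expect_equal(unname(norm[1:3, 1]), c(10, 20, 30) / 100 * 1e7)

  # a sample already at the target is unchanged
  at_target <- toy_screen(matrix(c(2e6, 2e6, 2e6, 2e6, 2e6), ncol = 1,
                                 dimnames = list(NULL, "s1")))
  expect_equal(depth_normalize(at_target, cfg)[, 1],
               at_target$counts[, 1], tolerance = 1e-9)

  zero <- toy_screen(matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), ncol = 2,
                            dimnames = list(NULL, c("ok", "empty"))))
  expect_error(depth_normalize(zero), "empty")
})

test_that("log2 fold-changes match a spreadsheet-style recomputation", {
  counts <- matrix(
    c(100, 200, 50, 100, 150,     # r1 t0
      50, 210, 20, 110, 140,      # r1 t1
      80, 180, 60, 90, 160,       # r2 t0
      85, 160, 65, 95, 150),      # r2 t1
    ncol = 4,
    dimnames = list(NULL, c("v_r1_t0", "v_r1_t1", "v_r2_t0", "v_r2_t1"))
  )
  screen <- toy_screen(counts)
  meta <- toy_meta(colnames(counts))
  cfg <- analysis_config(depth_total = 1e6, pseudocount = 1)
  fc <- guide_log2fc(depth_normalize(screen, cfg), screen, meta, cfg)
  is_ntc <- screen$guide_map$is_nontargeting
  for (r in 1:2) {
    oracle <- oracle_log2fc_one_rep(counts[, 2 * r - 1], counts[, 2 * r],
                                    is_ntc, 1e6, 1)
    expect_equal(unname(fc$log2fc[, r]), unname(oracle), tolerance = 1e-10)
  }
  # non-targeting guides keep uncentered values; centering the centered
  # gene-targeting values by the NTC median again subtracts zero only if
  # medians were zero, so instead verify the self-consistency identity:
  for (r in 1:2) {
    raw_delta <- log2(depth_normalize(screen, cfg)[, 2 * r] + 1) -
      log2(depth_normalize(screen, cfg)[, 2 * r - 1] + 1)
    expect_equal(unname(fc$log2fc[is_ntc, r]), unname(raw_delta[is_ntc]),
                 tolerance = 1e-10)
    expect_equal(median(fc$log2fc[!is_ntc, r] -
                          (raw_delta[!is_ntc] - median(raw_delta[is_ntc]))),
                 0, tolerance = 1e-10)
  }
})

test_that("centering arithmetic and the identity case behave as printed", {
  # identical t0 and t1 -> all log2FC zero before centering; NTC median 0
  counts <- matrix(rep(c(10, 20, 30, 40, 50), 2), ncol = 2,
                   dimnames = list(NULL, c("a_t0", "a_t1")))
  screen <- toy_screen(counts)
  fc <- guide_log2fc(depth_normalize(screen), screen, toy_meta(colnames(counts)))
  expect_true(all(abs(fc$log2fc) < 1e-12))
  expect_equal(unname(fc$nontargeting_median), 0)

  # all NTC at +0.5 and a gene guide at +1.5 -> centered value 1.0
  d <- 1e6 / 5
  t0 <- rep(d, 5)
  t1 <- c(2^1.5 * d, 2^1.5 * d, 2^1.5 * d, 2^0.5 * d, 2^0.5 * d)
  t1 <- t1 / sum(t1) * 1e6  # renormalized by depth; ratios preserved
  # bypass depth wrinkles: feed already-normalized counts with pseudocount 0
  cfg <- analysis_config(depth_total = sum(t1), pseudocount = 0)
  norm <- cbind(c_t0 = t0 / sum(t0) * sum(t1), c_t1 = t1)
  rownames(norm) <- toy_screen(matrix(1, 5, 1, dimnames = list(NULL, "x")))$guide_map$guide_id
  fc2 <- guide_log2fc(norm, toy_screen(matrix(1, 5, 1, dimnames = list(NULL, "x"))),
                      toy_meta(c("c_t0", "c_t1")), cfg)
  expect_equal(unname(fc2$log2fc["gA_1", 1]), 1.0, tolerance = 1e-10)
})

test_that("gene-level values are unweighted guide means", {
  sim <- simulate_screen(n_genes = 5, guides_per_gene = 3, n_nontargeting = 4,
                         n_replicates = 2, depth = 1e5, seed = 8)
  fc <- guide_log2fc(depth_normalize(sim$screen), sim$screen, sim$meta)
  gl <- gene_log2fc(fc)
  for (g in rownames(gl)) {
    guides <- fc$guide_map$guide_id[fc$guide_map$gene == g]
    expect_equal(gl[g, ], colMeans(fc$log2fc[guides, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("arm-difference FDR agrees with exhaustive label enumeration", {
  vals <- matrix(c(1.0, 0.4, -0.2, 0.3), 1,
                 dimnames = list("geneA", sprintf("rep%d", 1:4)))
  arm <- setNames(c("in_vivo", "in_vivo", "in_vitro", "in_vitro"),
                  colnames(vals))
  observed <- mean(vals[1, 1:2]) - mean(vals[1, 3:4])
  splits <- combn(4, 2)
  exhaustive <- apply(splits, 2, function(s)
    mean(vals[1, s]) - mean(vals[1, -s]))
  expected_fdr <- mean(abs(exhaustive) > abs(observed))
  res <- arm_difference_fdr(vals, arm, analysis_config(n_perm_screen = 4000),
                            seed = 5)
  expect_equal(res$observed_difference, observed, tolerance = 1e-12)
  # sampled permutations draw uniformly over the 6 assignments
  expect_lt(abs(res$fdr - expected_fdr),
            3 * sqrt(expected_fdr * (1 - expected_fdr) / 4000) + 0.01)

  # degenerate: identical replicate values, flagged
  const <- matrix(0.5, 1, 4, dimnames = list("g", colnames(vals)))
  res0 <- arm_difference_fdr(const, arm, analysis_config(n_perm_screen = 50),
                             seed = 1)
  expect_true(res0$degenerate)
  expect_identical(res0$fdr, 0)

  single_arm <- setNames(rep("in_vivo", 4), colnames(vals))
  expect_error(arm_difference_fdr(vals, single_arm), "both screen arms")
})

test_that("implanted in-vivo depletion is recovered at FDR < 0.1", {
  eff <- data.frame(gene = "gene_001", arm = "in_vivo", log2fc = -2)
  sim <- simulate_screen(n_genes = 50, guides_per_gene = 4,
                         n_nontargeting = 20, effect_genes = eff,
                         n_replicates = 3, depth = 2e5, seed = 3)
  fc <- guide_log2fc(depth_normalize(sim$screen), sim$screen, sim$meta)
  gl <- gene_log2fc(fc)
  res <- arm_difference_fdr(gl, fc$arm, analysis_config(n_perm_screen = 1000),
                            seed = 3)
  expect_lt(res$fdr[res$gene == "gene_001"], 0.1)
  expect_lt(res$observed_difference[res$gene == "gene_001"], -1)
})

test_that("co-essentiality network construction applies the seeding rules", {
  edges <- data.frame(
    gene_a = c("S1", "S1", "S2", "C1", "X1", "S1", "S2"),
    gene_b = c("C1", "C2", "C1", "C2", "S1", "S2", "X2"),
    fdr = c(0.01, 0.05, 0.02, 0.03, 0.01, 0.04, 0.5),
    syntenic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  hits <- c(S1 = 0.01, S2 = 0.05, X3 = 0.5)
  net <- build_coessential_network(edges, hits)
  # seeds: S1, S2; C1 touches both seeds -> connector;
  # C2 touches S1 and connector C1 only -> excluded;
  # X1 edge is syntenic -> excluded; X2 edge above FDR -> excluded
  expect_setequal(net$nodes$gene, c("S1", "S2", "C1"))
  expect_identical(net$nodes$role[net$nodes$gene == "C1"], "connector")
  expect_false("C2" %in% net$nodes$gene)
  expect_true(all(net$edges$fdr < 0.10))
  expect_false(any(net$edges$syntenic))

  # brute-force rule application over the toy
  seeds <- names(hits)[hits < 0.1]
  uni <- edges[edges$fdr < 0.1 & !edges$syntenic, ]
  conn <- character(0)
  for (g in setdiff(unique(c(uni$gene_a, uni$gene_b)), seeds)) {
    nb <- unique(c(uni$gene_b[uni$gene_a == g], uni$gene_a[uni$gene_b == g]))
    if (sum(nb %in% seeds) >= 2) conn <- c(conn, g)
  }
  expect_setequal(net$nodes$gene, c(seeds, conn))

  # no hits below the cutoff -> empty network
  empty <- build_coessential_network(edges, c(S1 = 0.5))
  expect_identical(nrow(empty$nodes), 0L)

  # monotone in the FDR cutoff
  strict <- build_coessential_network(edges, hits,
                                      analysis_config(coessential_fdr = 0.03))
  expect_true(all(strict$nodes$gene %in% net$nodes$gene))

  # missing synteny flags warn and default to non-syntenic
  expect_warning(build_coessential_network(edges[, 1:3], hits), "synteny")
})
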