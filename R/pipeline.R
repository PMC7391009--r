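#' Run the synthetic end-to-end pipeline from a config file
#'
#' Executes the requested analysis stages in dependency order on
#' synthetically generated inputs and writes each stage's outputs plus a run
#' manifest. The config is a JSON object with a `seed`, an `out_dir`, an
#' optional `config` block overriding [analysis_config()] defaults, and a
#' `stages` array drawn from `"spatial"`, `"lr"`, `"mibi"`, `"screen"`,
#' `"cnv"`. Re-running with the same config reproduces all numeric outputs
#' exactly.
#'
#' @param config_path path to the JSON config, or an equivalent list.
#' @return The run manifest (also written as `manifest.json` under
#'   `out_dir`): config snapshot, seeds, package version, per-stage output
#'   paths and wall times.
#' @export
run_pipeline <- function(config_path) {
  config <- if (is.character(config_path))
    jsonlite::read_json(config_path, simplifyVector = TRUE) else config_path
  known <- c("spatial", "lr", "mibi", "screen", "cnv")
  stages <- config$stages
  if (is.null(stages)) stages <- known
  unknown <- setdiff(stages, known)
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) tempfile("nichestat_run_") else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(analysis_config, c(as.list(config$config), list(seed = seed)))
  manifest <- list(
    config = config, seed = seed, package_version = "0.1.0",
    stages = list()
  )
  record <- function(name, paths, elapsed) {
    manifest$stages[[name]] <<- list(outputs = paths,
                                     wall_time_s = round(elapsed, 3))
    message(sprintf("[%s] done in %.2fs (seed %d)", name, elapsed, seed))
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  if ("spatial" %in% stages) {
    t0 <- proc.time()[3]
    lattice <- generate_st_lattice("ST", 1.5, 1.5)
    genes <- sprintf("g%03d", 1:60)
    prog <- list(list(domain_label = "tumor", genes = genes[1:10],
                      mean_shift = 1.5,
                      region = function(x, y) x < 600 & y < 600))
    sim <- simulate_spot_expression(lattice, prog, genes, seed = seed)
    adj <- adjacency_permutation_test(sim$lattice, n_perm = cfg$n_perm_spatial,
                                      seed = seed)
    expr <- log_normalize(sim$expression)
    graph <- build_spot_graph(sim$lattice)
    win <- sliding_window_average(expr, graph)
    corr <- spatial_gene_correlation(expr, win, anchor_gene = genes[1])
    paths <- c(tsv(adj$results, "spatial_adjacency.tsv"),
               tsv(corr, "spatial_correlation.tsv"))
    record("spatial", paths, proc.time()[3] - t0)
  }
  if ("lr" %in% stages) {
    t0 <- proc.time()[3]
    genes <- sprintf("g%03d", 1:40)
    truth <- data.frame(ligand = "g001", receptor = "g002",
                        sender = "tumor", receiver = "fibroblast", effect = 3)
    sim <- simulate_scrnaseq(c("tumor", "fibroblast", "tcell"), 150, genes,
                             lr_truth = truth, seed = seed)
    pairs <- data.frame(ligand = c("g001", "g005"),
                        receptor = c("g002", "g006"))
    lr <- lr_permutation_test(log_normalize(sim$expression), sim$annotations,
                              pairs, cfg, seed = seed)
    record("lr", tsv(lr$results, "lr_results.tsv"), proc.time()[3] - t0)
  }
  if ("mibi" %in% stages) {
    t0 <- proc.time()[3]
    cells <- simulate_mibi_fov(
      400, c(CD8 = 0.3, FOXP3 = 0.3, CD4 = 0.4),
      attraction_specs = list(list(type_a = "CD8", type_b = "FOXP3",
                                   attraction = 8, cluster_radius = 40)),
      tumor_blob = list(center = c(400, 400), radius = 250), seed = seed
    )
    norm <- normalize_markers(cells, cfg = cfg)
    coloc <- colocalization_test(norm$cells, "CD8", "FOXP3", cfg, seed = seed)
    labs <- classify_infiltration(cells, cfg)
    comp <- compartment_composition(labs$labels, cells)
    coloc_df <- do.call(rbind, lapply(coloc, function(r) {
      if (!is.null(r$skipped))
        data.frame(fov_id = r$fov_id, observed_median = NA, fdr = NA,
                   note = r$skipped)
      else data.frame(fov_id = r$fov_id, observed_median = r$observed_median,
                      fdr = r$permutation$p_value, note = "")
    }))
    paths <- c(tsv(coloc_df, "mibi_colocalization.tsv"),
               tsv(labs$labels, "mibi_compartments.tsv"),
               tsv(as.data.frame(comp$proportions), "mibi_composition.tsv"))
    record("mibi", paths, proc.time()[3] - t0)
  }
  if ("screen" %in% stages) {
    t0 <- proc.time()[3]
    eff <- data.frame(gene = "gene_001", arm = "in_vivo", log2fc = -2)
    sim <- simulate_screen(effect_genes = eff, seed = seed)
    fc <- guide_log2fc(depth_normalize(sim$screen, cfg), sim$screen, sim$meta, cfg)
    gl <- gene_log2fc(fc)
    fdr <- arm_difference_fdr(gl, fc$arm, cfg, seed = seed)
    record("screen", tsv(fdr, "screen_arm_fdr.tsv"), proc.time()[3] - t0)
  }
  if ("cnv" %in% stages) {
    t0 <- proc.time()[3]
    genes <- sprintf("g%03d", 1:80)
    caf <- genes[61:70]
    eff <- data.frame(gene = "g001", shift = 1)
    sim <- simulate_bulk_cohort(genes = genes, caf_genes = caf,
                                effect_genes = eff, seed = seed)
    scores <- module_score(t(sim$cohort$expression), gene_set("CAF", caf),
                           cfg, seed = seed)
    sig <- permutation_significance(sim$cohort, genes[1:10], scores$scores,
                                    cfg, seed = seed)
    record("cnv", tsv(sig, "cnv_effect.tsv"), proc.time()[3] - t0)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}
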