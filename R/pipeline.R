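#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage's defaults (HDplot
#' 0.55 / 7, MAC 2, 30\% missingness, 5000 diversity permutations, Pcrit sweep
#' 0 / 0.1 / 0.2 / 0.5, 999 spatial permutations, 1000 trees, distance classes
#' 10-300 km by 10, neighbourhood radius 220 km with min 20 members). Override
#' any entry via the \code{config} argument of \code{\link{run_pipeline}} or a
#' YAML file with the same structure. With \code{paper_scale = TRUE} the ABC
#' stage uses 5000 simulations per scenario and 1898 loci instead of the
#' desk-scale 500 / 300.
#'
#' @param paper_scale use the full ABC design (hours of CPU) instead of the
#'   desk-scale default
#' @return nested list of settings
#' @export
default_config <- function(paper_scale = FALSE) {
  list(
    input = list(vcf = NULL, metadata = NULL, distances = NULL),
    seed = 1L,
    filter = list(locus_missing = 0.30, individual_missing = 0.30,
                  min_mac = 2L, h_max = 0.55, d_max = 7),
    diversity = list(group_col = "era", n_perm = 5000L),
    ne = list(pcrit = c(0, 0.1, 0.2, 0.5), era = "contemporary"),
    structure = list(k_max = 10L),
    abc = list(enabled = FALSE,
               n_per_scenario = if (paper_scale) 5000L else 500L,
               n_estimation = if (paper_scale) 10000L else 1000L,
               n_loci = if (paper_scale) 1898L else 300L,
               n_trees = 1000L),
    spatial = list(class_start = 10, class_end = 300, class_step = 10,
                   n_perm = 999L, radius_km = 220, min_n = 20L),
    output = list(dir = "invadepop_run")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes filter, diversity, Ne, structure, spatial and (optionally) ABC
#' stages in dependency order from one configuration, writing per-stage TSV /
#' JSON outputs and a manifest recording seeds, settings and item counts in
#' and out of every filter. Stages whose output files already exist are
#' skipped when \code{resume = TRUE}; spatial stages are skipped with a notice
#' when no distance matrix is configured.
#'
#' @param config a nested list overriding \code{\link{default_config}}, or a
#'   path to a YAML file with the same structure
#' @param resume reuse existing stage outputs
#' @return (invisibly) list of stage results; files under the configured
#'   output directory
#' @export
run_pipeline <- function(config = list(), resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$input$vcf) || is.null(cfg$input$metadata))
    stop("config must provide input$vcf and input$metadata")
  out_dir <- cfg$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("invadepop")),
                   r_version = R.version.string,
                   seed = cfg$seed, config = cfg, stages = list())
  results <- list()
  stage_file <- function(name) file.path(out_dir, name)
  run_stage <- function(name, outputs, fun) {
    if (resume && all(file.exists(outputs))) {
      message("[", name, "] cached, skipping")
      manifest$stages[[name]] <<- list(status = "cached", outputs = outputs)
      return(invisible(NULL))
    }
    message("[", name, "] running")
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- c(list(status = "done", outputs = outputs),
                                  res$manifest)
    results[[name]] <<- res$value
    invisible(NULL)
  }

  g_raw <- read_vcf(cfg$input$vcf)
  md <- read_metadata(cfg$input$metadata)

  run_stage("filter", stage_file(c("filtered.vcf", "qc_report.tsv")), function() {
    g <- filter_cascade(g_raw, cfg$filter$locus_missing,
                        cfg$filter$individual_missing, cfg$filter$min_mac,
                        cfg$filter$h_max, cfg$filter$d_max)
    write_vcf(g, stage_file("filtered.vcf"))
    qc <- if (!is.null(g$ref_depth)) hdplot(g) else
      data.frame(snp_id = colnames(g$codes), maf = geno_maf(g),
                 missing_fraction = geno_missing_by_locus(g))
    write.table(qc, stage_file("qc_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(value = g, manifest = list(dims_in = dim(g_raw), dims_out = dim(g),
                                    cascade = attr(g, "cascade_log")))
  })
  g <- results$filter
  if (is.null(g)) g <- read_vcf(stage_file("filtered.vcf"))
  md <- md[match(rownames(g$codes), md$sample_id), ]
  groups <- md[[cfg$diversity$group_col]]

  run_stage("diversity", stage_file(c("diversity_population.tsv",
                                      "diversity_individual.tsv")), function() {
    dt <- diversity_table(g, groups)
    tests <- list()
    if (length(unique(groups)) == 2) {
      lev <- sort(unique(groups))
      h1 <- ho_hs_fis(g[groups == lev[1], ])$per_locus
      h2 <- ho_hs_fis(g[groups == lev[2], ])$per_locus
      common <- intersect(h1$snp_id, h2$snp_id)
      i1 <- match(common, h1$snp_id); i2 <- match(common, h2$snp_id)
      tests$wilcoxon_Ho <- paired_wilcoxon_by_locus(h1$Ho[i1], h2$Ho[i2])
      tests$wilcoxon_Hs <- paired_wilcoxon_by_locus(h1$Hs[i1], h2$Hs[i2])
      tests$perm_MLH <- permutation_mean_diff(dt$individual$MLH, groups,
                                              cfg$diversity$n_perm,
                                              seed = cfg$seed)
      tests$perm_IR <- permutation_mean_diff(dt$individual$IR, groups,
                                             cfg$diversity$n_perm,
                                             seed = cfg$seed + 1L)
      fst <- weir_cockerham_fst(g, groups, seed = cfg$seed + 2L)
      tests$fst <- fst[c("theta", "ci_low", "ci_high")]
    }
    write.table(dt$population, stage_file("diversity_population.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dt$individual, stage_file("diversity_individual.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(tests, stage_file("diversity_tests.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    list(value = c(dt, tests), manifest = list(groups = table(groups)))
  })

  run_stage("ne", stage_file("ne_ld.tsv"), function() {
    sub <- g[groups == cfg$ne$era, ]
    ne <- ne_ld_estimate(sub, cfg$ne$pcrit)
    write.table(ne, stage_file("ne_ld.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(value = ne,
         manifest = list(max_relative_spread = attr(ne, "max_relative_spread")))
  })

  run_stage("structure", stage_file(c("pca_scores.tsv", "clusters.tsv")), function() {
    pc <- geno_pca(g)
    scan <- kmeans_bic_scan(pc$scores, cfg$structure$k_max, seed = cfg$seed)
    write.table(data.frame(sample_id = rownames(pc$scores),
                           pc$scores[, seq_len(min(10, ncol(pc$scores)))]),
                stage_file("pca_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    k_use <- max(scan$best_k_diffNgroup, 2L)
    dp <- tryCatch(dapc(pc$scores, scan$assignments[[k_use]], n_pcs = "cv",
                        seed = cfg$seed),
                   error = function(e) NULL)
    write.table(data.frame(sample_id = rownames(pc$scores),
                           k_min = scan$assignments[[scan$best_k_min]],
                           k_diffNgroup = scan$assignments[[scan$best_k_diffNgroup]]),
                stage_file("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(value = list(pca = pc, scan = scan, dapc = dp),
         manifest = list(best_k_min = scan$best_k_min,
                         best_k_diffNgroup = scan$best_k_diffNgroup))
  })

  if (isTRUE(cfg$abc$enabled)) {
    run_stage("abc", stage_file("abc_results.json"), function() {
      obs <- summarize_dataset(list(genotypes = g, metadata = md))
      ref <- build_reference_table(n_per_scenario = cfg$abc$n_per_scenario,
                                   n_contemporary = sum(md$era == "contemporary"),
                                   n_historical = sum(md$era == "historical"),
                                   n_loci = cfg$abc$n_loci, seed = cfg$seed)
      ch_g <- scenario_choice(ref, obs, "group", cfg$abc$n_trees, cfg$seed)
      ch_s <- scenario_choice(ref, obs, "scenario", cfg$abc$n_trees, cfg$seed)
      # dedicated (larger) training set under the selected scenario, as is
      # standard for the parameter-estimation step
      est_ref <- build_reference_table(
        scenarios = default_scenarios()[paste0("s", ch_s$selected)],
        n_per_scenario = max(500L, cfg$abc$n_estimation),
        n_contemporary = sum(md$era == "contemporary"),
        n_historical = sum(md$era == "historical"),
        n_loci = cfg$abc$n_loci, seed = cfg$seed + 1L)
      est <- estimate_parameters(est_ref, obs,
                                 n_trees = cfg$abc$n_trees, seed = cfg$seed)
      res <- list(group = ch_g[c("votes", "selected", "posterior_probability",
                                 "prior_error_rate")],
                  scenario = ch_s[c("votes", "selected", "posterior_probability",
                                    "prior_error_rate")],
                  parameters = est)
      jsonlite::write_json(res, stage_file("abc_results.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      list(value = res, manifest = list(design = ref$design[
        c("n_per_scenario", "n_loci", "n_contemporary", "n_historical")]))
    })
  }

  has_dist <- !is.null(cfg$input$distances)
  if (!has_dist) {
    message("[spatial] no distance matrix configured: spatial stages skipped")
    manifest$stages$spatial <- list(status = "skipped",
                                    reason = "no distance matrix")
  } else {
    run_stage("spatial", stage_file(c("correlogram.tsv",
                                      "neighbourhood_diversity.tsv")), function() {
      d <- load_distances(cfg$input$distances, ids = rownames(g$codes))
      gd <- shared_allele_distance(g)
      cg <- mantel_correlogram(gd, d, cfg$spatial$class_start,
                               cfg$spatial$class_end, cfg$spatial$class_step,
                               cfg$spatial$n_perm, seed = cfg$seed)
      write.table(cg$classes, stage_file("correlogram.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      nb <- neighborhood_diversity(g, d, cfg$spatial$radius_km,
                                   cfg$spatial$min_n)
      write.table(nb, stage_file("neighbourhood_diversity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      proj <- nmds_project(d, seed = cfg$seed)
      sp <- spca(g, proj$coords, cfg$spatial$n_perm, seed = cfg$seed)
      mem <- mem_forward_selection(g, d, cfg$spatial$n_perm, seed = cfg$seed)
      decay <- list()
      if (all(c("dist_origin_km", "direction") %in% names(md))) {
        mm <- mlh(g)
        decay$MLH <- tryCatch(decay_regression(mm, md), error = function(e) NULL)
        decay$IR <- tryCatch(decay_regression(ir(g), md), error = function(e) NULL)
      }
      summary <- list(
        neighbourhood_size_km = cg$neighbourhood_size_km,
        spca_global = sp$global_test, spca_local = sp$local_test,
        mem_r2adj = mem$r2adj, mem_selected = mem$selected,
        nmds_stress = proj$stress,
        decay = lapply(decay, function(x) if (is.null(x)) NULL else
          list(terms = x$terms, adj_r2 = x$adj_r2,
               slopes = as.list(x$slopes_per_100km))))
      jsonlite::write_json(summary, stage_file("spatial_summary.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      list(value = list(correlogram = cg, neighbourhood = nb, spca = sp,
                        mem = mem, decay = decay),
           manifest = list(neighbourhood_size_km = cg$neighbourhood_size_km))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}
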