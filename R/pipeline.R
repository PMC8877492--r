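#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()]; any
#' element can be overridden through `...` (or by the YAML file passed to
#' [run_pipeline()]). Every stochastic stage derives its own seed
#' deterministically from the global `seed`, so a configuration fully
#' determines the result.
#'
#' @param ... overrides, e.g. `seed = 42`, `design = list(...)`,
#'   `n_permutations = 199`.
#' @return configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # either a synthetic design (list of synthetic_design() args) ...
    design = list(),
    # ... or explicit input paths
    table_path = NULL, metadata_path = NULL, tree_path = NULL,
    rarefaction_depth = "min",
    shannon_base = exp(1),
    unifrac_normalized = FALSE,
    n_permutations = 999,
    driver_variables = c("depth", "temperature", "salinity", "PO4",
                         "NO2NO3", "SiO2", "chl_gt20", "chl_2_20",
                         "chl_lt2", "HP_abundance", "PPE_abundance"),
    mlr_variables = c("temperature", "chl_lt2", "chl_2_20", "chl_gt20",
                      "PPE_abundance", "HP_abundance", "salinity",
                      "geographic"),
    taxa_level = 3,
    network = list(min_rel_abund = 1e-4, min_prevalence = 0.25,
                   rho_min = 0.6, alpha = 0.01, use_absolute = FALSE),
    enrichment_alpha = 0.05,
    attack = list(step = 1, max_fraction = 0.8, repetitions = 100),
    seed = 1
  )
  overrides <- list(...)
  utils::modifyList(cfg, overrides)
}

# deterministic per-stage seed derived from the global seed
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> rarefy -> alpha diversity -> beta diversity
#' and ANOSIM -> environmental drivers (Mantel screen, LMG decomposition,
#' taxon-environment screen) -> co-occurrence network (filter, Spearman +
#' BH, thresholded graph, enrichment classes, Louvain modules, node and
#' network metrics, habitat subnetworks) -> robustness (attack curves and
#' their comparison), all from one configuration and one global seed.
#' Identical configurations reproduce identical bundles.
#'
#' @param config a configuration from [pipeline_config()], a plain list of
#'   overrides, or the path of a YAML file with the same fields.
#' @return an object of class `results_bundle`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  seed <- cfg$seed
  log_counts <- list()

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$table_path)) {
    table <- read_zotu_table(cfg$table_path)
    metadata <- read_metadata(cfg$metadata_path)
    tree <- if (!is.null(cfg$tree_path)) read_newick(cfg$tree_path)
    truth <- NULL
  } else {
    design <- do.call(synthetic_design,
                      utils::modifyList(cfg$design,
                                        list(seed = stage_seed(seed, 0L))))
    sim <- simulate_community(design)
    table <- sim$table; metadata <- sim$metadata
    tree <- sim$tree; truth <- sim$truth
  }
  metadata <- metadata[match(sample_ids(table), metadata$sample_id), ,
                       drop = FALSE]
  habitat <- metadata$habitat
  log_counts$input <- c(samples = nrow(table$counts), zotus = ncol(table$counts))

  # --- rarefaction ----------------------------------------------------
  rarefied <- rarefy_table(table, depth = cfg$rarefaction_depth,
                           seed = stage_seed(seed, 101L))
  depth_used <- rowSums(rarefied$counts)[1]

  # --- alpha diversity ------------------------------------------------
  alpha <- alpha_diversity(rarefied, tree = tree, base = cfg$shannon_base)
  alpha_comparison <- compare_alpha(alpha, habitat)
  alpha_env <- alpha_env_spearman(alpha, metadata,
                                  variables = cfg$driver_variables)

  # --- beta diversity -------------------------------------------------
  d_bray <- bray_curtis(rarefied)
  d_wuf <- if (!is.null(tree)) {
    weighted_unifrac(rarefied, tree, normalized = cfg$unifrac_normalized)
  }
  pcoa_bray <- pcoa_ordination(d_bray)
  anosim_bray <- anosim_test(d_bray, habitat,
                             n_permutations = cfg$n_permutations,
                             seed = stage_seed(seed, 202L))
  pcoa_wuf <- if (!is.null(d_wuf)) pcoa_ordination(d_wuf)
  anosim_wuf <- if (!is.null(d_wuf)) {
    anosim_test(d_wuf, habitat, n_permutations = cfg$n_permutations,
                seed = stage_seed(seed, 203L))
  }

  # --- environmental drivers ------------------------------------------
  env <- env_distances(metadata, variables = cfg$driver_variables)
  mantel <- mantel_screen(d_bray, env, n_permutations = cfg$n_permutations,
                          seed = stage_seed(seed, 301L))
  mlr_vars <- intersect(cfg$mlr_variables, names(env$distances))
  lmg <- distance_mlr_lmg(d_bray, env, variables = mlr_vars,
                          seed = stage_seed(seed, 302L))
  taxa_env <- if (!is.null(rarefied$taxonomy)) {
    taxa_env_spearman(rarefied, level = cfg$taxa_level, metadata,
                      variables = cfg$driver_variables)
  }

  # --- co-occurrence network ------------------------------------------
  filtered <- filter_zotus(rarefied,
                           min_rel_abund = cfg$network$min_rel_abund,
                           min_prevalence = cfg$network$min_prevalence)
  sp <- spearman_matrix(filtered)
  q <- sp$p
  q[] <- NA_real_
  ut <- upper.tri(sp$p)
  q[ut] <- bh_adjust(sp$p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  network <- build_network(sp$rho, q,
                           rho_min = cfg$network$rho_min,
                           alpha = cfg$network$alpha,
                           use_absolute = cfg$network$use_absolute)
  enrichment <- classify_enrichment(filtered, habitat,
                                    alpha = cfg$enrichment_alpha)
  log_counts$network <- c(zotus_filtered = ncol(filtered$counts),
                          nodes = igraph::vcount(network),
                          edges = igraph::ecount(network))

  modules <- NULL; nodes <- NULL; net_metrics <- NULL
  subnets <- list(); subnet_metrics <- list()
  attacks <- list(); robustness <- NULL
  if (igraph::vcount(network) > 0) {
    modules <- detect_modules(network, seed = stage_seed(seed, 401L))
    nodes <- node_metrics(network)
    nodes$enrichment <- enrichment$class[match(nodes$node, enrichment$zotu_id)]
    nodes$module <- unname(modules$membership[nodes$node])
    igraph::V(network)$enrichment <- nodes$enrichment
    igraph::V(network)$module <- nodes$module
    net_metrics <- network_metrics(network)
    for (h in c("surface", "SCM")) {
      members <- enrichment$zotu_id[enrichment$class == h]
      members <- intersect(members, igraph::V(network)$name)
      if (length(members) >= 2) {
        subnets[[h]] <- subnetwork(network, members)
        subnet_metrics[[h]] <- network_metrics(subnets[[h]])
      }
    }
    for (h in names(subnets)) {
      if (igraph::vcount(subnets[[h]]) >= 3) {
        attacks[[h]] <- attack(subnets[[h]], strategy = "random",
                               step = cfg$attack$step,
                               max_fraction = cfg$attack$max_fraction,
                               repetitions = cfg$attack$repetitions,
                               seed = stage_seed(seed, 501L))
      }
    }
    if (all(c("surface", "SCM") %in% names(attacks))) {
      robustness <- compare_robustness(attacks$surface, attacks$SCM)
    }
  }

  # --- qualitative pattern flags --------------------------------------
  med <- function(metric, h) {
    stats::median(alpha[[metric]][habitat == h])
  }
  core <- intersect(c("richness", "shannon", "pd"), colnames(alpha))
  pat_alpha <- all(vapply(core, function(m) {
    row <- alpha_comparison[alpha_comparison$metric == m, ]
    row$p_value < 0.05 && med(m, "surface") > med(m, "SCM")
  }, logical(1)))
  pat_anosim <- anosim_bray$R > 0 && anosim_bray$p_value < 0.05
  pat_density <- length(subnet_metrics) == 2 &&
    subnet_metrics$surface$density > subnet_metrics$SCM$density &&
    subnet_metrics$surface$average_degree > subnet_metrics$SCM$average_degree
  pat_robust <- !is.null(robustness) && robustness$fraction_a_greater >= 0.9

  structure(list(
    config = cfg,
    metadata = metadata,
    truth = truth,
    rarefaction_depth = depth_used,
    alpha = alpha,
    alpha_comparison = alpha_comparison,
    alpha_env = alpha_env,
    distances = list(bray_curtis = d_bray, weighted_unifrac = d_wuf),
    pcoa = list(bray_curtis = pcoa_bray, weighted_unifrac = pcoa_wuf),
    anosim = list(bray_curtis = anosim_bray, weighted_unifrac = anosim_wuf),
    mantel = mantel,
    lmg = lmg,
    taxa_env = taxa_env,
    filtered_table = filtered,
    network = network,
    enrichment = enrichment,
    modules = modules,
    node_metrics = nodes,
    network_metrics = net_metrics,
    subnetworks = subnets,
    subnetwork_metrics = subnet_metrics,
    attack_curves = attacks,
    robustness = robustness,
    patterns = list(surface_alpha_higher = pat_alpha,
                    habitat_anosim_significant = pat_anosim,
                    surface_subnetwork_denser = pat_density,
                    surface_more_robust = pat_robust),
    provenance = list(
      seed = seed,
      stage_seeds = c(design = stage_seed(seed, 0L),
                      rarefy = stage_seed(seed, 101L),
                      anosim_bray = stage_seed(seed, 202L),
                      anosim_wunifrac = stage_seed(seed, 203L),
                      mantel = stage_seed(seed, 301L),
                      lmg = stage_seed(seed, 302L),
                      modules = stage_seed(seed, 401L),
                      attack = stage_seed(seed, 501L)),
      counts = log_counts,
      package_version = as.character(utils::packageVersion("haptonet")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    )
  ), class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Community analysis results bundle\n")
  cat(sprintf("  samples: %d | ZOTUs: %d (network stage: %d after filter)\n",
              nrow(x$metadata), x$provenance$counts$input[["zotus"]],
              x$provenance$counts$network[["zotus_filtered"]]))
  cat(sprintf("  rarefied to %d reads/sample\n", x$rarefaction_depth))
  cat(sprintf("  ANOSIM (Bray-Curtis): R = %.3f, p = %.3g\n",
              x$anosim$bray_curtis$R, x$anosim$bray_curtis$p_value))
  if (!is.null(x$anosim$weighted_unifrac)) {
    cat(sprintf("  ANOSIM (weighted UniFrac): R = %.3f, p = %.3g\n",
                x$anosim$weighted_unifrac$R, x$anosim$weighted_unifrac$p_value))
  }
  top <- x$mantel[which.max(x$mantel$r_squared), ]
  cat(sprintf("  top Mantel driver: %s (R^2 = %.3f, p = %.3g)\n",
              top$variable, top$r_squared, top$p_value))
  cat(sprintf("  LMG: total R^2 = %.3f; largest share %s (%.1f%%)\n",
              x$lmg$total_r_squared,
              names(which.max(x$lmg$contribution)),
              max(x$lmg$percent)))
  if (!is.null(x$network_metrics)) {
    cat(sprintf("  network: %d nodes, %d edges; modularity Q = %.3f\n",
                x$network_metrics$n_nodes, x$network_metrics$n_edges,
                x$modules$modularity))
  }
  en <- table(factor(x$enrichment$class, levels = c("surface", "SCM", "none")))
  cat(sprintf("  enriched ZOTUs: %d surface, %d SCM\n",
              en[["surface"]], en[["SCM"]]))
  cat("  pattern flags:",
      paste(names(x$patterns)[unlist(x$patterns)], collapse = ", "), "\n")
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Emits TSV/JSON/GraphML artifacts for every stage plus a manifest; the
#' layout mirrors the analysis surface (alpha table, distance matrices,
#' ordinations, ANOSIM/Mantel/LMG results, node metrics, module
#' assignment, attack curves).
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a named list of paths.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  w_tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  w_json <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[name]] <<- p
  }
  w_tsv(bundle$alpha, "alpha_diversity.tsv")
  w_tsv(bundle$alpha_comparison, "alpha_comparison.tsv")
  w_tsv(bundle$alpha_env, "alpha_env_spearman.tsv")
  write_distance_matrix(bundle$distances$bray_curtis,
                        file.path(dir, "bray_curtis.tsv"))
  paths[["bray_curtis.tsv"]] <- file.path(dir, "bray_curtis.tsv")
  if (!is.null(bundle$distances$weighted_unifrac)) {
    write_distance_matrix(bundle$distances$weighted_unifrac,
                          file.path(dir, "weighted_unifrac.tsv"))
    paths[["weighted_unifrac.tsv"]] <- file.path(dir, "weighted_unifrac.tsv")
  }
  co <- bundle$pcoa$bray_curtis$coordinates
  w_tsv(data.frame(sample_id = rownames(co), co), "pcoa_bray_curtis.tsv")
  w_json(list(
    bray_curtis = unclass(bundle$anosim$bray_curtis[c("R", "p_value", "n_permutations")]),
    weighted_unifrac = if (!is.null(bundle$anosim$weighted_unifrac)) {
      unclass(bundle$anosim$weighted_unifrac[c("R", "p_value", "n_permutations")])
    }), "anosim.json")
  w_tsv(bundle$mantel, "mantel.tsv")
  w_json(list(total_r_squared = bundle$lmg$total_r_squared,
              percent = as.list(bundle$lmg$percent)), "lmg.json")
  if (!is.null(bundle$taxa_env)) w_tsv(bundle$taxa_env, "taxa_env_spearman.tsv")
  w_tsv(bundle$enrichment, "enrichment.tsv")
  if (!is.null(bundle$node_metrics)) {
    w_tsv(bundle$node_metrics, "node_metrics.tsv")
    write_network(bundle$network, file.path(dir, "network.graphml"), "graphml")
    write_network(bundle$network, file.path(dir, "network.gml"), "gml")
    paths[["network.graphml"]] <- file.path(dir, "network.graphml")
    paths[["network.gml"]] <- file.path(dir, "network.gml")
    w_json(unclass(bundle$network_metrics), "network_metrics.json")
  }
  for (h in names(bundle$attack_curves)) {
    w_tsv(as.data.frame(bundle$attack_curves[[h]]),
          paste0("attack_", h, ".tsv"))
  }
  w_json(bundle$patterns, "patterns.json")
  w_json(bundle$provenance, "provenance.json")
  w_json(lapply(paths, basename), "manifest.json")
  invisible(paths)
}
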