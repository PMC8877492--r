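#' Describe a synthetic survey design
#'
#' Defines the ground-truth structure of a simulated two-layer (surface /
#' subsurface chlorophyll maximum) amplicon survey: how many stations and
#' ZOTUs, sequencing depth range, the strength of the planted habitat
#' contrast and temperature driver, and latent correlation blocks that
#' later appear as co-occurrence modules.
#'
#' The latent model is log-normal/multinomial: per-sample ZOTU
#' log-abundances are Gaussian (baseline + planted effects + noise) and
#' read counts are a single multinomial draw from their softmax, which
#' yields overdispersed compositional counts without extra parameters.
#'
#' @param n_stations number of stations; each contributes one surface and
#'   one SCM sample.
#' @param n_zotus number of ZOTUs in the pool.
#' @param depth_range integer pair: reads per sample are drawn uniformly
#'   within this closed interval.
#' @param habitat_effect non-negative log-scale contrast applied to each
#'   habitat's differential ZOTU set: `+habitat_effect * up_fraction` in
#'   its own habitat and `-habitat_effect * (1 - up_fraction)` in the
#'   other.
#' @param up_fraction how the contrast splits between enrichment in the
#'   home habitat and depletion in the other (default 0.2). A small value
#'   makes differential taxa moderately enriched where they belong but
#'   nearly absent elsewhere, which is what drives richness differences
#'   between layers without letting the enriched set monopolise reads.
#' @param temperature_effect non-negative strength of the temperature
#'   gradient: standardized temperature times a per-ZOTU loading is added
#'   to the latent log-abundances.
#' @param n_differential named pair `c(surface=, SCM=)`: sizes of the two
#'   differential ZOTU sets (surface set takes the lowest ids, SCM set the
#'   following ids). `NULL` scales the reference sizes (70 and 14 out of
#'   300) to `n_zotus`.
#' @param dominance named pair of multipliers on `habitat_effect` per
#'   habitat. The default gives the SCM-differential set a much weaker
#'   contrast than the surface set: surface specialists are strongly
#'   restricted (near-absent from the SCM), while SCM-enriched taxa are
#'   only moderately shifted — the asymmetry behind the higher surface
#'   richness and the tighter surface co-occurrence block typical of
#'   stratified water columns.
#' @param differential_baseline_shift named pair: additive log-scale
#'   offset on the baseline abundance of each habitat's differential set.
#'   The default places surface specialists in the rare tail, so their
#'   absence from the SCM changes richness without redistributing much
#'   read mass (which would otherwise make every common taxon look
#'   SCM-enriched through compositional closure).
#' @param module_spec list of blocks, each `list(habitat=, members=,
#'   rho=)` with `members` integer ZOTU ids and `rho` the within-block
#'   latent correlation in `[0, 1)`. Blocks must be disjoint within a
#'   habitat. `NULL` gives a default of one dense surface block (30
#'   members, rho 0.9) and one looser SCM block (the SCM-differential
#'   set, rho 0.55), truncated to fit small designs.
#' @param baseline_sd standard deviation of the per-ZOTU baseline
#'   log-abundance.
#' @param noise_sd named pair `c(surface=, SCM=)` of per-sample latent
#'   noise standard deviations (a scalar is recycled to both habitats).
#'   The default gives the SCM layer higher dispersion, which lowers its
#'   evenness (Shannon) and pushes more of its rare tail below detection
#'   — the planted counterpart of the lower SCM alpha diversity.
#' @param branch_mean mean of the exponential branch lengths used by
#'   [generate_tree()].
#' @param covariate_ranges nested list of per-habitat uniform ranges for
#'   the environmental covariates; see [default_covariate_ranges()].
#' @param seed integer seed; identical designs reproduce identical data.
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_stations = 14, n_zotus = 300,
                             depth_range = c(35677, 121493),
                             habitat_effect = 5, up_fraction = 0.2,
                             temperature_effect = 0.6,
                             n_differential = NULL,
                             dominance = c(surface = 1, SCM = 0.24),
                             differential_baseline_shift = c(surface = -2,
                                                             SCM = 0),
                             module_spec = NULL,
                             baseline_sd = 1.2, noise_sd = c(surface = 0.8, SCM = 1.25),
                             branch_mean = 0.1,
                             covariate_ranges = default_covariate_ranges(),
                             seed = 1) {
  stopifnot(n_stations >= 1, n_zotus >= 2, length(depth_range) == 2)
  depth_range <- as.integer(round(depth_range))
  if (depth_range[1] < 1 || depth_range[1] > depth_range[2]) {
    stop("depth_range must satisfy 1 <= lower <= upper", call. = FALSE)
  }
  if (habitat_effect < 0 || temperature_effect < 0) {
    stop("effect sizes must be non-negative", call. = FALSE)
  }
  if (up_fraction < 0 || up_fraction > 1) {
    stop("up_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(n_differential)) {
    n_differential <- c(surface = round(70 / 300 * n_zotus),
                        SCM = round(14 / 300 * n_zotus))
  }
  n_differential <- n_differential[c("surface", "SCM")]
  if (sum(n_differential) > n_zotus) {
    stop("differential sets exceed n_zotus", call. = FALSE)
  }
  diff_surface <- seq_len(n_differential[["surface"]])
  diff_scm <- seq_len(n_differential[["SCM"]]) + n_differential[["surface"]]
  if (is.null(module_spec)) {
    module_spec <- list(
      list(habitat = "surface", members = seq_len(min(30, length(diff_surface))),
           rho = 0.9),
      list(habitat = "SCM", members = diff_scm, rho = 0.55)
    )
    module_spec <- Filter(function(b) length(b$members) >= 2, module_spec)
  }
  for (b in module_spec) {
    if (!b$habitat %in% c("surface", "SCM")) stop("block habitat must be surface/SCM", call. = FALSE)
    if (b$rho < 0 || b$rho >= 1) stop("block rho must lie in [0, 1)", call. = FALSE)
    if (any(b$members < 1 | b$members > n_zotus)) {
      stop("block member id(s) outside 1..n_zotus", call. = FALSE)
    }
  }
  for (h in c("surface", "SCM")) {
    mem <- unlist(lapply(Filter(function(b) b$habitat == h, module_spec),
                         `[[`, "members"))
    if (anyDuplicated(mem)) {
      stop("module blocks overlap within habitat ", h, call. = FALSE)
    }
  }
  structure(list(
    n_stations = n_stations, n_zotus = n_zotus, depth_range = depth_range,
    habitat_effect = habitat_effect, up_fraction = up_fraction,
    temperature_effect = temperature_effect,
    differential = list(surface = diff_surface, SCM = diff_scm),
    dominance = dominance,
    differential_baseline_shift = differential_baseline_shift,
    module_spec = module_spec,
    baseline_sd = baseline_sd, noise_sd = noise_sd,
    branch_mean = branch_mean, covariate_ranges = covariate_ranges,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' Default covariate ranges for the synthetic survey
#'
#' Per-habitat uniform ranges for each environmental covariate: depth (m),
#' temperature (deg C), salinity, PO4 / NO2+NO3 / SiO2 / NH4 (uM),
#' size-fractionated chlorophyll a (ug/L) and heterotrophic-prokaryote /
#' pigmented-picoeukaryote abundances (cells/mL). SCM ranges follow the
#' hydrography of a stratified Arctic summer water column (SCM depth
#' 15-62 m, SCM temperature -1.58 to 2.96 deg C, salinity 30.7-32.4,
#' elevated nutrients at depth); surface ranges sit above/below these
#' accordingly.
#'
#' @return nested list `ranges[[variable]][[habitat]] = c(lo, hi)`.
#' @export
default_covariate_ranges <- function() {
  list(
    depth         = list(surface = c(2, 5),        SCM = c(15, 62)),
    temperature   = list(surface = c(-1.0, 8.0),   SCM = c(-1.58, 2.96)),
    salinity      = list(surface = c(27.5, 31.5),  SCM = c(30.7, 32.4)),
    PO4           = list(surface = c(0.1, 1.0),    SCM = c(0.71, 2.01)),
    NO2NO3        = list(surface = c(0.05, 2.0),   SCM = c(0.7, 8.22)),
    SiO2          = list(surface = c(1.0, 10.0),   SCM = c(2.55, 23.74)),
    NH4           = list(surface = c(0.01, 0.6),   SCM = c(0.01, 0.3)),
    chl_gt20      = list(surface = c(0.02, 1.5),   SCM = c(0.1, 4.0)),
    chl_2_20      = list(surface = c(0.02, 1.0),   SCM = c(0.05, 2.0)),
    chl_lt2       = list(surface = c(0.02, 0.8),   SCM = c(0.05, 1.5)),
    HP_abundance  = list(surface = c(2e5, 1.2e6),  SCM = c(1.28e5, 1.01e6)),
    PPE_abundance = list(surface = c(2.5e3, 9e4),  SCM = c(2.12e3, 7.89e4))
  )
}

#' Generate a random rooted tree over ZOTU leaves
#'
#' Random binary topology (sequential joins) with exponential branch
#' lengths; leaves are named `ZOTU_1..ZOTU_n`. Any rooted tree serves for
#' phylogenetic diversity and UniFrac testing; no attempt is made to mimic
#' real 18S phylogenies.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed; the Newick string is reproducible.
#' @param branch_mean mean exponential branch length.
#' @return a rooted [ape::phylo] tree with positive branch lengths.
#' @export
generate_tree <- function(n_leaves, seed = 1, branch_mean = 0.1) {
  if (n_leaves < 2) stop("n_leaves must be >= 2", call. = FALSE)
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE,
                     br = function(n) stats::rexp(n, rate = 1 / branch_mean))
  tree$tip.label <- sub("^t", "ZOTU_", tree$tip.label)
  tree
}

#' Generate sample metadata for a synthetic design
#'
#' One surface and one SCM sample per station. Station coordinates are
#' shared between layers; every covariate is drawn uniformly within its
#' per-habitat range, so the SCM depth always exceeds the surface depth
#' under the default ranges. Ammonium is set below detection (missing) in
#' most SCM samples, mirroring its typical behaviour at depth.
#'
#' @param design a [synthetic_design()].
#' @return a metadata `data.frame` with 2 x `n_stations` rows.
#' @export
generate_metadata <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed + 1L)
  ns <- design$n_stations
  station <- sprintf("St%02d", seq_len(ns))
  lat <- stats::runif(ns, 68, 78)
  lon <- stats::runif(ns, -170, -150)
  rows <- list()
  for (h in c("surface", "SCM")) {
    df <- data.frame(
      sample_id = paste0(station, ".", h), station = station, habitat = h,
      latitude = lat, longitude = lon, stringsAsFactors = FALSE
    )
    for (v in names(design$covariate_ranges)) {
      r <- design$covariate_ranges[[v]][[h]]
      df[[v]] <- stats::runif(ns, r[1], r[2])
    }
    rows[[h]] <- df
  }
  md <- rbind(rows$surface, rows$SCM)
  # NH4 below detection in most SCM samples: keep ~5 stations, blank the rest
  scm_rows <- which(md$habitat == "SCM")
  keep <- sample(scm_rows, size = min(5, length(scm_rows)))
  md$NH4[setdiff(scm_rows, keep)] <- NA
  rownames(md) <- NULL
  md
}

#' Generate a ZOTU count table with planted ground truth
#'
#' Latent log-abundances are `baseline + habitat contrast + temperature
#' gradient + block-correlated noise`; counts are one multinomial draw per
#' sample at a uniform random depth within `depth_range`. Block structure
#' is implemented through a shared latent factor per block with loading
#' `sqrt(rho)`, giving exactly `rho` latent correlation within blocks and
#' zero across.
#'
#' @param design a [synthetic_design()].
#' @param metadata metadata from [generate_metadata()] for the same design.
#' @return a list with elements `table` (a [zotu_table()]) and `truth`
#'   (class `ground_truth`: differential sets, planted module labels, the
#'   name of the true driver and the latent log-abundance matrix).
#' @export
generate_counts <- function(design, metadata) {
  stopifnot(inherits(design, "synthetic_design"))
  if (nrow(metadata) != 2 * design$n_stations) {
    stop("metadata does not match design (expected ",
         2 * design$n_stations, " samples)", call. = FALSE)
  }
  set.seed(design$seed + 2L)
  n <- nrow(metadata)
  p <- design$n_zotus
  zid <- paste0("ZOTU_", seq_len(p))

  base <- stats::rnorm(p, 0, design$baseline_sd)
  for (h in c("surface", "SCM")) {
    base[design$differential[[h]]] <- base[design$differential[[h]]] +
      design$differential_baseline_shift[[h]]
  }
  load <- stats::rnorm(p, 0, 1)
  z_temp <- as.numeric(scale(metadata$temperature))

  eta <- matrix(rep(base, each = n), nrow = n)
  # asymmetric habitat contrast: +e*up in the home habitat, -e*(1-up) away
  for (h in c("surface", "SCM")) {
    idx <- design$differential[[h]]
    if (!length(idx)) next
    e <- design$habitat_effect * design$dominance[[h]]
    shift <- ifelse(metadata$habitat == h,
                    e * design$up_fraction, -e * (1 - design$up_fraction))
    eta[, idx] <- eta[, idx] + matrix(rep(shift, length(idx)), nrow = n)
  }
  eta <- eta + design$temperature_effect * outer(z_temp, load)

  nsd <- design$noise_sd
  if (length(nsd) == 1) nsd <- c(surface = unname(nsd), SCM = unname(nsd))
  sample_sd <- unname(nsd[metadata$habitat])
  eps <- matrix(stats::rnorm(n * p), nrow = n) * sample_sd
  modules <- integer(0)
  for (b in seq_along(design$module_spec)) {
    blk <- design$module_spec[[b]]
    f <- stats::rnorm(n)
    eps[, blk$members] <- sample_sd *
      (sqrt(blk$rho) * matrix(rep(f, length(blk$members)), nrow = n) +
         sqrt(1 - blk$rho) *
           matrix(stats::rnorm(n * length(blk$members)), nrow = n))
    modules[as.character(blk$members)] <- b
  }
  eta <- eta + eps

  depths <- floor(stats::runif(n, design$depth_range[1], design$depth_range[2] + 1))
  depths <- pmin(depths, design$depth_range[2])
  counts <- matrix(0, n, p, dimnames = list(metadata$sample_id, zid))
  for (s in seq_len(n)) {
    pr <- exp(eta[s, ] - max(eta[s, ]))
    counts[s, ] <- stats::rmultinom(1, depths[s], pr / sum(pr))[, 1]
  }

  # toy taxonomy: random genus-level paths so rank aggregation is exercised
  genera <- c("Chrysochromulina", "Phaeocystis", "Prymnesium", "Haptolina",
              "Chrysochromulina_UC", "Phaeocystis_UC", "Prymnesium_UC",
              "Clade_D", "Clade_E", "Clade_B3", "Clade_HAP2", "Clade_HAP3")
  taxonomy <- paste("Haptophyta", "Prymnesiophyceae",
                    sample(genera, p, replace = TRUE), sep = ";")

  planted <- structure(modules,
                       names = zid[as.integer(names(modules))])
  truth <- structure(list(
    differential = lapply(design$differential, function(i) zid[i]),
    planted_modules = planted,
    true_driver = "temperature",
    latent = structure(eta, dimnames = dimnames(counts))
  ), class = "ground_truth")
  list(table = zotu_table(counts, taxonomy), truth = truth)
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper: metadata, counts with ground truth, and a rooted
#' tree over the full ZOTU pool, all derived from the design seed.
#'
#' @param design a [synthetic_design()].
#' @return list with `metadata`, `table`, `truth`, `tree`.
#' @export
simulate_community <- function(design) {
  metadata <- generate_metadata(design)
  cc <- generate_counts(design, metadata)
  tree <- generate_tree(design$n_zotus, seed = design$seed + 3L,
                        branch_mean = design$branch_mean)
  list(metadata = metadata, table = cc$table, truth = cc$truth, tree = tree)
}

#' Write a simulated survey to disk
#'
#' Emits the ZOTU table TSV, metadata TSV, Newick tree, and a ground-truth
#' JSON into `dir`.
#'
#' @param sim result of [simulate_community()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table = file.path(dir, "zotu_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_zotu_table(sim$table, paths["table"])
  write_metadata(sim$metadata, paths["metadata"])
  write_newick(sim$tree, paths["tree"])
  truth <- sim$truth
  truth$latent <- NULL
  truth$planted_modules <- as.list(truth$planted_modules)
  jsonlite::write_json(unclass(truth), paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
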