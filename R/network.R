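#' Prevalence/abundance filter for network construction
#'
#' A ZOTU is deleted only when it fails BOTH criteria: overall relative
#' abundance (pooled over the whole table) below `min_rel_abund` AND
#' present in fewer than `min_prevalence` of samples. Failing a single
#' criterion keeps the ZOTU — deletion requires the conjunction.
#'
#' @param table a [zotu_table()].
#' @param min_rel_abund overall relative-abundance threshold (default
#'   1e-4, i.e. 0.01%).
#' @param min_prevalence minimum fraction of samples with a nonzero count
#'   (default 0.25).
#' @return the filtered [zotu_table()].
#' @export
filter_zotus <- function(table, min_rel_abund = 1e-4, min_prevalence = 0.25) {
  counts <- table$counts
  rel <- colSums(counts) / sum(counts)
  prev <- colMeans(counts > 0)
  drop <- rel < min_rel_abund & prev < min_prevalence
  if (all(drop)) {
    stop("all ZOTUs deleted; relax min_rel_abund/min_prevalence", call. = FALSE)
  }
  subset_zotu_table(table, zotus = !drop)
}

#' Pairwise Spearman correlation matrix between ZOTUs
#'
#' Spearman rho (average ranks on ties) on per-sample relative abundances,
#' with two-sided p-values from the t approximation. Pairs involving a
#' zero-variance ZOTU are `NA` (not computed). The diagonal carries
#' `rho = 1` and `p = NA` so it is never fed into multiple-testing
#' correction.
#'
#' @param table a [zotu_table()] with >= 5 samples.
#' @return list with matrices `rho` and `p`.
#' @export
spearman_matrix <- function(table) {
  rel <- relative_abundance(table)
  n <- nrow(rel)
  if (n < 5) stop("need >= 5 samples for the correlation screen", call. = FALSE)
  sds <- apply(rel, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(rel, method = "spearman"))
  rho[sds == 0, ] <- NA
  rho[, sds == 0] <- NA
  p <- matrix(NA_real_, ncol(rel), ncol(rel), dimnames = dimnames(rho))
  finite <- !is.na(rho)
  t_stat <- rho[finite] * sqrt((n - 2) / pmax(1 - rho[finite]^2, 1e-300))
  p[finite] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  diag(rho) <- ifelse(sds > 0, 1, NA)
  diag(p) <- NA
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values: sort p ascending, `q_(i) = min_{j >= i} p_(j) m / j`
#' capped at 1, returned in the original input order (wrapper over
#' [stats::p.adjust()]). `NA`s are preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m number of tests (default `length(p)` excluding `NA`s).
#' @return q-values aligned with `p`.
#' @export
bh_adjust <- function(p, m = sum(!is.na(p))) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH", n = m)
}

#' Build the co-occurrence network from correlation screens
#'
#' An edge joins ZOTUs i and j when `q_ij < alpha` and `rho_ij >= rho_min`
#' (positive associations only, the default) or `|rho_ij| >= rho_min`
#' when `use_absolute = TRUE`. Isolated ZOTUs are dropped; node order
#' follows the correlation matrix, so construction is deterministic.
#' Edges carry `rho`, `q` and `sign` attributes.
#'
#' @param rho,q square matrices from [spearman_matrix()] +
#'   [bh_adjust()] (same dimnames).
#' @param rho_min correlation threshold (default 0.6).
#' @param alpha significance level on the adjusted q (default 0.01).
#' @param use_absolute admit strong negative correlations too?
#' @return an undirected simple [igraph::igraph] graph.
#' @export
build_network <- function(rho, q, rho_min = 0.6, alpha = 0.01,
                          use_absolute = FALSE) {
  if (!identical(dim(rho), dim(q))) stop("rho/q not conformable", call. = FALSE)
  strength <- if (use_absolute) abs(rho) else rho
  keep <- !is.na(strength) & !is.na(q) & strength >= rho_min & q < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ids <- colnames(rho)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(idx) == 0) return(g)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = rho[keep], q = q[keep],
                      sign = ifelse(rho[keep] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  nodes <- ids[sort(unique(c(idx[, 1], idx[, 2])))]
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Classify habitat-enriched ZOTUs
#'
#' Per-ZOTU two-sided Wilcoxon rank-sum test on relative abundances
#' between the two habitats, BH-adjusted across ZOTUs; a ZOTU is assigned
#' to the habitat with the larger mean relative abundance when its
#' q-value clears `alpha`, and `none` otherwise.
#'
#' @param table a [zotu_table()].
#' @param habitat habitat labels aligned with the table's samples.
#' @param alpha significance level on q (default 0.05).
#' @return data.frame of (zotu_id, p_value, q_value, class).
#' @export
classify_enrichment <- function(table, habitat, alpha = 0.05) {
  rel <- relative_abundance(table)
  habitat <- as.character(habitat)
  groups <- unique(habitat)
  if (length(groups) != 2) stop("need exactly two habitats", call. = FALSE)
  p <- apply(rel, 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x[habitat == groups[1]],
                                        x[habitat == groups[2]]))$p.value
  })
  q <- bh_adjust(p)
  m1 <- colMeans(rel[habitat == groups[1], , drop = FALSE])
  m2 <- colMeans(rel[habitat == groups[2], , drop = FALSE])
  cls <- ifelse(!is.na(q) & q < alpha,
                ifelse(m1 >= m2, groups[1], groups[2]), "none")
  data.frame(zotu_id = colnames(rel), p_value = p, q_value = q, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Louvain module detection
#'
#' Louvain community detection on the unweighted simple graph (edge
#' weights such as rho are ignored), seeded for reproducibility. Module
#' labels are renumbered by decreasing module size.
#'
#' @param network an [igraph::igraph] graph with >= 1 node.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
detect_modules <- function(network, resolution = 1.0, seed = 1) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(network, weights = NA, resolution = resolution)
  mem <- igraph::membership(cl)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  mem2 <- relabel[as.character(mem)]
  names(mem2) <- igraph::V(network)$name
  list(membership = mem2,
       modularity = igraph::modularity(network, mem))
}

#' Node-level topological metrics
#'
#' Degree; shortest-path betweenness normalized by `(N-1)(N-2)/2`; and
#' component-scaled closeness: within a node's connected component of
#' size `n_c`, closeness is `(n_c - 1) / sum(d)` further scaled by
#' `(n_c - 1)/(N - 1)` so values are comparable across components
#' (isolated nodes get 0).
#'
#' @param network an [igraph::igraph] graph.
#' @return data.frame of (node, degree, betweenness, closeness).
#' @export
node_metrics <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  N <- igraph::vcount(network)
  deg <- igraph::degree(network)
  btw <- if (N > 2) {
    igraph::betweenness(network, directed = FALSE, normalized = TRUE)
  } else rep(0, N)
  d <- igraph::distances(network)
  clo <- vapply(seq_len(N), function(i) {
    reach <- is.finite(d[i, ]) & seq_len(N) != i
    nc <- sum(reach) + 1
    if (nc < 2 || N < 2) return(0)
    ((nc - 1) / sum(d[i, reach])) * ((nc - 1) / (N - 1))
  }, numeric(1))
  data.frame(node = igraph::V(network)$name, degree = unname(deg),
             betweenness = unname(btw), closeness = clo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Network-level topological metrics
#'
#' Node/edge counts, average degree `2E/N`, density `2E/(N(N-1))`,
#' diameter and average path length over reachable pairs (per component),
#' average local clustering coefficient (nodes of degree < 2 contribute
#' 0), plus the same path statistics restricted to the largest component.
#'
#' @param network an [igraph::igraph] graph.
#' @return list of class `network_metrics`.
#' @export
network_metrics <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  N <- igraph::vcount(network)
  E <- igraph::ecount(network)
  local <- igraph::transitivity(network, type = "local", isolates = "zero")
  local[is.na(local)] <- 0
  d <- igraph::distances(network)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)]) & d[upper.tri(d)] > 0]
  comp <- igraph::components(network)
  big <- igraph::induced_subgraph(network,
                                  which(comp$membership == which.max(comp$csize)))
  db <- igraph::distances(big)
  fb <- db[upper.tri(db)][is.finite(db[upper.tri(db)]) & db[upper.tri(db)] > 0]
  structure(list(
    n_nodes = N, n_edges = E,
    average_degree = 2 * E / N,
    density = if (N > 1) 2 * E / (N * (N - 1)) else 0,
    diameter = if (length(finite)) max(finite) else 0,
    average_path_length = if (length(finite)) mean(finite) else 0,
    clustering_coefficient = mean(local),
    n_components = comp$no,
    largest_component = list(
      n_nodes = igraph::vcount(big),
      diameter = if (length(fb)) max(fb) else 0,
      average_path_length = if (length(fb)) mean(fb) else 0
    )
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("Network: %d nodes, %d edges | avg degree %.2f, ",
                     "density %.4f\n  diameter %g, avg path %.3f, ",
                     "clustering %.3f (%d component%s)\n"),
              x$n_nodes, x$n_edges, x$average_degree, x$density, x$diameter,
              x$average_path_length, x$clustering_coefficient,
              x$n_components, if (x$n_components == 1) "" else "s"))
  invisible(x)
}

#' Induced subnetwork
#'
#' @param network an [igraph::igraph] graph.
#' @param nodes node names to keep; must intersect the graph.
#' @return the induced subgraph (all edges among `nodes`).
#' @export
subnetwork <- function(network, nodes) {
  keep <- intersect(nodes, igraph::V(network)$name)
  if (!length(keep)) stop("node subset disjoint from network", call. = FALSE)
  igraph::induced_subgraph(network, keep)
}
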