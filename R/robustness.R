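#' Natural connectivity of a graph
#'
#' The natural connectivity is `ln((1/N) * sum_i exp(lambda_i))` over the
#' eigenvalues `lambda_i` of the simple, unweighted, undirected adjacency
#' matrix — the log of the average closed-walk generating function, a
#' spectral measure of how many redundant routes the network retains.
#' Computed with a max-shift (log-sum-exp) so large graphs do not
#' overflow.
#'
#' @param graph an [igraph::igraph] graph (or adjacency matrix) with at
#'   least one node. Isolated nodes count toward `N`.
#' @return a scalar; 0 for an edgeless graph.
#' @export
natural_connectivity <- function(graph) {
  a <- if (inherits(graph, "igraph")) {
    if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
    as.matrix(igraph::as_adjacency_matrix(graph, type = "both", sparse = TRUE))
  } else {
    as.matrix(graph)
  }
  if (nrow(a) == 0) stop("empty graph", call. = FALSE)
  a[a != 0] <- 1
  diag(a) <- 0
  lambda <- eigen((a + t(a)) / 2, symmetric = TRUE, only.values = TRUE)$values
  m <- max(lambda)
  m + log(sum(exp(lambda - m))) - log(length(lambda))
}

#' Node-removal attack simulation
#'
#' Removes nodes in a predetermined order fixed from the INTACT graph —
#' descending degree or betweenness with lexicographic node-name
#' tie-breaks — or uniformly at random, recomputing natural connectivity
#' after each removal batch. Nodes isolated by earlier removals stay in
#' the graph (and in `N`) until removed themselves. For the random
#' strategy the curve is the mean over seeded repetitions, with its
#' standard deviation.
#'
#' @param graph an [igraph::igraph] graph with >= 3 nodes.
#' @param strategy `"degree"`, `"betweenness"` or `"random"`.
#' @param step nodes removed per batch.
#' @param max_fraction largest fraction of nodes removed.
#' @param repetitions random-strategy repetitions.
#' @param seed integer seed (random strategy).
#' @param recompute if `TRUE`, re-rank remaining nodes after every batch
#'   instead of using the intact-graph order (sensitivity option).
#' @return object of class `attack_curve`: data.frame with columns
#'   `fraction_removed`, `n_removed`, `natural_connectivity` (mean for
#'   random) and `sd` (random only); attributes `strategy` and `seed`.
#' @export
attack <- function(graph, strategy = c("degree", "betweenness", "random"),
                   step = 1, max_fraction = 0.8, repetitions = 100, seed = 1,
                   recompute = FALSE) {
  strategy <- match.arg(strategy)
  N <- igraph::vcount(graph)
  if (N < 3) stop("attack needs >= 3 nodes", call. = FALSE)
  n_steps <- floor(max_fraction * N / step)
  removals <- seq(0, n_steps * step, by = step)

  curve_for_order <- function(order_names) {
    vapply(removals, function(k) {
      g <- if (k == 0) graph else
        igraph::delete_vertices(graph, order_names[seq_len(k)])
      natural_connectivity(g)
    }, numeric(1))
  }
  ranked_order <- function(g) {
    score <- if (strategy == "degree") igraph::degree(g) else
      igraph::betweenness(g, directed = FALSE)
    nm <- igraph::V(g)$name
    nm[order(-score, nm)]
  }

  if (strategy == "random") {
    set.seed(seed)
    mat <- vapply(seq_len(repetitions), function(r) {
      curve_for_order(sample(igraph::V(graph)$name))
    }, numeric(length(removals)))
    mat <- matrix(mat, nrow = length(removals))
    df <- data.frame(fraction_removed = removals / N, n_removed = removals,
                     natural_connectivity = rowMeans(mat),
                     sd = apply(mat, 1, stats::sd))
  } else if (!recompute) {
    df <- data.frame(fraction_removed = removals / N, n_removed = removals,
                     natural_connectivity = curve_for_order(ranked_order(graph)))
  } else {
    g <- graph
    nc <- natural_connectivity(g)
    for (k in removals[-1]) {
      victims <- ranked_order(g)[seq_len(min(step, igraph::vcount(g) - 1))]
      g <- igraph::delete_vertices(g, victims)
      nc <- c(nc, natural_connectivity(g))
    }
    df <- data.frame(fraction_removed = removals / N, n_removed = removals,
                     natural_connectivity = nc)
  }
  structure(df, class = c("attack_curve", "data.frame"),
            strategy = strategy, seed = seed)
}

#' Compare two attack curves
#'
#' Interpolates curve `b` onto curve `a`'s removal-fraction grid
#' (restricted to the overlapping fraction range) and reports the share
#' of grid points where `a` exceeds `b` plus the trapezoidal
#' area-under-curve difference `a - b`.
#'
#' @param curve_a,curve_b [attack()] results with the same strategy.
#' @return list with `fraction_a_greater`, `auc_difference`, `n_grid`.
#' @export
compare_robustness <- function(curve_a, curve_b) {
  if (!identical(attr(curve_a, "strategy"), attr(curve_b, "strategy"))) {
    stop("attack curves use different strategies", call. = FALSE)
  }
  hi <- min(max(curve_a$fraction_removed), max(curve_b$fraction_removed))
  grid <- curve_a$fraction_removed[curve_a$fraction_removed <= hi]
  ya <- curve_a$natural_connectivity[curve_a$fraction_removed <= hi]
  yb <- stats::approx(curve_b$fraction_removed, curve_b$natural_connectivity,
                      xout = grid, rule = 2)$y
  auc <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(
    fraction_a_greater = mean(ya > yb + 1e-12),
    auc_difference = if (length(grid) > 1) auc(grid, ya) - auc(grid, yb) else 0,
    n_grid = length(grid)
  )
}
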