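# shared fixtures and independent oracles used across test files

# small zotu table built by hand: counts is samples x zotus
toy_table <- function(counts, taxonomy = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("ZOTU_", seq_len(ncol(counts)))
  }
  zotu_table(counts, taxonomy)
}

# the 3-leaf reference tree used by the PD / UniFrac worked examples
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# all permutations of 1..n by lexicographic successor — written
# independently of the package's recursive enumerator
perms_lex <- function(n) {
  cur <- seq_len(n)
  out <- list(cur)
  repeat {
    i <- n - 1
    while (i >= 1 && cur[i] >= cur[i + 1]) i <- i - 1
    if (i < 1) break
    j <- n
    while (cur[j] <= cur[i]) j <- j - 1
    tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
    cur[(i + 1):n] <- rev(cur[(i + 1):n])
    out[[length(out) + 1]] <- cur
  }
  out
}

# Floyd-Warshall all-pairs hop distances on an adjacency matrix
fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# brute-force betweenness via shortest-path counting with adjacency powers
brute_betweenness <- function(a) {
  n <- nrow(a)
  d <- fw_distances(a)
  pows <- vector("list", n)
  pows[[1]] <- a
  for (k in seq_len(n - 1)) pows[[k + 1]] <- pows[[k]] %*% a
  sigma <- function(s, t) {
    if (s == t) return(1)
    if (!is.finite(d[s, t])) return(0)
    pows[[d[s, t]]][s, t]
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
        }
      }
    }
  }
  btw
}

# random simple graph as an igraph object plus its adjacency matrix
random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
  a <- a + t(a)
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  list(graph = igraph::graph_from_adjacency_matrix(a, mode = "undirected"),
       adj = a)
}

# small default design used by several tests (fast to simulate)
small_design <- function(seed = 1, ...) {
  synthetic_design(n_stations = 14, n_zotus = 80,
                   depth_range = c(2000, 5000),
                   n_differential = c(surface = 16, SCM = 6),
                   module_spec = list(
                     list(habitat = "surface", members = 1:10, rho = 0.9),
                     list(habitat = "SCM", members = 17:22, rho = 0.55)),
                   seed = seed, ...)
}
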