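test_that("the prevalence/abundance filter deletes only double failures", {
  # 10 samples, total 100000 reads; thresholds: <0.01% overall AND <25%
  # prevalence must BOTH hold for deletion
  n_s <- 10
  counts <- matrix(0, n_s, 5,
                   dimnames = list(paste0("S", 1:n_s), paste0("Z", 1:5)))
  counts[, 1] <- 9973            # abundant, everywhere -> kept
  counts[, 2] <- 10              # 0.1%, everywhere -> kept
  counts[1, 3] <- 20             # 0.02% but 10% prevalence -> kept (one fail)
  counts[1, 4] <- 5              # 0.005% and 10% prevalence -> deleted
  counts[2, 5] <- 2              # 0.002% and 10% prevalence -> deleted
  tb <- zotu_table(counts)
  kept <- zotu_ids(filter_zotus(tb))
  expect_setequal(kept, c("Z1", "Z2", "Z3"))

  # prevalence alone can rescue a rare ZOTU
  counts2 <- counts
  counts2[, 4] <- 1              # still ~0.001% but 100% prevalence -> kept
  kept2 <- zotu_ids(filter_zotus(zotu_table(counts2)))
  expect_true("Z4" %in% kept2)

  expect_error(filter_zotus(tb, min_rel_abund = 1, min_prevalence = 1.1),
               "relax")
})

test_that("Spearman matrix matches the rank formula and flags constants", {
  counts <- matrix(c(1, 2, 3, 4, 5,
                     2, 1, 4, 3, 5,
                     7, 7, 7, 7, 7), 5, 3,
                   dimnames = list(paste0("S", 1:5), c("Z1", "Z2", "Zc")))
  # make rows sum unequal so relative abundances are not all constant;
  # use equal totals so relative abundance preserves the planted ranks
  counts <- counts * 10
  counts[, 3] <- 100 - counts[, 1] - counts[, 2]
  tb <- zotu_table(counts)
  sp <- spearman_matrix(tb)
  expect_equal(sp$rho["Z1", "Z1"], 1)
  expect_equal(sp$rho["Z1", "Z2"], 0.8, tolerance = 1e-12)  # 1 - 6*4/120
  expect_true(is.na(sp$p["Z1", "Z1"]))

  const <- matrix(c(5, 5, 5, 5, 5,
                    1, 2, 3, 4, 5,
                    4, 3, 2, 1, 0), 5, 3,
                  dimnames = list(paste0("S", 1:5), c("Zc", "Za", "Zb")))
  # equal totals -> Zc's relative abundance is exactly constant
  spc <- spearman_matrix(zotu_table(const))
  expect_true(all(is.na(spc$rho["Zc", ])))
  expect_false(is.na(spc$rho["Za", "Zb"]))

  expect_error(spearman_matrix(toy_table(matrix(1:8, 4, 2))), ">= 5 samples")
})

test_that("BH adjustment equals independent step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- p[o] * m / seq_len(m)
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
  }
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
    # q never below raw p, monotone in p order
    expect_true(all(bh_adjust(p) >= p - 1e-12))
  }
})

test_that("network construction applies both thresholds and is monotone", {
  ids <- c("Z1", "Z2", "Z3")
  rho <- matrix(0.9, 3, 3, dimnames = list(ids, ids))
  q <- matrix(1e-6, 3, 3, dimnames = list(ids, ids))
  g <- build_network(rho, q)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::E(g)$sign, "+")

  q1 <- q; q1[] <- 1
  expect_equal(igraph::ecount(build_network(rho, q1)), 0)

  set.seed(23)
  n <- 15
  rr <- matrix(runif(n * n, -1, 1), n, n); rr <- (rr + t(rr)) / 2; diag(rr) <- 1
  qq <- matrix(runif(n * n), n, n); qq <- (qq + t(qq)) / 2
  dimnames(rr) <- dimnames(qq) <- list(paste0("Z", 1:n), paste0("Z", 1:n))
  base_edges <- igraph::ecount(build_network(rr, qq, rho_min = 0.3, alpha = 0.3))
  expect_lte(igraph::ecount(build_network(rr, qq, rho_min = 0.5, alpha = 0.3)),
             base_edges)
  expect_lte(igraph::ecount(build_network(rr, qq, rho_min = 0.3, alpha = 0.1)),
             base_edges)
  # absolute policy can only add edges relative to positive-only
  expect_gte(igraph::ecount(build_network(rr, qq, rho_min = 0.3, alpha = 0.3,
                                          use_absolute = TRUE)), base_edges)
})

test_that("enrichment classes follow habitat support", {
  set.seed(31)
  n <- 20
  habitat <- rep(c("surface", "SCM"), each = n / 2)
  counts <- matrix(rpois(n * 4, 30) + 1, n, 4,
                   dimnames = list(paste0("S", 1:n), paste0("Z", 1:4)))
  counts[habitat == "SCM", 1] <- 0          # surface-only, strongly
  counts[, 2] <- 40                          # fixed share once totals equal
  counts[, 4] <- 200 - rowSums(counts[, 1:3])  # equal totals -> no closure
  tb <- zotu_table(counts)
  cls <- classify_enrichment(tb, habitat)
  expect_equal(cls$class[cls$zotu_id == "Z1"], "surface")
  expect_equal(cls$class[cls$zotu_id == "Z2"], "none")
})

test_that("Louvain modules recover disjoint cliques deterministically", {
  k5a <- igraph::make_full_graph(5)
  k5b <- igraph::make_full_graph(5)
  g <- igraph::disjoint_union(k5a, k5b)
  igraph::V(g)$name <- paste0("Z", 1:10)
  mod <- detect_modules(g, seed = 1)
  expect_equal(length(unique(mod$membership)), 2)
  expect_equal(length(unique(mod$membership[1:5])), 1)
  expect_equal(length(unique(mod$membership[6:10])), 1)
  expect_gt(mod$modularity, 0.3)
  expect_identical(detect_modules(g, seed = 1)$membership, mod$membership)

  single <- igraph::make_full_graph(4)
  igraph::V(single)$name <- paste0("Z", 1:4)
  expect_equal(length(unique(detect_modules(single)$membership)), 1)
})

test_that("node metrics match closed forms on stars, cliques and dyads", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  nm <- node_metrics(star)
  expect_equal(nm$degree[nm$node == "hub"], 3)
  expect_equal(nm$betweenness[nm$node == "hub"], 1)   # all 3 leaf pairs
  expect_equal(nm$betweenness[nm$node == "l1"], 0)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("Z", 1:4)
  expect_true(all(node_metrics(k4)$betweenness == 0))
  expect_true(all(node_metrics(k4)$closeness == 1))

  # triangle plus a detached dyad: dyad closeness is scaled by (nc-1)/(N-1)
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("d", "e")), directed = FALSE)
  nm2 <- node_metrics(g)
  expect_equal(nm2$closeness[nm2$node == "d"], (1 / 1) * (1 / 4))
  expect_equal(nm2$closeness[nm2$node == "a"], (2 / 2) * (2 / 4))
})

test_that("network metrics match pair enumeration on K4, P4 and components", {
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- paste0("Z", 1:4)
  m <- network_metrics(k4)
  expect_equal(m$density, 1)
  expect_equal(m$average_degree, 3)
  expect_equal(m$clustering_coefficient, 1)
  expect_equal(m$diameter, 1)

  p4 <- igraph::make_ring(4, circular = FALSE)
  igraph::V(p4)$name <- paste0("Z", 1:4)
  mp <- network_metrics(p4)
  expect_equal(mp$diameter, 3)
  expect_equal(mp$average_path_length, 5 / 3, tolerance = 1e-12)

  tri_edge <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("d", "e")), directed = FALSE)
  expect_equal(network_metrics(tri_edge)$diameter, 1)  # reachable pairs only
  expect_equal(network_metrics(tri_edge)$n_components, 2)
})

test_that("node and network metrics agree with brute-force oracles", {
  for (seed in 1:6) {
    rg <- random_graph(n = sample(6:12, 1), p_edge = runif(1, 0.2, 0.6),
                       seed = seed)
    nm <- node_metrics(rg$graph)
    d <- fw_distances(rg$adj)
    n <- nrow(rg$adj)
    expect_equal(nm$degree, unname(rowSums(rg$adj)))
    expect_equal(nm$betweenness,
                 brute_betweenness(rg$adj) / ((n - 1) * (n - 2) / 2),
                 tolerance = 1e-10)
    clo <- sapply(seq_len(n), function(i) {
      reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
      if (!length(reach)) return(0)
      nc <- length(reach) + 1
      (nc - 1) / sum(d[i, reach]) * (nc - 1) / (n - 1)
    })
    expect_equal(nm$closeness, clo, tolerance = 1e-10)

    m <- network_metrics(rg$graph)
    finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)]) & d[upper.tri(d)] > 0]
    expect_equal(m$diameter, if (length(finite)) max(finite) else 0)
    expect_equal(m$average_path_length,
                 if (length(finite)) mean(finite) else 0, tolerance = 1e-12)
    # local clustering via triangle counting: diag(A^3)/2 per node
    tri <- diag(rg$adj %*% rg$adj %*% rg$adj) / 2
    deg <- rowSums(rg$adj)
    loc <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
    expect_equal(m$clustering_coefficient, mean(loc), tolerance = 1e-10)
  }
})

test_that("induced subnetworks preserve internal edges", {
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- paste0("Z", 1:4)
  sub <- subnetwork(k4, c("Z1", "Z2", "Z3"))
  expect_equal(igraph::vcount(sub), 3)
  expect_equal(igraph::ecount(sub), 3)
  all4 <- subnetwork(k4, paste0("Z", 1:4))
  expect_equal(igraph::ecount(all4), 6)
  expect_error(subnetwork(k4, c("nope")), "disjoint")
})
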