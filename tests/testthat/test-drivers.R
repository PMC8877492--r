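test_that("environmental distances are z-scored and haversine is exact", {
  md <- data.frame(sample_id = c("S1", "S2"), habitat = "surface",
                   temperature = c(0, 10),
                   latitude = c(0, 0), longitude = c(0, 90))
  env <- env_distances(md, variables = "temperature")
  expect_equal(as.vector(env$distances$temperature), sqrt(2), tolerance = 1e-5)
  # quarter great circle on the 6371 km sphere
  expect_equal(as.vector(env$distances$geographic), 6371 * pi / 2,
               tolerance = 1e-3)

  md2 <- data.frame(sample_id = c("S1", "S2"), habitat = "surface",
                    temperature = c(3, 3),
                    latitude = c(10, 10), longitude = c(20, 20))
  env2 <- env_distances(md2, variables = "temperature")
  expect_equal(env2$skipped, "temperature")
  expect_equal(as.vector(env2$distances$geographic), 0)
})

test_that("Mantel test equals 1 on self and matches vegan's statistic", {
  set.seed(3)
  d <- dist(matrix(rnorm(20), 10, 2))
  res <- mantel_test(d, d, n_permutations = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  e <- dist(matrix(rnorm(20), 10, 2))
  ours <- mantel_test(d, e, n_permutations = 9, seed = 1)
  ref <- vegan::mantel(d, e, permutations = 9)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)

  # symmetric in its two arguments
  expect_equal(mantel_test(e, d, n_permutations = 9)$r, ours$r,
               tolerance = 1e-12)
})

test_that("exhaustive Mantel equals enumeration over all 4! permutations", {
  set.seed(9)
  a <- as.matrix(dist(rnorm(4)))
  b <- as.matrix(dist(rnorm(4)))
  res <- mantel_test(as.dist(a), as.dist(b), permutations = "exhaustive")
  lt <- lower.tri(a)
  rs <- sapply(perms_lex(4), function(p) cor(a[lt], b[p, p][lt]))
  expect_equal(res$n_permutations, 24)
  expect_equal(res$p_value, mean(rs >= cor(a[lt], b[lt]) - 1e-12),
               tolerance = 1e-12)
})

test_that("LMG shares sum to R^2 and collapse to marginals when orthogonal", {
  # orthogonal predictor columns built by hand in unfolded space is not
  # possible through dist objects, so fabricate dist-shaped inputs directly
  n <- 5
  m <- n * (n - 1) / 2
  x1 <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  x2 <- c(1, 1, -1, -1, 1, 1, -1, -1, 1, 1)
  stopifnot(sum(x1 * x2) == 0, length(x1) == m)
  y <- 2 * x1 + 1 * x2 + c(0.1, -0.1, 0.05, -0.05, 0.2, -0.2, 0.1, -0.1, 0, 0)
  vec2dist <- function(v) {
    mm <- matrix(0, n, n, dimnames = list(paste0("S", 1:n), paste0("S", 1:n)))
    mm[lower.tri(mm)] <- v
    stats::as.dist(mm + t(mm))
  }
  env <- list(distances = list(p1 = vec2dist(x1), p2 = vec2dist(x2)))
  res <- distance_mlr_lmg(vec2dist(y), env)
  expect_equal(sum(res$contribution), res$total_r_squared, tolerance = 1e-10)
  r2_of <- function(x) summary(lm(y ~ x))$r.squared
  expect_equal(unname(res$contribution["p1"]), r2_of(x1), tolerance = 1e-10)
  expect_equal(unname(res$contribution["p2"]), r2_of(x2), tolerance = 1e-10)
})

test_that("LMG matches the 3!-ordering brute force on correlated predictors", {
  set.seed(4)
  n <- 8
  pts <- lapply(1:3, function(i) rnorm(n))
  ds <- lapply(pts, function(v) dist(v))
  y_d <- dist(pts[[1]] + 0.5 * pts[[2]] + rnorm(n, sd = 0.3))
  env <- list(distances = list(a = ds[[1]], b = ds[[2]], c = ds[[3]]))
  res <- distance_mlr_lmg(y_d, env)

  # oracle: average sequential R^2 gains over the 6 orderings using lm()
  lt <- lower.tri(as.matrix(y_d))
  y <- as.matrix(y_d)[lt]
  X <- sapply(ds, function(d) as.matrix(d)[lt])
  r2 <- function(cols) {
    if (!length(cols)) 0 else
      summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  contrib <- numeric(3)
  for (ord in perms_lex(3)) {
    prev <- 0
    for (i in 1:3) {
      cur <- r2(ord[1:i])
      contrib[ord[i]] <- contrib[ord[i]] + (cur - prev) / 6
      prev <- cur
    }
  }
  expect_equal(unname(res$contribution), contrib, tolerance = 1e-10)
  expect_equal(sum(res$contribution), res$total_r_squared, tolerance = 1e-10)
})

test_that("LMG flags rank-deficient designs and recovers a planted driver", {
  set.seed(6)
  v <- rnorm(8)
  env <- list(distances = list(a = dist(v), b = dist(2 * v)))
  expect_error(distance_mlr_lmg(dist(rnorm(8)), env), "rank deficient")

  md <- generate_metadata(synthetic_design(n_stations = 10, seed = 2))
  env2 <- env_distances(md, variables = c("temperature", "salinity", "PO4"))
  resp <- env2$distances$temperature
  res <- distance_mlr_lmg(resp, env2,
                          variables = c("temperature", "salinity", "PO4"))
  expect_gt(res$contribution[["temperature"]], 0.9 * res$total_r_squared)
})

test_that("taxon aggregation is additive and the screen flags constants", {
  counts <- matrix(c(10, 20, 30, 40,
                     10, 20, 30, 40,
                     80, 60, 40, 20), 4, 3,
                   dimnames = list(paste0("S", 1:4), c("Z1", "Z2", "Z3")))
  tb <- zotu_table(counts, taxonomy = c("K;GenA", "K;GenA", "K;GenB"))
  agg <- aggregate_taxa(tb, level = 2)
  expect_equal(unname(agg[, "GenA"]),
               unname(2 * counts[, 1] / rowSums(counts)))

  md <- data.frame(sample_id = paste0("S", 1:4), habitat = "surface",
                   depth = c(5, 10, 20, 30), flat = c(1, 1, 1, 1))
  res <- taxa_env_spearman(tb, level = 2, md, variables = c("depth", "flat"))
  expect_equal(res$rho[res$taxon == "GenA" & res$variable == "depth"], 1)
  expect_equal(res$rho[res$taxon == "GenB" & res$variable == "depth"], -1)
  expect_false(any(res$computed[res$variable == "flat"]))
  expect_true(all(is.na(res$rho[res$variable == "flat"])))

  expect_error(taxa_env_spearman(tb, level = 9, md), "level 9")

  const <- zotu_table(matrix(c(10, 10, 10, 10, 5, 6, 7, 8), 4, 2,
                             dimnames = list(paste0("S", 1:4), c("Z1", "Z2"))),
                      taxonomy = c("K;A", "K;B"))
  res2 <- taxa_env_spearman(const, 2, md, variables = "depth")
  # Z1 varies in relative abundance only through closure; a truly constant
  # taxon arises when composition is fixed
  expect_true(all(c("A", "B") %in% res2$taxon))
})

test_that("Mantel screen ranks a planted monotone driver first", {
  set.seed(10)
  n <- 20
  temp <- runif(n, -2, 8)
  md <- data.frame(sample_id = paste0("S", 1:n), habitat = "surface",
                   temperature = temp, salinity = runif(n, 28, 33),
                   PO4 = runif(n, 0.1, 2), SiO2 = runif(n, 1, 20),
                   depth = runif(n, 2, 60))
  env <- env_distances(md, variables = c("temperature", "salinity", "PO4",
                                         "SiO2", "depth"), geographic = FALSE)
  d_comm <- as.matrix(env$distances$temperature)
  d_comm <- d_comm + matrix(runif(n * n, 0, 0.1), n, n)
  d_comm <- (d_comm + t(d_comm)) / 2
  diag(d_comm) <- 0
  scr <- mantel_screen(stats::as.dist(d_comm), env, n_permutations = 99)
  expect_equal(scr$variable[1], "temperature")
  expect_gt(scr$r_squared[1], 0.9)
})
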