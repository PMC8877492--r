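#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on counts; lies in
#' `[0, 1]` for non-negative data. Computed with [vegan::vegdist()].
#'
#' @param table a [zotu_table()].
#' @return a [stats::dist] object labelled by sample id.
#' @export
bray_curtis <- function(table) {
  vegan::vegdist(table$counts, method = "bray")
}

#' Weighted UniFrac distance
#'
#' For each branch `b` of the rooted tree with length `l_b`, let `p_X(b)`
#' be the fraction of sample X's reads on leaves descending `b`. The raw
#' weighted UniFrac distance is `sum_b l_b |p_A(b) - p_B(b)|`; the
#' normalized form divides by `sum_b l_b (p_A(b) + p_B(b))`, bounding it
#' by 1. The raw form is the default; the study's variant is not
#' identifiable from its methods, so the choice is explicit here.
#'
#' @param table a [zotu_table()].
#' @param tree rooted [ape::phylo] tree containing every ZOTU with reads.
#' @param normalized divide by the branch-weighted total mass?
#' @return a [stats::dist] object.
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  counts <- table$counts
  present <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    stop("ZOTU(s) absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rel <- counts / rowSums(counts)
  n <- nrow(rel)
  prop <- branch_proportions(tree, rel)   # edges x samples
  len <- tree$edge.length
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      num <- sum(len * abs(prop[, i] - prop[, j]))
      if (normalized) {
        den <- sum(len * (prop[, i] + prop[, j]))
        d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
      } else {
        d[i, j] <- d[j, i] <- num
      }
    }
  }
  stats::as.dist(d)
}

# fraction of each sample's reads descending every edge of a rooted tree;
# returns an (edges x samples) matrix aligned with tree$edge
branch_proportions <- function(tree, rel) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # per-sample mass at each vertex, accumulated tips -> root (postorder)
  mass <- matrix(0, n_node, nrow(rel))
  idx <- match(tree$tip.label, colnames(rel))
  has <- !is.na(idx)
  mass[seq_len(n_tip)[has], ] <- t(rel[, idx[has], drop = FALSE])
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (k in seq_len(nrow(edge))) {
    mass[edge[k, 1], ] <- mass[edge[k, 1], ] + mass[edge[k, 2], ]
  }
  mass[tree$edge[, 2], , drop = FALSE]
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and keeps the axes with
#' positive eigenvalues (no Lingoes/Cailliez correction; the magnitude of
#' any negative eigenvalues is reported instead). Coordinates are
#' eigenvectors scaled by the square root of their eigenvalue; the sign of
#' each axis is fixed so its first nonzero loading is positive.
#'
#' @param dm a [stats::dist] or symmetric zero-diagonal matrix.
#' @param tol eigenvalues below `tol * max(eigenvalue)` are treated as
#'   null axes.
#' @return object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues`, `proportion_explained` (relative to the positive
#'   eigenvalue total), and `negative_mass` (sum of |negative
#'   eigenvalues|).
#' @export
pcoa_ordination <- function(dm, tol = 1e-9) {
  m <- as.matrix(dm)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(m)
  b <- -0.5 * m^2
  b <- sweep(b, 1, rowMeans(b))   # after both sweeps b is the doubly
  b <- sweep(b, 2, colMeans(b))   # centered Gower matrix -J D^2 J / 2
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  thr <- tol * max(abs(eig$values), 1e-300)
  pos <- which(eig$values > thr)
  vec <- eig$vectors[, pos, drop = FALSE]
  val <- eig$values[pos]
  coords <- sweep(vec, 2, sqrt(val), "*")
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- if (ncol(coords)) paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = val,
    proportion_explained = if (length(val)) val / sum(val) else numeric(0),
    negative_mass = sum(abs(pmin(eig$values, 0)))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", length(x$eigenvalues),
      "positive axes\n")
  if (length(x$eigenvalues)) {
    cat("  proportion explained (first axes):",
        paste(sprintf("%.3f", utils::head(x$proportion_explained, 4)),
              collapse = " "), "\n")
  }
  if (x$negative_mass > 0) {
    cat("  |negative eigenvalue| mass:", format(x$negative_mass), "\n")
  }
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise dissimilarities (average ranks on ties) and
#' computes `R = (mean rank between - mean rank within) / (n(n-1)/4)`.
#' Significance is assessed by permuting group labels: either
#' `n_permutations` seeded random permutations with the
#' `(1 + count) / (1 + N)` estimator, or exhaustive enumeration of all
#' distinct label arrangements (`permutations = "exhaustive"`), where the
#' p-value is the exact null probability `#\{R* >= R\} / #arrangements`.
#'
#' @param dm a [stats::dist] over samples.
#' @param groups group labels aligned with the dist labels; every group
#'   needs >= 2 members.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the random permutations.
#' @param permutations `"random"` or `"exhaustive"`.
#' @return object of class `anosim_result`: `R`, `p_value`,
#'   `n_permutations`, `permuted_R`.
#' @export
anosim_test <- function(dm, groups, n_permutations = 999, seed = 1,
                        permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2 || min(table(groups)) < 2) {
    stop("ANOSIM needs >= 2 groups with >= 2 members each", call. = FALSE)
  }
  m <- as.matrix(dm)
  n <- nrow(m)
  if (length(groups) != n) stop("groups length must match dist size", call. = FALSE)
  lower <- lower.tri(m)
  rk <- matrix(0, n, n)
  rk[lower] <- rank(m[lower])
  rk <- rk + t(rk)
  denom <- n * (n - 1) / 4

  r_stat <- function(g) {
    same <- outer(g, g, "==")
    (mean(rk[lower][!same[lower]]) - mean(rk[lower][same[lower]])) / denom
  }
  observed <- r_stat(groups)

  if (permutations == "exhaustive") {
    perms <- unique_label_arrangements(groups)
    permuted <- vapply(perms, r_stat, numeric(1))
    p <- mean(permuted >= observed - 1e-12)
    np <- length(perms)
  } else {
    set.seed(seed)
    permuted <- vapply(seq_len(n_permutations),
                       function(i) r_stat(sample(groups)), numeric(1))
    p <- (1 + sum(permuted >= observed - 1e-12)) / (1 + n_permutations)
    np <- n_permutations
  }
  structure(list(R = observed, p_value = p, n_permutations = np,
                 permuted_R = permuted), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}

# all distinct arrangements of a label vector (identity included)
unique_label_arrangements <- function(groups) {
  n <- length(groups)
  perms <- all_permutations(n)
  arr <- unique(lapply(perms, function(p) groups[p]))
  arr
}

# all permutations of 1..n (n <= 8 intended)
all_permutations <- function(n) {
  if (n > 9) stop("exhaustive enumeration limited to n <= 9", call. = FALSE)
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(s, n, after = pos - 1)
    }
  }
  out
}
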