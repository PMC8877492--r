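#' Rarefy a ZOTU table to even depth
#'
#' Subsamples each sample's reads to exactly `depth` without replacement
#' (one seeded draw per table, not an average over repetitions). ZOTU
#' columns that end up all-zero are retained so ids stay aligned with the
#' tree and taxonomy.
#'
#' @param table a [zotu_table()].
#' @param depth target reads per sample; must not exceed any sample total.
#'   `"min"` uses the smallest sample total.
#' @param seed integer seed.
#' @return a rarefied [zotu_table()] with every row sum equal to `depth`.
#' @export
rarefy_table <- function(table, depth = "min", seed = 1) {
  totals <- rowSums(table$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(round(depth))
  if (any(totals < depth)) {
    stop("rarefaction depth ", depth, " exceeds total reads of sample(s): ",
         paste(names(totals)[totals < depth], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # pre-scaled data); our inputs are validated integer counts, so mute it
  out <- withCallingHandlers(
    vegan::rrarefy(table$counts, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  zotu_table(out, table$taxonomy)
}

#' Per-sample alpha diversity
#'
#' Richness (ZOTUs with count > 0), Shannon entropy on relative abundances
#' and, if a rooted tree is supplied, Faith's phylogenetic diversity (sum
#' of branch lengths of the minimal subtree connecting the sample's ZOTUs
#' to the root, stem included).
#'
#' @param table a [zotu_table()].
#' @param tree optional rooted [ape::phylo] tree whose leaves include
#'   every ZOTU present in the table.
#' @param base logarithm base for Shannon; default `exp(1)` (nats).
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   and `pd` when a tree is given.
#' @export
alpha_diversity <- function(table, tree = NULL, base = exp(1)) {
  counts <- table$counts
  out <- data.frame(
    sample_id = rownames(counts),
    richness = rowSums(counts > 0),
    shannon = vegan::diversity(counts, index = "shannon", base = base),
    stringsAsFactors = FALSE
  )
  if (!is.null(tree)) {
    present <- colnames(counts)[colSums(counts) > 0]
    missing <- setdiff(present, tree$tip.label)
    if (length(missing)) {
      stop("ZOTU(s) absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    common <- intersect(colnames(counts), tree$tip.label)
    pruned <- if (length(common) < length(tree$tip.label)) {
      ape::keep.tip(tree, common)
    } else tree
    pd <- picante::pd(counts[, common, drop = FALSE], pruned,
                      include.root = TRUE)
    out$pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  rownames(out) <- NULL
  out
}

#' Compare alpha diversity between habitats
#'
#' Two-sided Wilcoxon rank-sum test per metric (exact when group sizes
#' permit and there are no ties, normal approximation with tie correction
#' otherwise), or the paired signed-rank variant with samples paired by
#' station.
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param habitat character vector of group labels aligned with
#'   `alpha$sample_id` (typically `metadata$habitat`).
#' @param paired if `TRUE`, use the signed-rank test pairing by `station`.
#' @param station station labels, required when `paired = TRUE`.
#' @param metrics which columns of `alpha` to test.
#' @return data.frame with one row per metric: statistic, p-value and the
#'   per-group medians.
#' @export
compare_alpha <- function(alpha, habitat, paired = FALSE, station = NULL,
                          metrics = setdiff(colnames(alpha), c("sample_id"))) {
  habitat <- as.character(habitat)
  groups <- unique(habitat)
  if (length(groups) != 2 || min(table(habitat)) < 2) {
    stop("need exactly two groups with >= 2 samples each", call. = FALSE)
  }
  res <- lapply(metrics, function(m) {
    x <- alpha[[m]][habitat == groups[1]]
    y <- alpha[[m]][habitat == groups[2]]
    if (paired) {
      if (is.null(station)) stop("paired test needs station labels", call. = FALSE)
      s1 <- station[habitat == groups[1]]
      s2 <- station[habitat == groups[2]]
      y <- y[match(s1, s2)]
      ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y))
    }
    data.frame(metric = m, statistic = unname(ht$statistic),
               p_value = ht$p.value,
               median_1 = stats::median(x), median_2 = stats::median(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  colnames(out)[4:5] <- paste0("median_", groups)
  out
}

#' Spearman correlations between alpha diversity and covariates
#'
#' Pairwise-complete Spearman rank correlation of each diversity metric
#' against each environmental covariate; the two-sided p-value uses the
#' t approximation. Pairs with fewer than 4 complete observations are
#' flagged as not computed (`NA` with `computed = FALSE`).
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param metadata metadata data.frame (matched on `sample_id`).
#' @param variables covariate column names to test.
#' @param metrics diversity columns to test.
#' @return data.frame of (metric, variable, n, rho, p_value, computed).
#' @export
alpha_env_spearman <- function(alpha, metadata,
                               variables = setdiff(colnames(metadata),
                                                   c("sample_id", "station", "habitat")),
                               metrics = setdiff(colnames(alpha), "sample_id")) {
  md <- metadata[match(alpha$sample_id, metadata$sample_id), , drop = FALSE]
  grid <- expand.grid(metric = metrics, variable = variables,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- alpha[[grid$metric[i]]]
    y <- md[[grid$variable[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      return(data.frame(grid[i, ], n = sum(ok), rho = NA_real_,
                        p_value = NA_real_, computed = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(grid[i, ], n = sum(ok), rho = unname(ct$estimate),
               p_value = spearman_p(unname(ct$estimate), sum(ok)),
               computed = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# two-sided p for Spearman rho via the t approximation on n - 2 df
spearman_p <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}
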