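#' Environmental distance matrices
#'
#' Each covariate is z-scored over its non-missing samples (mean 0, sd 1,
#' n-1 denominator) and turned into the pairwise distance `|z_i - z_j|`;
#' pairs involving a missing value are `NA`. If coordinates are present a
#' great-circle (haversine, 6371 km sphere) distance matrix in km is
#' added under `"geographic"`. Constant covariates (sd 0) cannot be
#' normalized and are reported in `skipped` instead.
#'
#' @param metadata metadata data.frame with `sample_id`.
#' @param variables covariate columns to convert.
#' @param geographic add a great-circle distance matrix from
#'   `latitude`/`longitude`?
#' @return list with `distances` (named list of [stats::dist], each
#'   carrying a `missing` attribute naming samples without a value) and
#'   `skipped` (character).
#' @export
env_distances <- function(metadata,
                          variables = c("depth", "temperature", "salinity",
                                        "PO4", "NO2NO3", "SiO2",
                                        "chl_gt20", "chl_2_20", "chl_lt2",
                                        "HP_abundance", "PPE_abundance"),
                          geographic = TRUE) {
  variables <- intersect(variables, colnames(metadata))
  if (!length(variables) && !geographic) stop("no variables found", call. = FALSE)
  ids <- metadata$sample_id
  out <- list()
  skipped <- character(0)
  for (v in variables) {
    x <- metadata[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0) {
      skipped <- c(skipped, v)
      next
    }
    z <- rep(NA_real_, length(x))
    z[ok] <- (x[ok] - mean(x[ok])) / stats::sd(x[ok])
    d <- abs(outer(z, z, "-"))
    dimnames(d) <- list(ids, ids)
    dd <- stats::as.dist(d)
    attr(dd, "missing") <- ids[!ok]
    out[[v]] <- dd
  }
  if (geographic && all(c("latitude", "longitude") %in% colnames(metadata))) {
    xy <- cbind(metadata$longitude, metadata$latitude)
    g <- geosphere::distm(xy, fun = function(a, b) {
      geosphere::distHaversine(a, b, r = 6371000)
    }) / 1000
    dimnames(g) <- list(ids, ids)
    gg <- stats::as.dist(g)
    attr(gg, "missing") <- character(0)
    out[["geographic"]] <- gg
  }
  list(distances = out, skipped = skipped)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation `r` of the lower-triangle vectors; significance by
#' jointly permuting rows and columns of the second matrix, one-sided for
#' positive association. Random mode uses the `(1 + count)/(1 + N)`
#' estimator; `permutations = "exhaustive"` enumerates all `n!` sample
#' permutations (identity included) and returns the exact null
#' probability. `r_squared` is reported alongside `r` because driver
#' tables in this literature print R^2.
#'
#' @param d_community,d_env [stats::dist] objects with identical labels in
#'   identical order; no missing entries.
#' @param n_permutations random permutation count.
#' @param seed integer seed.
#' @param permutations `"random"` or `"exhaustive"` (n <= 9).
#' @return object of class `mantel_result`: `r`, `r_squared`, `p_value`,
#'   `n_permutations`.
#' @export
mantel_test <- function(d_community, d_env, n_permutations = 999, seed = 1,
                        permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  a <- as.matrix(d_community)
  b <- as.matrix(d_env)
  if (!identical(dim(a), dim(b)) ||
      (!is.null(rownames(a)) && !is.null(rownames(b)) &&
       !identical(rownames(a), rownames(b)))) {
    stop("distance matrices must share labels in the same order", call. = FALSE)
  }
  n <- nrow(a)
  if (n < 4) stop("Mantel test needs >= 4 samples", call. = FALSE)
  lower <- lower.tri(a)
  va <- a[lower]
  if (any(is.na(va)) || any(is.na(b[lower]))) {
    stop("missing entries; subset to complete samples first", call. = FALSE)
  }
  r_of <- function(p) stats::cor(va, b[p, p][lower])
  observed <- r_of(seq_len(n))
  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    permuted <- vapply(perms, r_of, numeric(1))
    p <- mean(permuted >= observed - 1e-12)
    np <- length(perms)
  } else {
    set.seed(seed)
    permuted <- vapply(seq_len(n_permutations),
                       function(i) r_of(sample.int(n)), numeric(1))
    p <- (1 + sum(permuted >= observed - 1e-12)) / (1 + n_permutations)
    np <- n_permutations
  }
  structure(list(r = observed, r_squared = observed^2, p_value = p,
                 n_permutations = np), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f (R^2 = %.4f), p = %.4g (%d permutations)\n",
              x$r, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Mantel screen of candidate environmental drivers
#'
#' Runs [mantel_test()] of the community distance matrix against every
#' environmental distance matrix, subsetting both to the samples with a
#' value for that covariate (so below-detection covariates are handled
#' pairwise-complete, per sample).
#'
#' @param d_community community [stats::dist].
#' @param env result of [env_distances()].
#' @param n_permutations,seed passed to [mantel_test()].
#' @return data.frame of (variable, n, r, r_squared, p_value) sorted by
#'   decreasing `r_squared`, mirroring the driver tables of this
#'   literature.
#' @export
mantel_screen <- function(d_community, env, n_permutations = 999, seed = 1) {
  cm <- as.matrix(d_community)
  rows <- lapply(names(env$distances), function(v) {
    dv <- env$distances[[v]]
    keep <- setdiff(rownames(cm), attr(dv, "missing"))
    if (length(keep) < 4) {
      return(data.frame(variable = v, n = length(keep), r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_))
    }
    sub_c <- stats::as.dist(cm[keep, keep])
    sub_e <- stats::as.dist(as.matrix(dv)[keep, keep])
    mt <- mantel_test(sub_c, sub_e, n_permutations = n_permutations, seed = seed)
    data.frame(variable = v, n = length(keep), r = mt$r,
               r_squared = mt$r_squared, p_value = mt$p_value)
  })
  out <- do.call(rbind, rows)
  out[order(-out$r_squared), , drop = FALSE]
}

#' Distance-based regression with LMG variance decomposition
#'
#' Ordinary least squares of the unfolded community dissimilarities on the
#' unfolded environmental distance vectors (with intercept), followed by
#' the LMG decomposition: each predictor's share is its sequential R^2
#' gain averaged over all orderings of the predictors. Shares always sum
#' to the full-model R^2. Orderings are enumerated exhaustively for up to
#' 8 predictors and sampled (seeded) beyond that.
#'
#' @param d_community community [stats::dist].
#' @param env result of [env_distances()] (or a named list of dist under
#'   `$distances`).
#' @param variables predictors to use; default all non-skipped ones.
#' @param max_exhaustive largest predictor count decomposed by exhaustive
#'   enumeration.
#' @param n_orderings sampled orderings when beyond `max_exhaustive`.
#' @param seed seed for sampled orderings.
#' @return object of class `lmg_decomposition`: `total_r_squared`,
#'   `contribution` (named, sums to the total), `percent` (same on the
#'   cumulative % scale), `n_pairs`.
#' @export
distance_mlr_lmg <- function(d_community, env, variables = NULL,
                             max_exhaustive = 8, n_orderings = 5000, seed = 1) {
  dl <- if (!is.null(env$distances)) env$distances else env
  if (is.null(variables)) variables <- names(dl)
  if (length(variables) < 2) stop("need >= 2 predictors", call. = FALSE)
  absent <- setdiff(variables, names(dl))
  if (length(absent)) {
    stop("no distance matrix for: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  cm <- as.matrix(d_community)
  lower <- lower.tri(cm)
  y <- cm[lower]
  X <- sapply(variables, function(v) as.matrix(dl[[v]])[lower])
  ok <- stats::complete.cases(cbind(y, X))
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  p <- ncol(X)
  if (qr(cbind(1, X))$rank < p + 1) {
    cc <- stats::cor(X)
    pair <- which(abs(cc) > 1 - 1e-8 & row(cc) < col(cc), arr.ind = TRUE)
    hint <- if (nrow(pair)) {
      paste0(" (collinear: ", variables[pair[1, 1]], " ~ ",
             variables[pair[1, 2]], ")")
    } else ""
    stop("design matrix is rank deficient", hint, call. = FALSE)
  }

  # R^2 of the OLS fit on a subset of predictors
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }

  if (p <= max_exhaustive) {
    # cache subset R^2, then weight increments by s!(p-1-s)!/p!
    keys <- function(cols) {
      if (!length(cols)) "<none>" else paste(sort(cols), collapse = ",")
    }
    cache <- new.env(parent = emptyenv())
    subset_r2 <- function(cols) {
      k <- keys(cols)
      if (is.null(cache[[k]])) cache[[k]] <- r2(cols)
      cache[[k]]
    }
    contribution <- numeric(p)
    for (k in seq_len(p)) {
      others <- setdiff(seq_len(p), k)
      for (s in 0:length(others)) {
        subs <- if (s == 0) list(integer(0)) else
          utils::combn(others, s, simplify = FALSE)
        w <- factorial(s) * factorial(p - 1 - s) / factorial(p)
        for (S in subs) {
          contribution[k] <- contribution[k] +
            w * (subset_r2(c(S, k)) - subset_r2(S))
        }
      }
    }
  } else {
    set.seed(seed)
    contribution <- numeric(p)
    for (o in seq_len(n_orderings)) {
      ord <- sample.int(p)
      prev <- 0
      for (i in seq_len(p)) {
        cur <- r2(ord[seq_len(i)])
        contribution[ord[i]] <- contribution[ord[i]] + (cur - prev)
        prev <- cur
      }
    }
    contribution <- contribution / n_orderings
  }
  names(contribution) <- variables
  structure(list(
    total_r_squared = r2(seq_len(p)),
    contribution = contribution,
    percent = 100 * contribution,
    n_pairs = length(y)
  ), class = "lmg_decomposition")
}

#' @export
print.lmg_decomposition <- function(x, ...) {
  cat(sprintf("LMG decomposition over %d pairs, total R^2 = %.4f\n",
              x$n_pairs, x$total_r_squared))
  ord <- order(-x$contribution)
  for (i in ord) {
    cat(sprintf("  %-15s %6.2f %%\n", names(x$contribution)[i], x$percent[i]))
  }
  invisible(x)
}

#' Taxon-environment Spearman screen
#'
#' Aggregates ZOTU relative abundances to a taxonomy rank (summing member
#' ZOTUs per sample) and correlates each taxon with each covariate
#' (Spearman, pairwise-complete, two-sided t-approximation p), with
#' optional Benjamini-Hochberg q-values over the whole screen. Constant
#' taxa are flagged not-computed rather than given rho = 0.
#'
#' @param table a [zotu_table()] with taxonomy paths.
#' @param level 1-based rank position within the semicolon-delimited
#'   taxonomy path.
#' @param metadata metadata data.frame.
#' @param variables covariate columns.
#' @param adjust compute BH q-values?
#' @return data.frame of (taxon, variable, n, rho, p_value, q_value,
#'   computed).
#' @export
taxa_env_spearman <- function(table, level, metadata,
                              variables = c("depth", "temperature", "salinity",
                                            "PO4", "NO2NO3", "SiO2"),
                              adjust = TRUE) {
  agg <- aggregate_taxa(table, level)
  variables <- intersect(variables, colnames(metadata))
  md <- metadata[match(rownames(agg), metadata$sample_id), , drop = FALSE]
  grid <- expand.grid(taxon = colnames(agg), variable = variables,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- agg[, grid$taxon[i]]
    yv <- md[[grid$variable[i]]]
    ok <- stats::complete.cases(x, yv)
    if (sum(ok) < 4 || stats::sd(x[ok]) == 0 || stats::sd(yv[ok]) == 0) {
      return(data.frame(grid[i, ], n = sum(ok), rho = NA_real_,
                        p_value = NA_real_, computed = FALSE))
    }
    rho <- stats::cor(x[ok], yv[ok], method = "spearman")
    data.frame(grid[i, ], n = sum(ok), rho = rho,
               p_value = spearman_p(rho, sum(ok)), computed = TRUE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  if (adjust && any(out$computed)) {
    out$q_value[out$computed] <- bh_adjust(out$p_value[out$computed])
  }
  rownames(out) <- NULL
  out
}

#' Aggregate relative abundances to a taxonomy rank
#'
#' @param table a [zotu_table()] with taxonomy.
#' @param level 1-based position in the semicolon-delimited rank path;
#'   ZOTUs whose path is shorter (or missing) are pooled as
#'   `"Unclassified"`.
#' @return samples x taxa matrix of summed relative abundances.
#' @export
aggregate_taxa <- function(table, level) {
  if (is.null(table$taxonomy)) stop("table has no taxonomy", call. = FALSE)
  parts <- strsplit(ifelse(is.na(table$taxonomy), "", table$taxonomy), ";")
  parts <- lapply(parts, trimws)
  depths <- lengths(parts)
  if (all(depths < level)) {
    stop("taxonomy rank level ", level, " absent from all paths", call. = FALSE)
  }
  lab <- vapply(parts, function(x) {
    if (length(x) >= level && nzchar(x[level])) x[level] else "Unclassified"
  }, character(1))
  rel <- relative_abundance(table)
  t(rowsum(t(rel), group = lab))
}
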