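#' Read and write ZOTU tables
#'
#' The on-disk format is a tab-separated file with ZOTUs in rows and
#' samples in columns: a first column of ZOTU ids (header `#ZOTU_ID`), one
#' integer column per sample, and an optional trailing `taxonomy` column
#' with semicolon-delimited rank paths. [read_zotu_table()] and
#' [write_zotu_table()] round-trip counts, ids and taxonomy exactly.
#'
#' @param path file path.
#' @return [read_zotu_table()] returns a [zotu_table()];
#'   [write_zotu_table()] invisibly returns `path`.
#' @export
read_zotu_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ZOTU table needs an id column and >= 1 sample", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated ZOTU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  if (tolower(colnames(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- as.character(df[[ncol(df)]])
    df <- df[, -ncol(df), drop = FALSE]
  }
  if (anyDuplicated(colnames(df))) {
    stop("duplicated sample id(s) in header", call. = FALSE)
  }
  m <- as.matrix(df)
  if (!is.numeric(m) || any(is.na(m)) || any(m != round(m)) || any(m < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("empty sample column(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  zotu_table(t(m), taxonomy)
}

#' @rdname read_zotu_table
#' @param table a [zotu_table()]
#' @export
write_zotu_table <- function(table, path) {
  m <- t(table$counts)
  df <- data.frame(`#ZOTU_ID` = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata is a tab-separated table with one row per sample. Required
#' columns are `sample_id` and `habitat` (values `surface` or `SCM`);
#' environmental covariates (depth in m, temperature in degrees C,
#' salinity, nutrients in uM, size-fractionated chlorophyll a in ug/L,
#' picoplankton abundances in cells/mL) are numeric with missing values
#' written as literal `NA` (e.g. below-detection ammonium), never as zero.
#'
#' @param path file path.
#' @return a `data.frame` with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("sample_id", "habitat") %in% colnames(df))) {
    stop("metadata must have 'sample_id' and 'habitat' columns", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id", call. = FALSE)
  bad <- setdiff(unique(df$habitat), c("surface", "SCM"))
  if (length(bad)) {
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
         " (expected 'surface' or 'SCM')", call. = FALSE)
  }
  df
}

#' @rdname read_metadata
#' @param metadata a metadata `data.frame`
#' @export
write_metadata <- function(metadata, path) {
  df <- metadata
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    s <- formatC(x, format = "g", digits = 6)
    s[is.na(x)] <- NA
    s
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write rooted Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that
#' enforce unique leaf names on read.
#'
#' @param path file path.
#' @return [read_newick()] returns an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tree has duplicate leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tree
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' The full symmetric matrix is written with a leading id column; floats
#' use `%.6g` so writes are byte-stable.
#'
#' @param dm a [stats::dist] object or symmetric matrix with labels.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  chr <- matrix(formatC(m, format = "g", digits = 6), nrow = nrow(m))
  df <- data.frame(sample_id = rownames(m), chr, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @return [read_distance_matrix()] returns a [stats::dist] object.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)) || any(diag(m) != 0)) {
    stop("not a valid distance matrix (symmetry/diagonal)", call. = FALSE)
  }
  stats::as.dist(m)
}

#' Export and re-import a co-occurrence network
#'
#' Writes an igraph network (node attributes: enrichment class, module,
#' centralities; edge attributes: Spearman rho, BH q-value, sign) to
#' GraphML or GML via [igraph::write_graph()].
#'
#' @param network an [igraph::igraph] graph.
#' @param path file path.
#' @param format `"graphml"` or `"gml"`.
#' @export
write_network <- function(network, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  igraph::write_graph(network, path, format = format)
  invisible(path)
}

#' @rdname write_network
#' @return [read_network()] returns an [igraph::igraph] graph. GML files
#'   store node names in the `label` attribute; they are restored to
#'   igraph `name`s on read.
#' @export
read_network <- function(path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- igraph::read_graph(path, format = format)
  if (format == "gml" && !("name" %in% igraph::vertex_attr_names(g)) &&
      "label" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name <- igraph::V(g)$label
  }
  g
}
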