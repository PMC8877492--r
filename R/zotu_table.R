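#' Construct a ZOTU count table
#'
#' A `zotu_table` holds a samples x ZOTUs matrix of non-negative integer
#' read counts plus an optional taxonomy path (semicolon-delimited ranks)
#' per ZOTU. Internally the matrix is oriented samples x ZOTUs (the math
#' convention); the on-disk TSV dialect is ZOTUs x samples (the common
#' amplicon-table convention, see [write_zotu_table()]).
#'
#' @param counts numeric matrix, samples in rows, ZOTUs in columns, with
#'   unique dimnames. All entries must be non-negative integers and every
#'   sample (row) must have a positive total.
#' @param taxonomy optional character vector of taxonomy paths, one per
#'   ZOTU, either named by ZOTU id or in column order. `NA` entries are
#'   allowed (unclassified).
#' @return An object of class `zotu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (named character vector or `NULL`).
#' @export
zotu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have sample (row) and ZOTU (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate ZOTU ids in count matrix", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("empty sample(s) with zero total reads: ",
         paste(rownames(counts)[rs == 0], collapse = ", "), call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != ncol(counts)) {
      stop("taxonomy length must equal the number of ZOTUs", call. = FALSE)
    }
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "zotu_table")
}

#' @export
print.zotu_table <- function(x, ...) {
  cat("ZOTU table:", nrow(x$counts), "samples x", ncol(x$counts), "ZOTUs\n")
  cat("  reads per sample:", min(rowSums(x$counts)), "-", max(rowSums(x$counts)), "\n")
  if (!is.null(x$taxonomy)) {
    cat("  taxonomy paths for", sum(!is.na(x$taxonomy)), "ZOTUs\n")
  }
  invisible(x)
}

#' @export
dim.zotu_table <- function(x) dim(x$counts)

#' Sample and ZOTU identifiers
#' @param table a [zotu_table()]
#' @return character vector of ids.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
zotu_ids <- function(table) colnames(table$counts)

#' Per-sample relative abundances
#'
#' @param table a [zotu_table()]
#' @return numeric matrix with unit row sums.
#' @export
relative_abundance <- function(table) {
  sweep(table$counts, 1, rowSums(table$counts), "/")
}

#' Subset a ZOTU table
#'
#' @param table a [zotu_table()]
#' @param samples,zotus character or logical/integer index of rows/columns
#'   to keep; `NULL` keeps everything. Subsetting never drops all-zero
#'   ZOTU columns implicitly.
#' @return a [zotu_table()]; note that a subset making a sample empty is
#'   rejected by validation.
#' @export
subset_zotu_table <- function(table, samples = NULL, zotus = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(zotus)) counts <- counts[, zotus, drop = FALSE]
  tax <- table$taxonomy
  if (!is.null(tax)) tax <- tax[colnames(counts)]
  zotu_table(counts, tax)
}
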