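#' Construct a feature table
#'
#' A feature table holds a samples-by-taxa matrix of non-negative abundances
#' (counts or relative abundances) together with unique sample and taxon
#' identifiers and optional human-readable taxonomy labels (e.g. genus names).
#' This is the exposure object consumed by every downstream stage.
#'
#' @param values Numeric matrix, samples in rows and taxa in columns.
#' @param sample_ids Character vector of unique sample identifiers; defaults to
#'   the matrix row names.
#' @param taxon_ids Character vector of unique taxon identifiers (e.g. ASV
#'   hashes); defaults to the matrix column names.
#' @param taxon_labels Optional character vector of taxonomy labels, one per
#'   taxon.
#' @return An object of class `feature_table`: a list with elements `values`
#'   (the matrix, dimnames set to the ids) and `taxon_labels`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          taxon_ids = colnames(values), taxon_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("`values` must be a numeric matrix")
  if (any(!is.finite(values))) stopf("abundances must be finite")
  if (any(values < 0)) stopf("abundances must be non-negative")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("ASV", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(values))
    stopf("%d sample ids for %d rows", length(sample_ids), nrow(values))
  if (length(taxon_ids) != ncol(values))
    stopf("%d taxon ids for %d columns", length(taxon_ids), ncol(values))
  if (anyDuplicated(sample_ids)) stopf("sample ids must be unique")
  if (anyDuplicated(taxon_ids)) stopf("taxon ids must be unique")
  if (!is.null(taxon_labels)) {
    taxon_labels <- as.character(taxon_labels)
    if (length(taxon_labels) != length(taxon_ids))
      stopf("`taxon_labels` must have one entry per taxon")
    names(taxon_labels) <- taxon_ids
  }
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(list(values = values, taxon_labels = taxon_labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d taxa\n",
              nrow(x$values), ncol(x$values)))
  occ <- mean(x$values > 0)
  cat(sprintf("  occupancy (values > 0): %.1f%%; labels: %s\n", 100 * occ,
              if (is.null(x$taxon_labels)) "none" else "present"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table
#'
#' @param x A [feature_table()].
#' @param samples,taxa Index vectors (logical, integer, or id character) for
#'   the samples / taxa to keep; `NULL` keeps everything.
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
ft_subset <- function(x, samples = NULL, taxa = NULL) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(taxa)) v <- v[, taxa, drop = FALSE]
  labels <- x$taxon_labels
  if (!is.null(labels)) labels <- labels[colnames(v)]
  feature_table(v, taxon_labels = labels)
}

#' Read / write feature tables and metadata
#'
#' Feature tables are stored as plain tab-separated matrices: one header row of
#' taxon identifiers, then one row per sample whose first field is the sample
#' identifier. Metadata travel as ordinary CSV with a `sample_id` column.
#'
#' @param path File path.
#' @return `read_feature_table()` returns a [feature_table()];
#'   `read_metadata()` a `data.frame`.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1L)
  feature_table(as.matrix(df))
}

#' @rdname read_feature_table
#' @param x Object to write.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @export
read_metadata <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_feature_table
#' @export
write_metadata <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @details `write_feature_table_biom()` emits BIOM-format JSON (format 1.0)
#'   via the biomformat package, for interoperability with QIIME-style
#'   tooling; the package must be installed.
#' @export
write_feature_table_biom <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  if (!requireNamespace("biomformat", quietly = TRUE))
    stopf("the 'biomformat' package is required for BIOM output")
  b <- biomformat::make_biom(t(x$values))
  biomformat::write_biom(b, path)
  invisible(path)
}
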