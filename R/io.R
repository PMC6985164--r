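#' Construct an omics layer
#'
#' One molecular data type as a samples x features numeric matrix with unique
#' sample and feature identifiers.
#'
#' @param values numeric matrix with rownames (sample ids) and colnames
#'   (feature ids).
#' @param layer_name character label (e.g. "mRNA").
#' @return an `omics_layer` object.
#' @export
omics_layer <- function(values, layer_name = "other") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids")
  storage.mode(values) <- "double"
  structure(list(values = values,
                 sample_ids = rownames(values),
                 feature_ids = colnames(values),
                 layer_name = layer_name),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer '%s': %d samples x %d features>\n",
              x$layer_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write an omics layer as TSV
#'
#' Rows are samples, columns are features; header row of feature ids, first
#' column `sample_id`.
#'
#' @param layer an [omics_layer()].
#' @param path output file path.
#' @export
write_layer_tsv <- function(layer, path) {
  df <- data.frame(sample_id = layer$sample_ids, layer$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics layer from TSV
#'
#' @param path TSV as written by [write_layer_tsv()] (same dialect accepted
#'   for real exports: first column sample ids, header of feature ids).
#' @param layer_name label to attach.
#' @return an [omics_layer()].
#' @export
read_layer_tsv <- function(path, layer_name = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- as.character(df[[1]])
  if (is.null(layer_name))
    layer_name <- sub("\\.tsv$", "", basename(path))
  omics_layer(X, layer_name)
}

#' Write cluster/class assignments as two-column TSV
#' @param labels named vector (names = sample ids).
#' @param path output path.
#' @export
write_assignments_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), subtype = as.vector(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}
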