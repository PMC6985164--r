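#' Build a drug-response table with z-scores and ordinal categories
#'
#' Activity areas are z-scored per drug across cell lines (missing values
#' allowed) and categorized: z > 0.8 sensitive (2), z < -0.8 resistant (0),
#' otherwise intermediate (1). The boundaries are strict: z equal to 0.8 or
#' -0.8 is intermediate.
#'
#' @param activity line x drug numeric matrix (NA = missing), line ids as
#'   rownames and drug ids as colnames.
#' @param z_threshold category boundary on the z scale (default 0.8).
#' @return a `drug_response_table` with elements `activity`, `z`,
#'   `categories`, `line_ids`, `drug_ids`, `z_threshold`.
#' @export
drug_response_table <- function(activity, z_threshold = 0.8) {
  activity <- as.matrix(activity)
  if (is.null(rownames(activity)))
    rownames(activity) <- sprintf("L%03d", seq_len(nrow(activity)))
  if (is.null(colnames(activity)))
    colnames(activity) <- sprintf("drug%02d", seq_len(ncol(activity)))
  z <- apply(activity, 2, function(a) {
    s <- stats::sd(a, na.rm = TRUE)
    if (!is.finite(s) || s <= 0) stop("drug with zero variance: z undefined")
    (a - mean(a, na.rm = TRUE)) / s
  })
  dimnames(z) <- dimnames(activity)
  structure(list(activity = activity, z = z,
                 categories = categorize_response(z, z_threshold),
                 line_ids = rownames(activity),
                 drug_ids = colnames(activity),
                 z_threshold = z_threshold),
            class = "drug_response_table")
}

#' Categorize z-scored drug responses
#'
#' @param z numeric (vector or matrix) of per-drug z-scores.
#' @param z_threshold boundary (default 0.8); strict inequalities, so the
#'   boundary values themselves are intermediate.
#' @return integer codes: 0 resistant, 1 intermediate, 2 sensitive (NA kept).
#' @export
categorize_response <- function(z, z_threshold = 0.8) {
  out <- ifelse(z > z_threshold, 2L, ifelse(z < -z_threshold, 0L, 1L))
  if (is.matrix(z)) dimnames(out) <- dimnames(z)
  out
}

#' Exhaustive nearest-neighbour searcher over biomarker profiles
#'
#' Stores a standard-normalized biomarker matrix (cell lines and/or tumours
#' in rows) for brute-force squared-Euclidean neighbour queries.
#'
#' @param profiles samples x features numeric matrix (biomarker panel
#'   columns), ids as rownames.
#' @param standardize standard-normalize the profiles per feature (default
#'   TRUE).
#' @return a `neighbor_searcher`.
#' @export
neighbor_searcher <- function(profiles, standardize = TRUE) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) stop("profiles need sample ids as rownames")
  Z <- if (standardize) standardize_matrix(impute_missing(profiles)) else profiles
  structure(list(Z = Z, ids = rownames(profiles)),
            class = "neighbor_searcher")
}

#' Find nearest neighbours by squared Euclidean distance
#'
#' @param searcher a [neighbor_searcher()].
#' @param query_id id of a stored profile, or a numeric feature vector on the
#'   searcher's feature space.
#' @param n number of neighbours (default 10). The query itself is excluded.
#'   If n is at least the reference size, all references are returned with a
#'   warning.
#' @return data.frame (id, sq_distance) in ascending distance, ties broken
#'   by id order.
#' @export
find_neighbors <- function(searcher, query_id, n = 10) {
  stopifnot(inherits(searcher, "neighbor_searcher"))
  if (is.character(query_id)) {
    if (!query_id %in% searcher$ids) stop(sprintf("unknown id '%s'", query_id))
    q <- searcher$Z[query_id, ]
    ref <- setdiff(searcher$ids, query_id)
  } else {
    if (length(query_id) != ncol(searcher$Z))
      stop("query vector length must match the searcher's feature count")
    q <- as.numeric(query_id)
    ref <- searcher$ids
  }
  d2 <- colSums((t(searcher$Z[ref, , drop = FALSE]) - q)^2)
  if (n >= length(ref)) {
    warning("n >= reference size: returning all references")
    n <- length(ref)
  }
  ord <- order(d2, ref)[seq_len(n)]  # ties broken by id order
  data.frame(id = ref[ord], sq_distance = unname(d2[ord]),
             stringsAsFactors = FALSE)
}

#' Predict a cell line's drug responses from its nearest neighbours
#'
#' Finds the query's `n` nearest profiles, takes for each drug the median of
#' the neighbours' z-scored activities (neighbours without data for a drug
#' are skipped), and categorizes the median. With exactly two data-bearing
#' neighbours the median equals their mean.
#'
#' @param query_id cell line id present in the searcher.
#' @param searcher a [neighbor_searcher()].
#' @param table a [drug_response_table()]; neighbours absent from the table
#'   contribute no data.
#' @param n neighbour count (default 10).
#' @return data.frame (drug, median_z, category); drugs with no neighbour
#'   data carry NA.
#' @export
predict_drug_response <- function(query_id, searcher, table, n = 10) {
  stopifnot(inherits(table, "drug_response_table"))
  nbr <- find_neighbors(searcher, query_id, n = n)
  with_data <- intersect(nbr$id, table$line_ids)
  if (length(with_data) == 0)
    stop(sprintf("no neighbour of '%s' has drug-response data", query_id))
  Zn <- table$z[with_data, , drop = FALSE]
  med <- apply(Zn, 2, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA
  data.frame(drug = table$drug_ids,
             median_z = unname(med),
             category = unname(categorize_response(med, table$z_threshold)),
             stringsAsFactors = FALSE)
}

#' Quadratic weighted Cohen's kappa for ordinal agreement
#'
#' \deqn{\kappa = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}},
#'   \qquad w_{ij} = \frac{(i-j)^2}{(C-1)^2},}
#' with O the observed contingency matrix over the full C x C category grid
#' (categories unobserved in the data still included) and E the outer product
#' of the two marginal distributions scaled to the total count. Pairs with a
#' missing entry are dropped. Two constant, identical raters give kappa 1.
#'
#' @param pred,actual ordinal vectors with entries in 0..(n_categories-1).
#' @param n_categories size of the ordinal scale (default 3).
#' @return scalar kappa (<= 1).
#' @export
quadratic_kappa <- function(pred, actual, n_categories = 3) {
  if (length(pred) != length(actual)) stop("vectors must have equal length")
  keep <- !is.na(pred) & !is.na(actual)
  pred <- pred[keep]; actual <- actual[keep]
  if (length(pred) == 0) stop("no usable (non-missing) pairs")
  cats <- 0:(n_categories - 1)
  if (!all(pred %in% cats) || !all(actual %in% cats))
    stop("entries must lie in 0..(n_categories-1)")
  O <- table(factor(pred, cats), factor(actual, cats))
  total <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / total
  w <- outer(cats, cats, function(i, j) (i - j)^2) / (n_categories - 1)^2
  denom <- sum(w * E)
  if (denom == 0) return(1)  # both raters constant and identical
  1 - sum(w * O) / denom
}

#' Leave-one-out drug-response prediction benchmark
#'
#' Every cell line with drug data is predicted from its nearest neighbours
#' (itself excluded), and the prediction is scored against its observed
#' categories with the quadratic kappa over its drugs; the mean kappa across
#' lines is reported. With a single-drug table, per-line kappa is degenerate,
#' so one kappa pooled across lines is computed instead (with a message).
#'
#' @param table a [drug_response_table()].
#' @param searcher a [neighbor_searcher()] whose ids cover the table's lines.
#' @param n neighbour count (default 10).
#' @return list with `per_line` (named kappa vector, NA where prediction
#'   failed), `mean_kappa`, `n_drugs`.
#' @export
leave_one_out_benchmark <- function(table, searcher, n = 10) {
  lines <- intersect(table$line_ids, searcher$ids)
  if (length(lines) < 2) stop("need >= 2 lines with drug data")
  if (length(table$drug_ids) == 1) {
    message("single-drug table: computing one kappa pooled across lines")
    preds <- vapply(lines, function(id)
      predict_drug_response(id, searcher, table, n = n)$category, integer(1))
    kap <- quadratic_kappa(preds, table$categories[lines, 1])
    return(list(per_line = NULL, mean_kappa = kap, n_drugs = 1L,
                pooled = TRUE))
  }
  per_line <- vapply(lines, function(id) {
    pr <- tryCatch(predict_drug_response(id, searcher, table, n = n),
                   error = function(e) NULL)
    if (is.null(pr)) return(NA_real_)
    quadratic_kappa(pr$category, table$categories[id, ])
  }, numeric(1))
  failed <- sum(is.na(per_line))
  if (failed > 0)
    message(sprintf("%d line(s) could not be predicted (no neighbour data)", failed))
  list(per_line = per_line,
       mean_kappa = mean(per_line, na.rm = TRUE),
       n_drugs = length(table$drug_ids),
       pooled = FALSE)
}
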