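#' Per-feature Welch t-tests with Benjamini-Hochberg correction
#'
#' Unequal-variance two-sample t-test per feature between two subtypes,
#' BH step-up adjustment across features, and the direction of the shift.
#' Features with zero variance in both groups get p = 1 and a flag.
#'
#' @param X samples x features matrix.
#' @param labels two-group vector aligned with rows of X.
#' @param fdr significance threshold on the adjusted p (default 0.05).
#' @return data.frame: feature_id, mean_1, mean_2, t_statistic, p, q,
#'   direction, significant, degenerate.
#' @export
welch_bh <- function(X, labels, fdr = 0.05) {
  X <- as.matrix(X)
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required")
  i1 <- labels == groups[1]; i2 <- labels == groups[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop("both groups need >= 2 samples")
  res <- lapply(seq_len(ncol(X)), function(j) {
    x1 <- X[i1, j]; x2 <- X[i2, j]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0)
      return(list(m1 = mean(x1), m2 = mean(x2), t = 0, p = 1, degenerate = TRUE))
    tt <- stats::t.test(x1, x2, var.equal = FALSE)
    list(m1 = mean(x1), m2 = mean(x2), t = unname(tt$statistic),
         p = tt$p.value, degenerate = FALSE)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- data.frame(
    feature_id = colnames(X),
    mean_1 = vapply(res, `[[`, numeric(1), "m1"),
    mean_2 = vapply(res, `[[`, numeric(1), "m2"),
    t_statistic = vapply(res, `[[`, numeric(1), "t"),
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$mean_1 >= out$mean_2,
                          sprintf("up_in_%s", groups[1]),
                          sprintf("up_in_%s", groups[2]))
  out$significant <- out$q < fdr
  out
}

#' Hypergeometric gene-set overrepresentation
#'
#' Upper-tail hypergeometric test of the overlap between a query list and
#' each gene set, with BH correction across sets. Sets are intersected with
#' the universe first; the query must be a subset of the universe.
#'
#' @param query_list character vector of hits.
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all testable ids.
#' @param fdr reporting threshold on q (default 0.05; 0.10 is used for the
#'   kinase-enrichment display convention).
#' @return data.frame: term_id, set_size, overlap, p, q, significant.
#' @export
hypergeom_enrich <- function(query_list, gene_sets, universe, fdr = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  if (length(query_list) == 0) stop("empty query list")
  query_list <- unique(query_list)
  universe <- unique(universe)
  if (!all(query_list %in% universe))
    stop("query list must be a subset of the universe")
  N <- length(universe)
  nq <- length(query_list)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe)
    ov <- length(intersect(query_list, set))
    # P(overlap >= observed) under sampling nq of N without replacement
    p <- stats::phyper(ov - 1, length(set), N - length(set), nq,
                       lower.tail = FALSE)
    data.frame(term_id = term, set_size = length(set), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out[order(out$p), ]
}

#' Kaplan-Meier curves, median survival and log-rank test
#'
#' Product-limit estimator per group, median survival (smallest time with
#' S(t) <= 0.5; "not reached" reported as NA), and the two-or-more-group
#' log-rank test.
#'
#' @param records data.frame with columns time (> 0), event (logical/0-1)
#'   and group (as produced by [generate_survival()]).
#' @return list with `fit` (a survival::survfit), `median` (named per-group),
#'   `logrank_p`, `logrank_chisq`.
#' @export
km_curves <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  if (any(records$time <= 0)) stop("survival times must be positive")
  su <- survival::Surv(records$time, as.integer(records$event))
  fit <- survival::survfit(su ~ group, data = records)
  med <- summary(fit)$table
  med <- if (is.matrix(med)) med[, "median"] else med[["median"]]
  lr <- tryCatch(survival::survdiff(su ~ group, data = records),
                 error = function(e) NULL)
  logrank_p <- if (is.null(lr)) NA_real_
    else stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  list(fit = fit, median = med,
       logrank_chisq = if (is.null(lr)) NA_real_ else unname(lr$chisq),
       logrank_p = logrank_p)
}

#' Association between categorical variables
#'
#' Pearson chi-square (no continuity correction) for r x c tables and,
#' additionally, the two-sided Fisher exact p for 2 x 2 tables. Rows or
#' columns with zero margin are dropped with a warning.
#'
#' @param tab matrix of nonnegative integer counts.
#' @return list with `chisq`, `chisq_p`, `fisher_p` (NA unless 2 x 2), `df`.
#' @export
categorical_assoc <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin row(s)/column(s)")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2 x 2 table")
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fisher_p <- if (all(dim(tab) == 2)) stats::fisher.test(tab)$p.value else NA_real_
  list(chisq = unname(ch$statistic), chisq_p = ch$p.value,
       fisher_p = fisher_p, df = unname(ch$parameter))
}
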