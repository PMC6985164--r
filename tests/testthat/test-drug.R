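test_that("z-normalization is idempotent and category boundaries are strict", {
  set.seed(1)
  act <- matrix(rnorm(40 * 6, mean = 5, sd = 2), 40, 6)
  tab <- drug_response_table(act)
  expect_equal(colMeans(tab$z), rep(0, 6), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(tab$z, 2, sd), rep(1, 6), ignore_attr = TRUE, tolerance = 1e-12)
  tab2 <- drug_response_table(tab$z)
  expect_equal(tab2$z, tab$z, tolerance = 1e-12)
  # boundaries: z equal to +/-0.8 is intermediate (strict inequalities)
  expect_identical(categorize_response(c(0.8, -0.8, 0.800001, -0.800001, 0)),
                   c(1L, 1L, 2L, 0L, 1L))
  expect_true(is.na(categorize_response(NA_real_)))
})

test_that("neighbour search matches hand arithmetic and a brute-force scan", {
  ref <- matrix(0:4, 5, 1, dimnames = list(sprintf("L%d", 1:5), "f1"))
  searcher <- neighbor_searcher(ref, standardize = FALSE)
  nb <- find_neighbors(searcher, matrix(1.4, 1, 1), n = 2)
  expect_equal(nb$id, c("L2", "L3"))
  expect_equal(nb$sq_distance, c(0.16, 0.36))
  # stored query excludes itself and returns distance 0 for a duplicate
  ref2 <- rbind(ref, L6 = 0)
  s2 <- neighbor_searcher(ref2, standardize = FALSE)
  nb2 <- find_neighbors(s2, "L6", n = 1)
  expect_equal(nb2$id, "L1")
  expect_equal(nb2$sq_distance, 0)
  # n >= reference size returns everything with a warning
  expect_warning(all_nb <- find_neighbors(searcher, matrix(0, 1, 1), n = 10),
                 "all references")
  expect_equal(nrow(all_nb), 5)
  # brute-force equivalence on 100 random points
  set.seed(2)
  P <- matrix(rnorm(100 * 7), 100, 7, dimnames = list(sprintf("P%03d", 1:100), NULL))
  s3 <- neighbor_searcher(P, standardize = FALSE)
  for (q in c("P001", "P050")) {
    d2 <- colSums((t(P[setdiff(rownames(P), q), ]) - P[q, ])^2)
    expect_equal(find_neighbors(s3, q, n = 10)$id,
                 names(sort(d2))[1:10])
  }
})

test_that("drug prediction takes the categorized median of neighbour z-scores", {
  # two data-bearing neighbours: median equals their mean
  act <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(sprintf("L%02d", 1:30), NULL))
  tab <- drug_response_table(act)
  # direct check of the median+threshold rule
  expect_equal(categorize_response(stats::median(c(1.0, 1.2))), 2L)  # 1.1 sensitive
  expect_equal(categorize_response(stats::median(c(1.0, -1.0))), 1L) # 0 intermediate
  # pipeline-level: all neighbours sensitive for a drug -> sensitive predicted.
  # 30 lines; the 10 nearest to the query are the minority with high activity,
  # so their z-scores sit at +sqrt(20/10) = 1.41 > 0.8 (and -1.41 for drugB).
  prof <- matrix(c(seq(0.01, 0.1, length.out = 10), rep(10, 19), 0), 30, 1,
                 dimnames = list(sprintf("L%02d", 1:30), "f1"))
  searcher <- neighbor_searcher(prof, standardize = FALSE)
  act2 <- cbind(drugA = c(rep(5, 10), rep(1, 20)),
                drugB = c(rep(1, 10), rep(5, 20)))
  rownames(act2) <- rownames(prof)
  tab2 <- drug_response_table(act2)
  pr <- predict_drug_response("L30", searcher, tab2, n = 10)
  expect_equal(pr$category, c(2L, 0L))
})

test_that("quadratic kappa matches the brute-force contingency oracle", {
  expect_equal(quadratic_kappa(c(0, 1, 2, 1), c(0, 2, 2, 1)),
               kappa_bruteforce(c(0, 1, 2, 1), c(0, 2, 2, 1)))
  expect_equal(quadratic_kappa(0:2, 0:2), 1)
  # perfect agreement, constant identical raters, constant disagreeing raters
  expect_equal(quadratic_kappa(rep(1, 5), rep(1, 5)), 1)
  expect_true(is.finite(quadratic_kappa(rep(0, 5), rep(2, 5))))
  expect_error(quadratic_kappa(NA, NA), "no usable")
  # 1000 random ordinal pairs against the oracle
  set.seed(4)
  for (i in 1:20) {
    n <- sample(3:60, 1)
    p <- sample(0:2, n, replace = TRUE)
    a <- sample(0:2, n, replace = TRUE)
    if (all(p == a)) a[1] <- (a[1] + 1) %% 3
    expect_equal(quadratic_kappa(p, a), kappa_bruteforce(p, a), tolerance = 1e-12)
  }
  # reversing the ordinal scale on both vectors leaves kappa unchanged
  set.seed(5)
  p <- sample(0:2, 200, replace = TRUE); a <- sample(0:2, 200, replace = TRUE)
  expect_equal(quadratic_kappa(2 - p, 2 - a), quadratic_kappa(p, a))
  # independent pairs: kappa near zero at large n
  set.seed(6)
  p <- sample(0:2, 1e5, replace = TRUE); a <- sample(0:2, 1e5, replace = TRUE)
  expect_lt(abs(quadratic_kappa(p, a)), 0.05)
})

test_that("leave-one-out benchmark is exact without noise and handles one drug", {
  lines <- generate_multiomics(cell_line_scenario(seed = 31))
  searcher <- neighbor_searcher(
    lines$layers$mRNA$values[, lines$informative_features$mRNA])
  tab0 <- generate_drug_panel(lines$true_labels, n_drugs = 24,
                              subtype_effect = 2, noise_sd = 1e-9, seed = 31)
  bench <- leave_one_out_benchmark(tab0, searcher)
  expect_equal(bench$mean_kappa, 1)
  # single-drug table switches to pooled kappa with a message
  tab1 <- drug_response_table(tab0$activity[, 1, drop = FALSE])
  expect_message(b1 <- leave_one_out_benchmark(tab1, searcher), "pooled")
  expect_true(b1$pooled)
  expect_equal(b1$n_drugs, 1L)
})
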