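test_that("generator is deterministic and shares sample ids across layers", {
  cfg <- standard_scenario(seed = 11)
  a <- generate_multiomics(cfg)
  b <- generate_multiomics(cfg)
  expect_identical(a$layers$mRNA$values, b$layers$mRNA$values)
  expect_identical(a$true_labels, b$true_labels)
  ids <- a$layers[[1]]$sample_ids
  for (ly in a$layers) expect_identical(ly$sample_ids, ids)
  expect_equal(length(ids), 45)
  expect_setequal(unique(a$true_labels), 1:2)
  expect_true(all(table(a$true_labels) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(layer_spec("x", 10, 11), "n_informative")
  expect_error(layer_spec("x", 10, 5, discordance_fraction = 1))
  expect_error(synth_config(3, 5, list(layer_spec("x", 10, 2))), "n_subtypes")
  expect_error(generate_drug_panel(integer(0)), "non-empty")
  expect_error(generate_drug_panel(c(a = 1L, b = 2L), n_drugs = 0), "n_drugs")
  expect_error(generate_survival(c(a = 1L), scales = -1), "positive")
})

test_that("effect_size = 0 leaves informative features indistinguishable from noise", {
  cfg <- synth_config(40, 2, seed = 3, layer_specs = list(
    layer_spec("x", 100, 20, effect_size = 0, noise_sd = 1)))
  ds <- generate_multiomics(cfg)
  X <- ds$layers$x$values
  inf <- ds$informative_features$x
  nuis <- setdiff(colnames(X), inf)
  # per-feature |between-subtype shift|: same distribution for both groups
  shift <- abs(colMeans(X[ds$true_labels == 1, ]) - colMeans(X[ds$true_labels == 2, ]))
  expect_gt(stats::t.test(shift[inf], shift[nuis])$p.value, 0.01)
})

test_that("strong clean signal makes single-layer k-means recover truth exactly", {
  cfg <- synth_config(40, 2, seed = 5, layer_specs = list(
    layer_spec("x", 50, 25, effect_size = 5, noise_sd = 1,
               discordance_fraction = 0)))
  ds <- generate_multiomics(cfg)
  set.seed(1)
  km <- stats::kmeans(standardize_matrix(ds$layers$x$values), 2, nstart = 20)
  expect_equal(cluster_concordance(km$cluster, ds$true_labels)$ari, 1)
})

test_that("discordance permutes informative sub-rows without touching marginals", {
  cfg <- synth_config(40, 2, seed = 7, layer_specs = list(
    layer_spec("x", 60, 20, effect_size = 2, discordance_fraction = 0.4)))
  ds <- generate_multiomics(cfg)
  disc <- ds$discordant_samples$x
  expect_length(disc, floor(0.4 * 40))
  # a discordant layer's own clustering is degraded relative to a clean copy
  cfg0 <- synth_config(40, 2, seed = 7, layer_specs = list(
    layer_spec("x", 60, 20, effect_size = 2, discordance_fraction = 0)))
  ds0 <- generate_multiomics(cfg0)
  # same noise seedings: the multisets of informative values per feature match
  inf <- ds$informative_features$x
  expect_equal(apply(ds$layers$x$values[, inf], 2, sort),
               apply(ds0$layers$x$values[, inf], 2, sort))
})

test_that("drug panel separates subtypes and degenerates correctly without noise", {
  labels <- stats::setNames(rep(1:2, length.out = 44), sprintf("L%03d", 1:44))
  tab <- generate_drug_panel(labels, n_drugs = 24, subtype_effect = 3,
                             noise_sd = 0.5, seed = 2)
  expect_equal(dim(tab$activity), c(44, 24))
  pvals <- vapply(seq_len(24), function(d)
    stats::t.test(tab$activity[labels == 1, d],
                  tab$activity[labels == 2, d])$p.value, numeric(1))
  expect_gte(mean(pvals < 0.01), 0.9)
  # zero noise: same-subtype lines have identical drug rows
  tab0 <- generate_drug_panel(labels, n_drugs = 5, subtype_effect = 2,
                              noise_sd = 1e-12, seed = 2)
  rows1 <- tab0$activity[labels == 1, ]
  expect_lt(max(abs(sweep(rows1, 2, rows1[1, ]))), 1e-9)
})

test_that("survival generator honours censoring and the exponential median", {
  labs <- stats::setNames(rep(1:2, each = 1000), sprintf("S%04d", 1:2000))
  s0 <- generate_survival(labs, scales = c(10, 20), censor_rate = 0, seed = 1)
  expect_true(all(s0$event))
  km <- km_curves(s0)
  expect_equal(unname(km$median[2]), 20 * log(2), tolerance = 0.1)
  s1 <- generate_survival(labs, scales = c(10, 20), censor_rate = 0.3, seed = 1)
  expect_equal(mean(!s1$event), 0.3, tolerance = 0.1)
  expect_identical(s1, generate_survival(labs, scales = c(10, 20),
                                         censor_rate = 0.3, seed = 1))
})

test_that("layer TSV round-trips exactly", {
  bl <- blob_layer(n = 8, p = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layer_tsv(bl$layer, path)
  back <- read_layer_tsv(path, layer_name = "blobs")
  expect_equal(back$values, bl$layer$values, tolerance = 1e-12)
  expect_identical(back$sample_ids, bl$layer$sample_ids)
})
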