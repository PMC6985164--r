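#' Assemble a pipeline configuration
#'
#' All the thresholds the analysis depends on are surfaced here as named
#' fields with their standard defaults: K = 24 neighbours, alpha = 0.7,
#' t = 25 fusion iterations, k-means over k = 2..5 with 500 restarts,
#' 5-fold CV, posterior confidence flag at 0.7, drug z-boundary 0.8, 10
#' nearest neighbours.
#'
#' @param layer_paths named character vector of layer TSV paths, or NULL to
#'   simulate (then `scenario` is used).
#' @param scenario a [synth_config()] used when `layer_paths` is NULL.
#' @param outdir output directory.
#' @param seed integer seed recorded in all outputs.
#' @param snf an [snf_params()].
#' @param n_clusters "auto" (eigengap) or an integer.
#' @param kmeans_k candidate k values for the single-layer k-means baseline.
#' @param kmeans_replicates restarts per k.
#' @param panel_size biomarker panel size per layer (top_n rule).
#' @param folds CV folds.
#' @param n_drug_neighbors neighbour count for drug prediction.
#' @param drug_effect,drug_noise synthetic drug-panel parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(layer_paths = NULL,
                            scenario = standard_scenario(),
                            outdir = tempfile("fuseomics_run_"),
                            seed = 1L,
                            snf = snf_params(),
                            n_clusters = "auto",
                            kmeans_k = 2:5,
                            kmeans_replicates = 500,
                            panel_size = 20,
                            folds = 5,
                            n_drug_neighbors = 10,
                            drug_effect = 2, drug_noise = 1) {
  if (!is.null(layer_paths)) {
    missing <- layer_paths[!file.exists(layer_paths)]
    if (length(missing) > 0)
      stop(sprintf("layer path(s) do not exist: %s",
                   paste(missing, collapse = ", ")))
  }
  structure(list(layer_paths = layer_paths, scenario = scenario,
                 outdir = outdir, seed = as.integer(seed), snf = snf,
                 n_clusters = n_clusters, kmeans_k = kmeans_k,
                 kmeans_replicates = kmeans_replicates,
                 panel_size = panel_size, folds = folds,
                 n_drug_neighbors = n_drug_neighbors,
                 drug_effect = drug_effect, drug_noise = drug_noise),
            class = "pipeline_config")
}

#' Validate layer input files before any computation
#'
#' Checks each TSV for parseability, non-numeric cells, duplicate ids, and
#' sample-id consistency across layers. Every violation is reported with
#' file, row and column.
#'
#' @param paths character vector of layer TSV paths.
#' @return list with `layers` (loaded [omics_layer()]s, possibly empty on
#'   fatal findings) and `findings` (data.frame: file, row, column, problem).
#' @export
validate_inputs <- function(paths) {
  findings <- data.frame(file = character(), row = character(),
                         column = character(), problem = character(),
                         stringsAsFactors = FALSE)
  note <- function(file, row, column, problem)
    findings <<- rbind(findings, data.frame(file = file, row = row,
                                            column = column, problem = problem,
                                            stringsAsFactors = FALSE))
  layers <- list()
  id_sets <- list()
  for (path in paths) {
    df <- tryCatch(utils::read.delim(path, check.names = FALSE,
                                     stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df) || ncol(df) < 2) {
      note(path, "-", "-", "not parseable as a sample x feature TSV")
      next
    }
    ids <- as.character(df[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup) > 0)
      note(path, paste(dup, collapse = ","), names(df)[1], "duplicate sample id")
    ok <- TRUE
    for (j in 2:ncol(df)) {
      v <- df[[j]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & v != "")
        for (i in utils::head(bad, 10))
          note(path, ids[i], names(df)[j], sprintf("non-numeric cell '%s'", v[i]))
        ok <- FALSE
      }
    }
    if (ok && length(dup) == 0) {
      X <- as.matrix(df[, -1, drop = FALSE])
      rownames(X) <- ids
      layers[[path]] <- omics_layer(X, sub("\\.tsv$", "", basename(path)))
      id_sets[[path]] <- ids
    }
  }
  if (length(id_sets) > 1) {
    ref <- id_sets[[1]]
    for (p in names(id_sets)[-1]) {
      diff <- union(setdiff(ref, id_sets[[p]]), setdiff(id_sets[[p]], ref))
      if (length(diff) > 0)
        note(p, paste(utils::head(diff, 10), collapse = ","), "-",
             "sample set differs from first layer")
    }
  }
  list(layers = layers, findings = findings)
}

run_manifest_path <- function(outdir) file.path(outdir, "run_manifest.json")

config_hash <- function(config) {
  cfg <- config
  cfg$outdir <- NULL
  substr(digest_string(paste(utils::capture.output(utils::str(cfg)),
                             collapse = "\n")), 1, 16)
}

# md5 of a string via a temp file (tools::md5sum is file-based)
digest_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Run the full subtyping analysis
#'
#' Executes, in order: simulate (or load), per-layer affinity + fusion,
#' clustering (fused + single-layer baselines), biomarker selection,
#' classifier training/CV, cohort transfer, drug-response prediction, and
#' differential/survival statistics. Outputs are written under
#' `config$outdir` with a manifest (config hash, seed, file checksums); a
#' second invocation on an unchanged workspace returns the stored report
#' without recomputation.
#'
#' @param config a [pipeline_config()].
#' @return the run report (named list with one block per stage), invisibly
#'   also written as `report.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config)

  # resume: unchanged workspace -> return stored report
  mpath <- run_manifest_path(outdir)
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    files <- file.path(outdir, names(man$checksums))
    if (identical(man$config_hash, chash) && all(file.exists(files)) &&
        identical(unname(tools::md5sum(files)), unname(unlist(man$checksums)))) {
      rep <- jsonlite::read_json(file.path(outdir, "report.json"),
                                 simplifyVector = TRUE)
      rep$resumed <- TRUE
      return(rep)
    }
  }

  seed <- config$seed
  report <- list(seed = seed, config_hash = chash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (rerun: run_pipeline(<config>, seed %d))",
                   name, conditionMessage(e), seed), call. = FALSE))
  }

  ## 1. data -------------------------------------------------------------
  truth <- NULL
  if (is.null(config$layer_paths)) {
    ds <- stage("simulate", {
      sc <- config$scenario
      sc$seed <- seed
      generate_multiomics(sc)
    })
    layers <- ds$layers
    truth <- ds$true_labels
    for (nm in names(layers))
      write_layer_tsv(layers[[nm]], file.path(outdir, paste0(nm, ".tsv")))
    write_assignments_tsv(truth, file.path(outdir, "truth.tsv"))
    report$simulate <- list(n_samples = length(truth),
                            n_layers = length(layers),
                            layer_names = names(layers))
  } else {
    val <- stage("simulate", validate_inputs(config$layer_paths))
    if (nrow(val$findings) > 0)
      stop(sprintf("stage 'simulate' failed: %d validation finding(s); see validate_inputs()",
                   nrow(val$findings)), call. = FALSE)
    layers <- val$layers
    names(layers) <- vapply(layers, `[[`, character(1), "layer_name")
    report$simulate <- list(n_samples = length(layers[[1]]$sample_ids),
                            n_layers = length(layers),
                            layer_names = names(layers))
  }

  ## 2. fusion -----------------------------------------------------------
  fused <- stage("fuse", {
    nets <- lapply(layers, affinity_from_layer, params = config$snf)
    ps <- lapply(nets, status_and_local, K = config$snf$K)
    snf_fuse(ps, t = config$snf$t)
  })
  utils::write.table(fused$W, file.path(outdir, "fused_network.tsv"),
                     sep = "\t", quote = FALSE)
  report$fuse <- list(K = config$snf$K, alpha = config$snf$alpha,
                      iterations = config$snf$t)

  ## 3. clustering -------------------------------------------------------
  clus <- stage("cluster", {
    k <- if (identical(config$n_clusters, "auto"))
      as.integer(estimate_k_eigengap(fused, k_max = min(8, length(fused$sample_ids) - 1)))
    else as.integer(config$n_clusters)
    labels <- spectral_cluster(fused, k, seed = seed)
    single <- lapply(layers, function(ly) {
      net <- affinity_from_layer(ly, params = config$snf)
      spectral_cluster(net, k, seed = seed)
    })
    list(k = k, labels = labels, single = single)
  })
  write_assignments_tsv(clus$labels, file.path(outdir, "fused_assignments.tsv"))
  report$cluster <- list(
    k = clus$k,
    ari_vs_truth = if (!is.null(truth)) cluster_concordance(clus$labels, truth)$ari else NA,
    single_layer_ari = if (!is.null(truth))
      vapply(clus$single, function(l) cluster_concordance(l, truth)$ari, numeric(1))
    else NULL)

  ## 4. biomarkers -------------------------------------------------------
  panels <- stage("biomarkers", {
    lapply(layers, function(ly) {
      Z <- standardize_matrix(impute_missing(ly$values))
      fit <- fit_nca_weights(Z, clus$labels[rownames(Z)],
                             layer_name = ly$layer_name)
      select_panel(fit, "top_n", n = min(config$panel_size, ncol(Z)))
    })
  })
  for (nm in names(panels)) {
    pan <- panels[[nm]]
    utils::write.table(
      data.frame(feature_id = names(pan$weights), weight = unname(pan$weights),
                 selected = names(pan$weights) %in% pan$selected),
      file.path(outdir, paste0("panel_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report$biomarkers <- list(panel_sizes = vapply(panels, function(p)
    length(p$selected), integer(1)))

  ## 5. classifiers ------------------------------------------------------
  clsf <- stage("classify", {
    ly <- layers[[1]]
    pan <- panels[[1]]
    Xp <- ly$values[, pan$selected, drop = FALSE]
    spec <- classifier_spec("knn", n_neighbors = 5, distance_exponent = 3)
    cv <- cross_validate(spec, Xp, clus$labels[rownames(Xp)],
                         folds = config$folds, seed = seed)
    model <- train_classifier(spec, Xp, clus$labels[rownames(Xp)], seed = seed)
    list(model = model, cv = cv, panel = pan, layer = ly$layer_name)
  })
  report$classify <- list(layer = clsf$layer,
                          cv_accuracy = clsf$cv$accuracy,
                          auroc = clsf$cv$auroc)

  ## 6. transfer ---------------------------------------------------------
  transfer <- stage("transfer", {
    if (is.null(config$layer_paths)) {
      sc <- config$scenario
      sc$seed <- derive_seed(seed, 71)
      ext <- generate_multiomics(sc)
      res <- cohort_transfer(clsf$model, ext$layers[[1]], clsf$panel)
      res$accuracy_vs_truth <- best_match_agreement(
        stats::setNames(res$predictions$label, res$predictions$sample_id),
        ext$true_labels[res$predictions$sample_id])
      res
    } else {
      res <- cohort_transfer(clsf$model, layers[[1]], clsf$panel)
      res$accuracy_vs_truth <- NA
      res
    }
  })
  report$transfer <- list(agreement_with_unsupervised = transfer$agreement,
                          accuracy_vs_truth = transfer$accuracy_vs_truth,
                          n_panel_features_used = length(transfer$features_used))

  ## 7. drug response ----------------------------------------------------
  drugs <- stage("drugs", {
    lines <- generate_multiomics(cell_line_scenario(derive_seed(seed, 83)))
    feats <- intersect(panels[[1]]$selected, lines$layers[[1]]$feature_ids)
    if (length(feats) < 2) feats <- lines$informative_features[[1]]
    tab <- generate_drug_panel(lines$true_labels, n_drugs = 24,
                               subtype_effect = config$drug_effect,
                               noise_sd = config$drug_noise,
                               seed = derive_seed(seed, 84))
    searcher <- neighbor_searcher(
      lines$layers[[1]]$values[, feats, drop = FALSE])
    leave_one_out_benchmark(tab, searcher, n = config$n_drug_neighbors)
  })
  report$drugs <- list(mean_kappa = drugs$mean_kappa, n_drugs = drugs$n_drugs)

  ## 8. statistics -------------------------------------------------------
  stats_block <- stage("stats", {
    Z <- standardize_matrix(impute_missing(layers[[1]]$values))
    diff <- welch_bh(Z, clus$labels[rownames(Z)])
    labs <- if (!is.null(truth)) truth else clus$labels
    surv <- generate_survival(labs,
                              scales = config$scenario$survival_scale_per_subtype,
                              censor_rate = config$scenario$censor_rate,
                              seed = derive_seed(seed, 97))
    km <- km_curves(surv)
    list(n_significant = sum(diff$significant),
         median_survival = km$median, logrank_p = km$logrank_p)
  })
  report$stats <- stats_block
  report$resumed <- FALSE

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  files <- setdiff(list.files(outdir), basename(run_manifest_path(outdir)))
  checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(checksums) <- files
  jsonlite::write_json(list(config_hash = chash, seed = seed,
                            package_version = as.character(utils::packageVersion("fuseomics")),
                            checksums = checksums),
                       mpath, auto_unbox = TRUE, pretty = TRUE)
  report
}
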