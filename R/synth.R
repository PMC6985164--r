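#' Layer specification for the synthetic multi-omics generator
#'
#' @param layer_name character, e.g. "mRNA", "protein", "miRNA", "methylation".
#' @param n_features total number of features in the layer.
#' @param n_informative number of features carrying subtype signal
#'   (must be <= n_features).
#' @param effect_size standardized between-subtype mean shift of informative
#'   features (shift in units of the noise standard deviation); must be >= 0.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param discordance_fraction fraction in [0, 1) of samples whose informative
#'   signal in this layer is permuted across subtypes, so this layer's own
#'   clustering disagrees with the truth.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(layer_name, n_features, n_informative,
                       effect_size = 2, noise_sd = 1,
                       discordance_fraction = 0) {
  stopifnot(n_features >= 1, n_informative >= 0,
            n_informative <= n_features,
            effect_size >= 0, noise_sd > 0,
            discordance_fraction >= 0, discordance_fraction < 1)
  structure(list(layer_name = as.character(layer_name),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 discordance_fraction = discordance_fraction),
            class = "layer_spec")
}

#' Configuration for a synthetic multi-omics cohort
#'
#' Bundles the cohort size, number of planted subtypes, per-layer
#' specifications, survival parameters and the seed. An identical config
#' (including seed) always produces bit-identical data.
#'
#' @param n_samples number of samples (tumours or cell lines).
#' @param n_subtypes number of planted subtypes (default 2).
#' @param layer_specs list of [layer_spec()] objects.
#' @param seed integer random seed.
#' @param censor_rate fraction in [0, 1] of survival records censored.
#' @param survival_scale_per_subtype positive exponential scales (mean event
#'   time, in months), one per subtype.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_samples, n_subtypes = 2, layer_specs, seed = 1L,
                         censor_rate = 0.2,
                         survival_scale_per_subtype = rep(15, n_subtypes)) {
  stopifnot(n_samples >= 1, n_subtypes >= 1,
            n_subtypes <= n_samples,
            length(layer_specs) >= 1,
            censor_rate >= 0, censor_rate <= 1,
            length(survival_scale_per_subtype) == n_subtypes)
  if (any(survival_scale_per_subtype <= 0))
    stop("survival scales must be positive")
  for (ls in layer_specs)
    if (!inherits(ls, "layer_spec")) stop("layer_specs must be layer_spec objects")
  structure(list(n_samples = as.integer(n_samples),
                 n_subtypes = as.integer(n_subtypes),
                 layer_specs = layer_specs,
                 seed = as.integer(seed),
                 censor_rate = censor_rate,
                 survival_scale_per_subtype = survival_scale_per_subtype),
            class = "synth_config")
}

#' Standard synthetic study scenario
#'
#' The default multi-omics benchmark cohort: 45 samples, 2 subtypes, 4 layers
#' (mRNA, methylation, protein, miRNA) with effect size 2 and 40% discordant
#' samples on all layers except mRNA, so that single-layer clusterings
#' disagree with the truth while the fused clustering can recover it. mRNA is
#' the faithful layer: its biomarker panel is the one carried forward to
#' classification, cohort transfer and drug-response prediction, matching the
#' observation that mRNA panels transfer across cohorts.
#'
#' @param seed integer seed.
#' @param discordance discordance fraction for the three discordant layers.
#' @param effect_size standardized subtype shift of informative features.
#' @return a [synth_config()].
#' @export
standard_scenario <- function(seed = 1L, discordance = 0.4, effect_size = 2) {
  synth_config(
    n_samples = 45, n_subtypes = 2, seed = seed,
    layer_specs = list(
      layer_spec("mRNA",        400, 60, effect_size, 1, 0),
      layer_spec("methylation", 300, 45, effect_size, 1, discordance),
      layer_spec("protein",     120, 24, effect_size, 1, discordance),
      layer_spec("miRNA",       150, 30, effect_size, 1, discordance)),
    survival_scale_per_subtype = c(25, 12))
}

#' Generate a synthetic multi-omics cohort with planted subtypes
#'
#' Each layer is Gaussian noise of the requested standard deviation; the
#' informative features receive a subtype-specific mean shift of
#' `effect_size * noise_sd` between adjacent subtypes. In each layer, a
#' `discordance_fraction` of samples have their informative-feature sub-rows
#' permuted among themselves (marginal feature distributions preserved), so
#' that layer's own clustering disagrees with the truth. Discordant sample
#' sets are allocated to be as disjoint across layers as the cohort size
#' allows. Feature columns are shuffled after signal placement; the true
#' informative feature ids are recorded.
#'
#' @param config a [synth_config()].
#' @return a `synthetic_dataset` list with elements `layers` (list of
#'   [omics_layer()]), `true_labels` (named integer vector),
#'   `informative_features` and `discordant_samples` (per-layer character
#'   vectors of ground-truth metadata).
#' @export
generate_multiomics <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  k <- config$n_subtypes
  set.seed(config$seed)

  sample_ids <- sprintf("S%03d", seq_len(n))
  # balanced subtype assignment, shuffled
  labels <- sample(rep_len(seq_len(k), n))
  names(labels) <- sample_ids

  layers <- list()
  informative <- list()
  discordant <- list()
  discord_count <- integer(n)  # how many layers already made each sample discordant

  for (ls in config$layer_specs) {
    p <- ls$n_features
    m <- ls$n_informative
    X <- matrix(stats::rnorm(n * p, sd = ls$noise_sd), n, p)
    if (m > 0) {
      # adjacent subtypes differ by effect_size on the standardized scale
      centers <- (seq_len(k) - (k + 1) / 2) * ls$effect_size * ls$noise_sd
      X[, seq_len(m)] <- X[, seq_len(m)] + centers[labels]
    }
    # discordance: permute informative sub-rows of a subset of samples.
    # Sets are kept disjoint across layers as far as n allows; when the
    # cohort is too small for disjointness, the reused samples' blocks are
    # permuted within their own subtype, so no sample's informative signal
    # contradicts the truth in more than one layer and the consensus stays
    # recoverable (the scenario's defining property).
    n_disc <- floor(ls$discordance_fraction * n)
    disc <- integer(0)
    if (n_disc > 1 && m > 0) {
      ord <- order(discord_count, sample(n))
      disc <- ord[seq_len(n_disc)]
      fresh <- disc[discord_count[disc] == 0L]
      reused <- setdiff(disc, fresh)
      discord_count[disc] <- discord_count[disc] + 1L
      if (length(fresh) > 1)
        X[fresh, seq_len(m)] <- X[sample(fresh), seq_len(m)]
      for (s in unique(labels[reused])) {
        grp <- intersect(which(labels == s), reused)
        donors <- setdiff(which(labels == s), grp)
        # within-subtype block swap (marginals preserved, truth kept)
        X[grp, seq_len(m)] <- X[sample(donors, length(grp),
                                       replace = length(donors) < length(grp)),
                                seq_len(m)]
      }
      disc <- sort(disc)
    }
    discordant[[ls$layer_name]] <- sample_ids[disc]
    feature_ids <- sprintf("%s_f%04d", ls$layer_name, seq_len(p))
    shuffle <- sample(p)
    X <- X[, shuffle, drop = FALSE]
    colnames(X) <- feature_ids[shuffle]
    rownames(X) <- sample_ids
    layers[[ls$layer_name]] <- omics_layer(X, layer_name = ls$layer_name)
    informative[[ls$layer_name]] <- feature_ids[seq_len(m)]
  }

  structure(list(layers = layers, true_labels = labels,
                 informative_features = informative,
                 discordant_samples = discordant,
                 config = config),
            class = "synthetic_dataset")
}

#' Generate a synthetic cell-line drug-response panel
#'
#' Each drug's activity area is a subtype-specific mean plus Gaussian noise.
#' Per drug, a random direction decides which subtype is the sensitive one,
#' and drugs differ in how strongly they discriminate the subtypes: the
#' between-subtype separation of drug d is `subtype_effect` times a uniform
#' multiplier on (1.5, 3.5), so at the default settings the panel spans drugs
#' whose discriminated subtype falls clearly beyond the z = 0.8 sensitivity
#' boundary alongside drugs that sit near it — the agreement regime observed
#' in real activity-area panels.
#'
#' @param labels named integer vector of subtype labels per cell line.
#' @param n_drugs number of drugs (default 24).
#' @param subtype_effect scale of the between-subtype shift in activity-area
#'   units (per-drug separation = subtype_effect x U(1.5, 3.5)).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return a [drug_response_table()] with attribute `true_labels`.
#' @export
generate_drug_panel <- function(labels, n_drugs = 24, subtype_effect = 2,
                                noise_sd = 1, seed = 1L) {
  if (length(labels) == 0) stop("labels must be non-empty")
  if (n_drugs < 1) stop("n_drugs must be >= 1")
  set.seed(seed)
  n <- length(labels)
  k <- max(labels)
  drug_ids <- sprintf("drug%02d", seq_len(n_drugs))
  direction <- sample(c(-1, 1), n_drugs, replace = TRUE)
  separation <- subtype_effect * stats::runif(n_drugs, 1.5, 3.5)
  centers <- outer(seq_len(k) - (k + 1) / 2, direction * separation)
  activity <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * n_drugs, sd = noise_sd), n, n_drugs)
  dimnames(activity) <- list(names(labels), drug_ids)
  tab <- drug_response_table(activity)
  attr(tab, "true_labels") <- labels
  tab
}

#' Cell-line cohort scenario for drug-response benchmarking
#'
#' A single clean mRNA expression layer (no cross-platform discordance: that
#' mechanism emulates disagreement between molecular layers of the same
#' tumours, which has no counterpart in a one-layer cell-line panel) with the
#' same feature design as the standard tumour scenario.
#'
#' @param seed integer seed.
#' @param n_lines number of cell lines (default 45).
#' @param effect_size standardized subtype shift of informative features.
#' @return a [synth_config()].
#' @export
cell_line_scenario <- function(seed = 1L, n_lines = 45, effect_size = 2) {
  synth_config(n_samples = n_lines, n_subtypes = 2, seed = seed,
               layer_specs = list(layer_spec("mRNA", 400, 60, effect_size, 1, 0)),
               survival_scale_per_subtype = c(25, 12))
}

#' Generate subtype-dependent survival records
#'
#' Event times are exponential with a subtype-specific scale (mean event
#' time). Censoring is independent: a censoring time is drawn from an
#' independent exponential whose rate is calibrated so the expected censored
#' fraction equals `censor_rate` within each subtype, and the observed time
#' is the minimum of the two (so the Kaplan-Meier estimator stays unbiased).
#'
#' @param labels named integer subtype vector.
#' @param scales positive exponential scales, one per subtype.
#' @param censor_rate fraction in [0, 1].
#' @param seed integer seed.
#' @return data.frame with columns sample_id, time, event, group.
#' @export
generate_survival <- function(labels, scales, censor_rate = 0.2, seed = 1L) {
  if (any(scales <= 0)) stop("survival scales must be positive")
  if (length(scales) < max(labels)) stop("one scale needed per subtype")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  set.seed(seed)
  n <- length(labels)
  rate <- 1 / scales[labels]
  t_event <- stats::rexp(n, rate = rate)
  if (censor_rate > 0) {
    # competing exponentials: P(censored) = rate_c / (rate_c + rate)
    rate_c <- rate * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, rate = rate_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(sample_id = names(labels),
             time = pmin(t_event, t_cens),
             event = t_event <= t_cens,
             group = as.integer(labels),
             stringsAsFactors = FALSE)
}
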