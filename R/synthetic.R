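#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: 4 groups
#' (Ctrl, NonCax, PreCax, Cax) x 8 tissues x 4 replicates, lognormal
#' intensities, class-structured group effects, completely-at-random
#' missingness and sporadic high outliers. The non-cachectic tumour group
#' (NonCax) carries a zero effect in every default template.
#'
#' @param n_tissues number of tissues, taken in order from \code{TISSUES}
#' @param n_replicates replicates per (tissue, group)
#' @param groups ordered group labels
#' @param n_metabolites number of metabolites
#' @param class_proportions named fractions over \code{METABOLITE_CLASSES},
#'   summing to 1
#' @param effect_templates named list of per-group log-scale effect vectors;
#'   defaults to \code{\link{defaultEffectTemplates}}
#' @param template_weights sampling weights over template names for
#'   metabolites not captured by the class-linked rules
#' @param missing_rate fraction of cells set missing, in [0, 1)
#' @param outlier_rate fraction of cells spiked upwards, in [0, 1)
#' @param noise_sd residual standard deviation on the log scale
#' @param baseline_mean,baseline_sd log-scale distribution of metabolite
#'   baselines
#' @param censor_quantile optional left-censoring quantile; when non-NULL,
#'   missingness is intensity-dependent (cells below this per-metabolite
#'   quantile are preferentially dropped) instead of uniform
#' @param seed master seed; one RNG stream per tissue is derived from it
#' @return a \code{cohort_config} list
#' @export
cohortConfig <- function(n_tissues = 8L, n_replicates = 4L, groups = GROUPS,
                         n_metabolites = 200L,
                         class_proportions = c(
                           "amino acids" = 0.22, "carbohydrates" = 0.08,
                           "energy" = 0.15, "lipids" = 0.15,
                           "nucleosides" = 0.10,
                           "organoheterocyclic" = 0.10, "other" = 0.20),
                         effect_templates = defaultEffectTemplates(
                           n_groups = length(groups)),
                         template_weights = NULL,
                         missing_rate = 0.05, outlier_rate = 0.005,
                         noise_sd = 0.4,
                         baseline_mean = 11, baseline_sd = 1.5,
                         censor_quantile = NULL,
                         seed = 1L) {
  if (n_metabolites < 1L || n_replicates < 1L || n_tissues < 1L)
    stop("degenerate config: tissues, replicates and metabolites must be >= 1")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (!all(names(class_proportions) %in% METABOLITE_CLASSES))
    stop("unknown class in class_proportions")
  if (!all(vapply(effect_templates, length, 1L) == length(groups)))
    stop("every effect template must have one entry per group")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate not in [0,1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate not in [0,1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(template_weights)) {
    nms <- names(effect_templates)
    template_weights <- stats::setNames(rep(0.5 / max(1, length(nms) - 1),
                                            length(nms)), nms)
    if ("null" %in% nms) template_weights[["null"]] <- 0.5
  }
  structure(list(n_tissues = as.integer(n_tissues),
                 n_replicates = as.integer(n_replicates), groups = groups,
                 n_metabolites = as.integer(n_metabolites),
                 class_proportions = class_proportions,
                 effect_templates = effect_templates,
                 template_weights = template_weights,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 censor_quantile = censor_quantile,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-group effect templates
#'
#' Eight disease-progression scenarios over the (Ctrl, PreCax, Cax)
#' pseudo-time (early/late/gradual up or down, up-then-down, down-then-up)
#' plus a null template. NonCax is always 0: non-cachexia-inducing tumours
#' leave the metabolome essentially unaltered.
#'
#' @param effect_size log-scale magnitude of the full excursion
#' @param n_groups number of groups (must be 4)
#' @return named list of numeric vectors (Ctrl, NonCax, PreCax, Cax)
#' @export
defaultEffectTemplates <- function(effect_size = 1.5, n_groups = 4L) {
  stopifnot(n_groups == 4L)
  shape <- list(
    "early-up"     = c(0, 1, 1),
    "late-up"      = c(0, 0, 1),
    "gradual-up"   = c(0, 0.5, 1),
    "up-down"      = c(0, 1, 0),
    "early-down"   = c(0, -1, -1),
    "late-down"    = c(0, 0, -1),
    "gradual-down" = c(0, -0.5, -1),
    "down-up"      = c(0, -1, 0)
  )
  out <- lapply(shape, function(s)
    effect_size * c(s[1], 0, s[2], s[3]))  # Ctrl, NonCax, PreCax, Cax
  out$null <- c(0, 0, 0, 0)
  lapply(out, function(v) stats::setNames(v, GROUPS))
}

# Derived per-tissue seed, kept below 2^31.
tissueSeed <- function(seed, i) (seed + 7919L * i) %% .Machine$integer.max

#' Generate a synthetic multi-tissue cohort with recorded ground truth
#'
#' Intensities are lognormal: \code{exp(baseline + effect[group] +
#' N(0, noise_sd))}. Missing cells are injected completely at random at
#' \code{missing_rate} (or intensity-dependently when
#' \code{censor_quantile} is set); outlier cells are spiked by at least
#' \code{6 * noise_sd} on the log scale at \code{outlier_rate}. Each tissue
#' consumes its own RNG stream derived from the master seed, so adding
#' tissues does not perturb existing ones. Identical seeds give identical
#' output.
#'
#' @param config a \code{\link{cohortConfig}}
#' @return list with elements \code{data} (a raw-scale
#'   \linkS4class{MetaboSet} spanning all tissues) and \code{truth}
#'   (template assignment, flagged outlier cells, true log-scale group
#'   means)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n_met <- config$n_metabolites
  ids <- sprintf("met%04d", seq_len(n_met))
  cls <- sample(names(config$class_proportions), n_met, replace = TRUE,
                prob = config$class_proportions)
  formulas <- sprintf("C%dH%dN%dO%d", sample(2:10, n_met, TRUE),
                      sample(4:16, n_met, TRUE), sample(0:3, n_met, TRUE),
                      sample(1:7, n_met, TRUE))
  formulas <- gsub("N0", "", formulas)
  one_carbon_id <- rep(NA_integer_, n_met)
  oc_pool <- which(cls %in% c("amino acids", "other"))
  oc_pick <- oc_pool[seq_len(min(18L, length(oc_pool)))]
  one_carbon_id[oc_pick] <- seq_along(oc_pick)

  # class-linked template assignment: one-carbon products rise late in
  # cachexia, energy metabolites fall late; the rest draw from the weights
  tmpl_names <- names(config$effect_templates)
  assignment <- sample(tmpl_names, n_met, replace = TRUE,
                       prob = config$template_weights[tmpl_names])
  if ("late-down" %in% tmpl_names)
    assignment[cls == "energy" & stats::runif(n_met) < 0.7] <- "late-down"
  if ("late-up" %in% tmpl_names)
    assignment[!is.na(one_carbon_id)] <- "late-up"

  baseline <- stats::rnorm(n_met, config$baseline_mean, config$baseline_sd)
  eff <- do.call(rbind, config$effect_templates[assignment])
  true_means <- sweep(eff, 1L, baseline, "+")
  dimnames(true_means) <- list(ids, config$groups)

  metabolites <- data.frame(metabolite_id = ids, name = ids,
                            formula = formulas, cls = cls,
                            one_carbon_id = one_carbon_id)

  tissues <- TISSUES[seq_len(config$n_tissues)]
  all_values <- NULL
  all_samples <- NULL
  flagged <- data.frame(metabolite_id = character(), sample_id = character())
  for (ti in seq_along(tissues)) {
    tis <- tissues[ti]
    set.seed(tissueSeed(config$seed, ti))
    groups <- config$groups
    if (tis == "tumour") groups <- setdiff(groups, "Ctrl")
    sm <- expand.grid(replicate = seq_len(config$n_replicates),
                      group = groups, stringsAsFactors = FALSE)
    sm$tissue <- tis
    sm$sample_id <- sprintf("%s_%s_r%d", tis, sm$group, sm$replicate)
    n_s <- nrow(sm)
    mu <- true_means[, sm$group, drop = FALSE]
    v <- mu + matrix(stats::rnorm(n_met * n_s, 0, config$noise_sd),
                     n_met, n_s)
    # outlier spikes: at least 6 noise sds upward
    n_cells <- n_met * n_s
    n_out <- stats::rbinom(1L, n_cells, config$outlier_rate)
    out_idx <- sample.int(n_cells, n_out)
    v[out_idx] <- v[out_idx] +
      (6 + stats::rexp(n_out)) * config$noise_sd
    inten <- exp(v)
    # missingness: MCAR by default, left-censoring when requested
    if (is.null(config$censor_quantile)) {
      n_miss <- stats::rbinom(1L, n_cells, config$missing_rate)
      miss_idx <- sample(setdiff(seq_len(n_cells), out_idx),
                         min(n_miss, n_cells - n_out))
    } else {
      thr <- apply(inten, 1L, stats::quantile,
                   probs = config$censor_quantile, names = FALSE)
      p_cell <- ifelse(sweep(inten, 1L, thr, "<="),
                       min(1, config$missing_rate * 3), config$missing_rate / 3)
      draw <- matrix(stats::runif(n_cells), n_met, n_s) < p_cell
      miss_idx <- setdiff(which(draw), out_idx)
    }
    inten[miss_idx] <- NA_real_
    if (n_out) {
      rc <- arrayInd(out_idx, c(n_met, n_s))
      flagged <- rbind(flagged,
                       data.frame(metabolite_id = ids[rc[, 1]],
                                  sample_id = sm$sample_id[rc[, 2]]))
    }
    all_values <- cbind(all_values, inten)
    all_samples <- rbind(all_samples,
                         sm[, c("sample_id", "tissue", "group", "replicate")])
  }
  ms <- MetaboSet(all_values, all_samples, metabolites, scale = "raw")
  list(data = ms,
       truth = list(assignment = stats::setNames(assignment, ids),
                    flagged_outlier_cells = flagged,
                    true_group_means = true_means))
}

#' Simulate noisy steady-state labelling data from known fluxes
#'
#' Computes steady-state MDVs of the network's measured metabolites with
#' \code{\link{simulateMDVs}}, then per sample adds truncated Gaussian noise
#' (sd \code{mdv_noise_sd}, matching the 3\% mass-distribution-vector
#' standard error assumed by the flux fit) to each fraction, renormalizes to
#' sum 1 and scales to plausible MS intensities.
#'
#' @param network a \linkS4class{FluxNetwork}
#' @param true_fluxes named flux vector satisfying the network's balance
#'   constraints
#' @param mdv_noise_sd per-fraction noise sd, default 0.03
#' @param n_samples number of samples to draw
#' @param seed RNG seed
#' @param metabolites metabolites to report, default the network's measured
#'   set
#' @return list: \code{iso} (an \linkS4class{IsotopologueSet}),
#'   \code{mdv_noisy} (named list of per-sample noisy MDV lists),
#'   \code{true_fluxes} and \code{true_mdvs} for recovery tests
#' @export
generateLabelling <- function(network, true_fluxes, mdv_noise_sd = 0.03,
                              n_samples = 4L, seed = 1L,
                              metabolites = measuredMetabolites(network)) {
  checkFluxBalance(network, true_fluxes)
  mdvs <- simulateMDVs(network, true_fluxes, metabolites)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  rows <- list()
  mdv_noisy <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    sid <- sprintf("s%02d", s)
    total <- exp(stats::rnorm(1L, log(1e6), 0.2))
    mdv_noisy[[s]] <- lapply(mdvs, function(m) {
      noisy <- m + stats::rnorm(length(m), 0, mdv_noise_sd)
      noisy[noisy < 0] <- 0
      if (sum(noisy) == 0) noisy <- m
      noisy / sum(noisy)
    })
    for (met in names(mdvs)) {
      frac <- mdv_noisy[[s]][[met]]
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite_id = met, sample_id = sid,
        mass_shift = seq_along(frac) - 1L, intensity = frac * total)
    }
  }
  names(mdv_noisy) <- sprintf("s%02d", seq_len(n_samples))
  carbons <- metaboliteCarbons(network)[names(mdvs)]
  iso <- IsotopologueSet(do.call(rbind, rows), carbons)
  list(iso = iso, mdv_noisy = mdv_noisy,
       true_fluxes = true_fluxes, true_mdvs = mdvs)
}

#' Write small deterministic unit-test fixtures
#'
#' Known names: \code{"missingness_boundary"} (one metabolite at exactly
#' 4/16 missing, one at 5/16), \code{"rsd_ladder"} (10 metabolites with
#' strictly increasing relative standard deviations in a single condition)
#' and \code{"tukey_shift"} (4 groups x 4 replicates with the Cax mean
#' shifted by 5 residual sds).
#'
#' @param name fixture name
#' @param dir output directory
#' @return named list of file paths (values, samples, metabolites)
#' @export
generateToyFixture <- function(name, dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta_df <- function(ids) {
    data.frame(metabolite_id = ids, name = ids, formula = "C6H12O6",
               cls = "carbohydrates")
  }
  sample_df <- function(groups, reps) {
    sm <- expand.grid(replicate = seq_len(reps), group = groups,
                      stringsAsFactors = FALSE)
    data.frame(sample_id = sprintf("liver_%s_r%d", sm$group, sm$replicate),
               tissue = "liver", group = sm$group, replicate = sm$replicate)
  }
  write_fixture <- function(values, samples, metabolites) {
    paths <- list(
      values = file.path(dir, paste0(name, "_values.csv")),
      samples = file.path(dir, paste0(name, "_samples.csv")),
      metabolites = file.path(dir, paste0(name, "_metabolites.csv")))
    tab <- data.frame(metabolite_id = metabolites$metabolite_id, values,
                      check.names = FALSE)
    colnames(tab) <- c("metabolite_id", samples$sample_id)
    utils::write.csv(tab, paths$values, row.names = FALSE, quote = FALSE,
                     na = "NA")
    utils::write.csv(samples, paths$samples, row.names = FALSE, quote = FALSE)
    utils::write.csv(metabolites, paths$metabolites, row.names = FALSE,
                     quote = FALSE)
    paths
  }
  if (name == "missingness_boundary") {
    samples <- sample_df(GROUPS, 4L)          # 16 samples
    mets <- meta_df(c("met_at_boundary", "met_over_boundary", "met_clean"))
    v <- matrix(1000, 3L, 16L)
    v[1, 1:4] <- NA   # exactly 25%: retained under the strictly-greater rule
    v[2, 1:5] <- NA   # 31.25%: removed
    write_fixture(v, samples, mets)
  } else if (name == "rsd_ladder") {
    samples <- sample_df("Ctrl", 8L)          # one condition
    ids <- sprintf("rsd%02d", 1:10)
    u <- zStandardize(1:8)                    # mean 0, sd 1 pattern
    v <- t(vapply(1:10, function(i) 1000 * (1 + 0.05 * i * u),
                  numeric(8L)))               # RSD of row i is exactly 0.05 i
    write_fixture(v, samples, meta_df(ids))
  } else if (name == "tukey_shift") {
    samples <- sample_df(GROUPS, 4L)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(42L)
    base <- stats::rnorm(4L, mean = 7, sd = 0.3)
    logv <- numeric(16L)
    logv[samples$group == "Ctrl"] <- base
    logv[samples$group == "NonCax"] <- base  # identical control groups
    logv[samples$group == "PreCax"] <- stats::rnorm(4L, 7, 0.3)
    logv[samples$group == "Cax"] <- stats::rnorm(4L, 7, 0.3) + 5 * 0.3
    v <- matrix(exp(logv), 1L, 16L)
    write_fixture(v, samples, meta_df("met_shifted"))
  } else {
    stop("unknown fixture name: ", name)
  }
}
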