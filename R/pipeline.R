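#' Default pipeline configuration
#'
#' Nested parameter blocks per stage. Defaults reproduce the workflow's
#' stated constants: outlier mask at mean + 4 sd, missingness cut at 25\%,
#' RSD cut at the 80th percentile, 8 trajectory clusters, 3\% MDV standard
#' error, 95\% Monte-Carlo intervals, reference flux V12 = 100.
#'
#' @param seed master seed; per-stage seeds are derived from it
#' @return a \code{pipeline_config} list
#' @export
defaultConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    tissues = TISSUES,
    synthetic = list(n_tissues = 8L, n_replicates = 4L,
                     n_metabolites = 120L, missing_rate = 0.05,
                     outlier_rate = 0.005, noise_sd = 0.4),
    preprocess = list(outlier_sd_multiplier = 4, missing_fraction_max = 0.25,
                      rsd_percentile = 80, knn_k = 5L, log_base = "natural"),
    differential = list(alpha = 0.05, min_tissues = 2L,
                        require_direction = TRUE),
    trajectory = list(fuzzifier = 2, max_iter = 300L, tol = 1e-6,
                      min_membership = 0.5),
    labelling = list(method = "dunnett", tracer_purity = 1.0),
    mfa = list(mdv_se = 0.03, n_draws = 500L, ci_level = 0.95,
               n_starts = 10L, reference_value = 100,
               true_fluxes = c(V9 = 25, V11 = 40, V16 = 20))
  ), class = "pipeline_config")
}

# Allowed keys and numeric ranges, used by validateConfig.
configSchema <- function() {
  list(
    seed = c(1, .Machine$integer.max),
    tissues = NULL,
    synthetic = list(n_tissues = c(1, 8), n_replicates = c(1, Inf),
                     n_metabolites = c(1, Inf), missing_rate = c(0, 1),
                     outlier_rate = c(0, 1), noise_sd = c(1e-12, Inf)),
    preprocess = list(outlier_sd_multiplier = c(1e-12, Inf),
                      missing_fraction_max = c(0, 1),
                      rsd_percentile = c(1e-12, 100), knn_k = c(1, Inf),
                      log_base = NULL),
    differential = list(alpha = c(0, 1), min_tissues = c(1, Inf),
                        require_direction = NULL),
    trajectory = list(fuzzifier = c(1 + 1e-9, Inf), max_iter = c(1, Inf),
                      tol = c(0, Inf), min_membership = c(0, 1)),
    labelling = list(method = NULL, tracer_purity = c(1e-12, 1)),
    mfa = list(mdv_se = c(1e-12, 1), n_draws = c(1, Inf),
               ci_level = c(0, 1), n_starts = c(1, Inf),
               reference_value = c(1e-12, Inf), true_fluxes = NULL)
  )
}

#' Validate and default a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills unset values with the
#' documented defaults, rejects unknown keys fail-fast, and checks numeric
#' ranges; all schema violations are reported at once. An empty file yields
#' the full default configuration.
#'
#' @param path YAML file path, or NULL when \code{config} is given
#' @param config a list overriding defaults (alternative to \code{path})
#' @return a validated \code{pipeline_config}
#' @export
validateConfig <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    if (is.null(path)) stop("either path or config must be given")
    if (!file.exists(path)) stop("config file does not exist: ", path)
    config <- yaml::read_yaml(path)
    if (is.null(config)) config <- list()
  }
  defaults <- defaultConfig()
  schema <- configSchema()
  errors <- character()
  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown_top, collapse = ", ")))
  merged <- defaults
  for (k in intersect(names(config), names(schema))) {
    if (is.list(schema[[k]])) {
      unknown <- setdiff(names(config[[k]]), names(schema[[k]]))
      if (length(unknown))
        errors <- c(errors, paste0("unknown key(s) under ", k, ": ",
                                   paste(unknown, collapse = ", ")))
      for (kk in intersect(names(config[[k]]), names(schema[[k]]))) {
        val <- config[[k]][[kk]]
        rng <- schema[[k]][[kk]]
        if (!is.null(rng) && is.numeric(val) &&
            (any(val < rng[1]) || any(val > rng[2])))
          errors <- c(errors, sprintf("%s.%s = %s outside [%g, %g]",
                                      k, kk, toString(val), rng[1], rng[2]))
        merged[[k]][[kk]] <- val
      }
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  if (length(errors)) stop("invalid configuration:\n  ",
                           paste(errors, collapse = "\n  "))
  # YAML maps come back as lists; the flux truth is a named numeric vector
  merged$mfa$true_fluxes <- unlist(merged$mfa$true_fluxes)
  merged$tissues <- as.character(unlist(merged$tissues))
  class(merged) <- "pipeline_config"
  merged
}

# rbind data.frames whose columns differ (tumour lacks the Ctrl contrasts)
rbindFill <- function(a, b) {
  if (is.null(a)) return(b)
  cols <- union(colnames(a), colnames(b))
  for (cc in setdiff(cols, colnames(a))) a[[cc]] <- NA
  for (cc in setdiff(cols, colnames(b))) b[[cc]] <- NA
  rbind(a[, cols], b[, cols])
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f)
  unname(tools::md5sum(f))
}

# Formulas of the default network's measured metabolites, used to emulate
# and undo natural-abundance convolution in the synthetic labelling stage.
networkFormulas <- function() {
  data.frame(metabolite_id = c("CIT", "SUC", "FUM", "MAL", "OGA", "PYR"),
             formula = c("C6H8O7", "C4H6O4", "C4H4O4", "C4H6O5",
                         "C5H6O5", "C3H4O3"))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate, preprocess, differential + signature, trajectory
#' clustering, labelling summary and flux analysis in dependency order,
#' writes one CSV per result table and returns a manifest. Every stage
#' derives its seed from the master seed, so stages are individually
#' reproducible; the manifest carries the configuration hash. Identical
#' configuration and seed give identical result files.
#'
#' @param config a \code{pipeline_config} (see \code{\link{validateConfig}})
#' @param out_dir output directory
#' @param stages stages to run, default all
#' @return list: \code{manifest} (files written), \code{objects} (in-memory
#'   stage results), \code{log} (key=value stage summaries)
#' @export
runPipeline <- function(config = defaultConfig(), out_dir = tempfile("run"),
                        stages = c("simulate", "preprocess", "diff",
                                   "cluster", "labelling", "mfa")) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- configHash(config)
  log <- c(sprintf("config_hash=%s", hash),
           sprintf("seed=%d", config$seed))
  tables <- list(); objects <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeResults(tables, out_dir)  # persist partial outputs
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  cohort <- run_stage("simulate", {
    cc <- do.call(cohortConfig, c(config$synthetic,
                                  list(seed = config$seed)))
    generateCohort(cc)
  })
  objects$cohort <- cohort
  log <- c(log, sprintf("simulate: metabolites=%d samples=%d",
                        nrow(cohort$data), ncol(cohort$data)))
  if (!"preprocess" %in% stages)
    return(list(manifest = writeResults(tables, out_dir),
                objects = objects, log = log))

  pp <- config$preprocess
  params <- preprocessParams(pp$outlier_sd_multiplier, pp$missing_fraction_max,
                             pp$rsd_percentile, pp$knn_k, pp$log_base)
  tissues <- intersect(config$tissues,
                       unique(sampleData(cohort$data)$tissue))
  processed <- list(); diff_all <- NULL
  for (tis in tissues) {
    res <- run_stage("preprocess", {
      runPreprocess(tissueSubset(cohort$data, tis), params)
    })
    processed[[tis]] <- res
    log <- c(log, sprintf(
      "preprocess tissue=%s in=%d retained=%d masked=%d imputed=%d",
      tis, res$report$n_input, length(res$report$retained_ids),
      res$report$n_outlier_cells_masked, res$report$n_imputed_cells))
    if ("diff" %in% stages) {
      d <- run_stage("diff", differentialAnalysis(res$data))
      diff_all <- rbindFill(diff_all, d)
    }
  }
  objects$processed <- processed

  if ("diff" %in% stages && !is.null(diff_all)) {
    objects$differential <- diff_all
    tables$differential_contrasts <- diff_all
    sig <- run_stage("diff", crossTissueSignature(
      diff_all[diff_all$tissue != "tumour", ],
      alpha = config$differential$alpha,
      min_tissues = config$differential$min_tissues,
      require_direction = config$differential$require_direction))
    objects$signature <- sig
    tables$signature_up <- sig$up
    tables$signature_down <- sig$down
    log <- c(log, sprintf("diff: tested=%d signature_up=%d signature_down=%d",
                          nrow(diff_all), nrow(sig$up), nrow(sig$down)))
  }

  if ("cluster" %in% stages) {
    cl <- run_stage("cluster", {
      profiles <- do.call(rbind, lapply(tissues, function(tis)
        suppressWarnings(buildProfiles(processed[[tis]]$data))))
      clustering <- fuzzyCluster(profiles,
                                 fuzzifier = config$trajectory$fuzzifier,
                                 max_iter = config$trajectory$max_iter,
                                 tol = config$trajectory$tol)
      contrib <- contributionTables(clustering, profiles,
                                    metaboliteData(cohort$data),
                                    config$trajectory$min_membership)
      list(profiles = profiles, clustering = clustering, contrib = contrib)
    })
    objects$trajectory <- cl
    tables$cluster_centroids <- data.frame(cluster = SCENARIO_LABELS,
                                           centroids(cl$clustering))
    tables$cluster_members <- rankMembers(cl$clustering)
    tables$contrib_tissue <- as.data.frame(cl$contrib$tissue_by_cluster)
    tables$contrib_class <- as.data.frame(cl$contrib$cluster_by_class)
    log <- c(log, sprintf("cluster: profiles=%d assigned=%d xie_beni=%.4f",
                          nrow(cl$profiles), cl$contrib$n_assigned,
                          xieBeni(cl$clustering)))
  }

  if ("labelling" %in% stages || "mfa" %in% stages) {
    lab <- run_stage("labelling", {
      network <- defaultNetwork()
      truth <- completeFluxes(network, config$mfa$true_fluxes,
                              config$mfa$reference_value)
      n_rep <- config$synthetic$n_replicates
      groups <- c("Ctrl", "Cax")
      sets <- lapply(seq_along(groups), function(gi) {
        tf <- truth
        if (groups[gi] == "Cax") {   # cachectic shift: more PC, less V11
          tf <- completeFluxes(network,
                               config$mfa$true_fluxes * c(1.8, 0.6, 1.4),
                               config$mfa$reference_value)
        }
        generateLabelling(network, tf, config$mfa$mdv_se, n_rep,
                          seed = config$seed + 100L + gi)
      })
      names(sets) <- groups
      list(network = network, sets = sets)
    })
    samples <- do.call(rbind, lapply(names(lab$sets), function(g)
      data.frame(sample_id = paste(g, names(lab$sets[[g]]$mdv_noisy),
                                   sep = "_"),
                 tissue = "gastrocnemius", group = g)))
    mdvs <- do.call(rbind, lapply(names(lab$sets), function(g) {
      d <- isoTable(lab$sets[[g]]$iso)
      tot <- stats::ave(d$intensity,
                        paste(d$metabolite_id, d$sample_id), FUN = sum)
      data.frame(metabolite_id = d$metabolite_id,
                 sample_id = paste(g, d$sample_id, sep = "_"),
                 mass_shift = d$mass_shift, fraction = d$intensity / tot)
    }))
    objects$labelling_mdvs <- mdvs
    if ("labelling" %in% stages) {
      summ <- run_stage("labelling", summarizeLabelling(mdvs, samples))
      cmp <- run_stage("labelling", compareIsotopologues(
        mdvs, samples, control = "Ctrl",
        method = config$labelling$method))
      objects$labelling <- list(summary = summ, comparisons = cmp)
      tables$labelling_summary <- summ$summary
      tables$labelling_totals <- summ$labelled
      tables$isotopologue_tests <- cmp
      log <- c(log, sprintf("labelling: rows=%d tests=%d",
                            nrow(summ$summary), nrow(cmp)))
    }
    if ("mfa" %in% stages) {
      fits <- run_stage("mfa", {
        lapply(names(lab$sets), function(g) {
          mean_mdvs <- groupMeanMDVs(lab$sets[[g]]$mdv_noisy)
          fit <- fitFluxes(lab$network, mean_mdvs,
                           mdv_se = config$mfa$mdv_se,
                           n_starts = config$mfa$n_starts,
                           seed = config$seed + 200L,
                           reference_value = config$mfa$reference_value)
          monteCarloCI(lab$network, mean_mdvs, fit,
                       n_draws = config$mfa$n_draws,
                       level = config$mfa$ci_level,
                       seed = config$seed + 300L,
                       mdv_se = config$mfa$mdv_se)
        })
      })
      names(fits) <- names(lab$sets)
      objects$mfa <- fits
      flux_tab <- do.call(rbind, lapply(names(fits), function(g)
        data.frame(group = g, reaction = names(fluxes(fits[[g]])),
                   flux = unname(fluxes(fits[[g]])),
                   lower = fluxCI(fits[[g]])[, 1],
                   upper = fluxCI(fits[[g]])[, 2], row.names = NULL)))
      tables$flux_estimates <- flux_tab
      tables$flux_comparison <- compareFluxes(fits[[1]], fits[[2]])
      log <- c(log, sprintf("mfa: groups=%d ssr_ctrl=%.2f converged=%s",
                            length(fits), fits[[1]]@ssr,
                            all(vapply(fits, slot, TRUE, "converged"))))
    }
  }

  manifest <- writeResults(tables, out_dir)
  manifest$config_hash <- hash
  writeLines(log, file.path(out_dir, "pipeline.log"))
  list(manifest = manifest, objects = objects, log = log)
}

#' Average per-sample MDVs into group-mean MDVs
#'
#' @param mdv_list list (per sample) of named lists of MDVs
#' @return named list of mean MDVs, renormalized to sum 1
#' @export
groupMeanMDVs <- function(mdv_list) {
  mets <- names(mdv_list[[1]])
  out <- lapply(mets, function(m) {
    v <- Reduce(`+`, lapply(mdv_list, `[[`, m)) / length(mdv_list)
    v / sum(v)
  })
  names(out) <- mets
  out
}
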