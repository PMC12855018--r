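#' Preprocessing parameters
#'
#' Defaults reproduce the stated workflow thresholds: outlier masking above
#' mean + 4 sd, removal above 25\% missingness, removal above the 80th
#' RSD percentile in any condition, knn imputation with k = 5.
#'
#' @param outlier_sd_multiplier sd multiplier of the outlier mask
#' @param missing_fraction_max maximal tolerated missing fraction
#' @param rsd_percentile percentile of the per-condition RSD distribution
#' @param knn_k neighbours used by knn imputation
#' @param log_base \code{"natural"}, \code{"2"} or \code{"10"}
#' @export
preprocessParams <- function(outlier_sd_multiplier = 4,
                             missing_fraction_max = 0.25,
                             rsd_percentile = 80, knn_k = 5L,
                             log_base = "natural") {
  stopifnot(outlier_sd_multiplier > 0,
            missing_fraction_max >= 0, missing_fraction_max <= 1,
            rsd_percentile > 0, rsd_percentile <= 100, knn_k >= 1L)
  log_base <- match.arg(as.character(log_base), c("natural", "2", "10"))
  structure(list(outlier_sd_multiplier = outlier_sd_multiplier,
                 missing_fraction_max = missing_fraction_max,
                 rsd_percentile = rsd_percentile, knn_k = as.integer(knn_k),
                 log_base = log_base),
            class = "preprocess_params")
}

logBaseValue <- function(log_base) {
  switch(log_base, natural = exp(1), "2" = 2, "10" = 10)
}

#' Log-transform a raw-scale MetaboSet
#'
#' Missing cells stay missing; the raw matrix is kept as assay \code{"raw"}
#' because the RSD filter is defined on raw values. Zero or negative
#' observed values are a hard error — no silent pseudo-count.
#'
#' @param object raw-scale \linkS4class{MetaboSet}
#' @param base \code{"natural"} (default), \code{"2"} or \code{"10"}
#' @return log-scale MetaboSet
#' @export
logTransform <- function(object, base = "natural") {
  stopifnot(is(object, "MetaboSet"))
  if (valueScale(object) != "raw") stop("matrix is already log scale")
  base <- match.arg(as.character(base), c("natural", "2", "10"))
  v <- intensities(object)
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive intensity at (", rownames(v)[bad[1, 1]], ", ",
         colnames(v)[bad[1, 2]], "); log transform undefined")
  lg <- log(v, base = logBaseValue(base))
  out <- object
  assay(out, "intensity", withDimnames = FALSE) <- lg
  assays(out)[["raw"]] <- v
  out@valueScale <- "log"
  metadata(out)$log_base <- base
  validObject(out)
  out
}

#' Mask outliers above mean + multiplier * sd
#'
#' Per metabolite, within each tissue, mean and sd are taken over the
#' observed log-scale values of all that tissue's samples; cells strictly
#' greater than mean + multiplier * sd are set missing. One pass, no
#' iteration. With at most one observed value nothing is masked.
#'
#' @param object log-scale \linkS4class{MetaboSet}
#' @param multiplier sd multiplier, default 4
#' @return list: \code{data} (masked MetaboSet) and \code{masked}
#'   (data.frame of metabolite_id, sample_id)
#' @export
maskOutliers <- function(object, multiplier = 4) {
  stopifnot(is(object, "MetaboSet"), multiplier > 0)
  if (valueScale(object) != "log") stop("outlier mask expects log scale")
  v <- intensities(object)
  raw <- if ("raw" %in% assayNames(object)) assay(object, "raw") else NULL
  tis <- sampleData(object)$tissue
  masked <- NULL
  for (t in unique(tis)) {
    cols <- which(tis == t)
    sub <- v[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    thr <- mu + multiplier * sdv
    hit <- which(!is.na(sub) & sub > thr, arr.ind = TRUE)  # strict >
    if (nrow(hit)) {
      masked <- rbind(masked, data.frame(
        metabolite_id = rownames(v)[hit[, 1]],
        sample_id = colnames(v)[cols[hit[, 2]]]))
      v[cbind(hit[, 1], cols[hit[, 2]])] <- NA_real_
      if (!is.null(raw)) raw[cbind(hit[, 1], cols[hit[, 2]])] <- NA_real_
    }
  }
  out <- object
  assay(out, "intensity", withDimnames = FALSE) <- v
  if (!is.null(raw)) assays(out)[["raw"]] <- raw
  if (is.null(masked))
    masked <- data.frame(metabolite_id = character(), sample_id = character())
  list(data = out, masked = masked)
}

#' Remove metabolites with too many missing values
#'
#' A metabolite is removed iff its missing fraction over all samples is
#' strictly greater than \code{max_fraction} ("more than"): exactly 25\%
#' missing is retained under the default.
#'
#' @param object single-tissue \linkS4class{MetaboSet}
#' @param max_fraction default 0.25
#' @return list: \code{data}, \code{removed} (metabolite ids)
#' @export
filterMissingness <- function(object, max_fraction = 0.25) {
  stopifnot(is(object, "MetaboSet"))
  requireSingleTissue(object, "filterMissingness")
  v <- intensities(object)
  frac <- rowMeans(is.na(v))
  removed <- rownames(v)[frac > max_fraction]
  list(data = object[!rownames(v) %in% removed, ], removed = removed)
}

#' Remove metabolites with high relative standard deviation
#'
#' Per metabolite and condition (experimental group), RSD = sd/mean over the
#' observed raw-scale values; the cut sits at the stated percentile of each
#' condition's RSD distribution across metabolites (linear interpolation
#' between order statistics), and a metabolite is removed iff its RSD
#' strictly exceeds the threshold in at least one condition. A
#' (metabolite, condition) cell with fewer than 2 observed values
#' contributes no RSD.
#'
#' @param object single-tissue \linkS4class{MetaboSet}; raw values are taken
#'   from assay \code{"raw"} when log scale
#' @param percentile default 80
#' @return list: \code{data}, \code{removed}, \code{rsd} (long table)
#' @export
filterRSD <- function(object, percentile = 80) {
  stopifnot(is(object, "MetaboSet"))
  requireSingleTissue(object, "filterRSD")
  raw <- if (valueScale(object) == "log") {
    if (!"raw" %in% assayNames(object))
      stop("log-scale matrix without a 'raw' assay; RSD needs raw values")
    assay(object, "raw")
  } else intensities(object)
  grp <- sampleData(object)$group
  conds <- unique(grp)
  rsd <- sapply(conds, function(g) {
    sub <- raw[, grp == g, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    r <- apply(sub, 1L, stats::sd, na.rm = TRUE) /
      rowMeans(sub, na.rm = TRUE)
    r[n_obs < 2L] <- NA_real_
    r
  })
  rsd <- matrix(rsd, nrow = nrow(raw),
                dimnames = list(rownames(raw), conds))
  thr <- apply(rsd, 2L, function(col)
    if (all(is.na(col))) NA_real_
    else stats::quantile(col, percentile / 100, na.rm = TRUE,
                         type = RSD_QUANTILE_TYPE, names = FALSE))
  exceeds <- sweep(rsd, 2L, thr, ">")
  removed <- rownames(raw)[rowSums(exceeds, na.rm = TRUE) > 0]
  list(data = object[!rownames(raw) %in% removed, ], removed = removed,
       rsd = rsd)
}

#' knn imputation of remaining missing values
#'
#' For each missing cell, donors are the k nearest metabolite rows by
#' Euclidean distance over mutually observed samples, scaled by the number
#' of shared samples, among metabolites observed in the target sample; the
#' donors' unweighted mean fills the cell. A cell without any eligible
#' donor falls back to the metabolite's own observed mean and is recorded.
#'
#' @param object log-scale \linkS4class{MetaboSet} with every metabolite
#'   observed at least once
#' @param k number of donors, default 5
#' @return list: \code{data} (complete matrix), \code{imputed} (cells),
#'   \code{fallback} (cells imputed by the row mean)
#' @export
knnImpute <- function(object, k = 5L) {
  stopifnot(is(object, "MetaboSet"), k >= 1L)
  v <- intensities(object)
  if (any(rowSums(!is.na(v)) == 0L))
    stop("metabolite(s) with no observed value cannot be imputed")
  miss <- which(is.na(v), arr.ind = TRUE)
  imputed <- data.frame(metabolite_id = character(), sample_id = character())
  fallback <- imputed
  if (nrow(miss)) {
    filled <- v
    for (idx in seq_len(nrow(miss))) {
      i <- miss[idx, 1]; j <- miss[idx, 2]
      cand <- which(!is.na(v[, j]))
      cand <- setdiff(cand, i)
      d <- vapply(cand, function(r) {
        shared <- !is.na(v[i, ]) & !is.na(v[r, ])
        n <- sum(shared)
        if (n == 0L) return(Inf)
        sqrt(sum((v[i, shared] - v[r, shared])^2) / n)
      }, numeric(1))
      ok <- is.finite(d)
      if (!any(ok)) {
        filled[i, j] <- mean(v[i, ], na.rm = TRUE)
        fallback <- rbind(fallback, data.frame(
          metabolite_id = rownames(v)[i], sample_id = colnames(v)[j]))
      } else {
        don <- cand[ok][order(d[ok])][seq_len(min(k, sum(ok)))]
        filled[i, j] <- mean(v[don, j])
      }
      imputed <- rbind(imputed, data.frame(
        metabolite_id = rownames(v)[i], sample_id = colnames(v)[j]))
    }
    v <- filled
  }
  out <- object
  assay(out, "intensity", withDimnames = FALSE) <- v
  list(data = out, imputed = imputed, fallback = fallback)
}

#' Run the full preprocessing chain on one tissue
#'
#' Stages in order: log transform, outlier masking, missingness filter, RSD
#' filter, knn imputation.
#'
#' @param object raw-scale single-tissue \linkS4class{MetaboSet}
#' @param params a \code{\link{preprocessParams}}
#' @return list: \code{data} (log-scale, imputed) and \code{report}
#' @export
runPreprocess <- function(object, params = preprocessParams()) {
  stopifnot(is(object, "MetaboSet"), inherits(params, "preprocess_params"))
  requireSingleTissue(object, "runPreprocess")
  n_input <- nrow(object)
  lg <- logTransform(object, params$log_base)
  m <- maskOutliers(lg, params$outlier_sd_multiplier)
  f1 <- filterMissingness(m$data, params$missing_fraction_max)
  f2 <- filterRSD(f1$data, params$rsd_percentile)
  imp <- knnImpute(f2$data, params$knn_k)
  report <- structure(list(
    n_input = n_input,
    n_outlier_cells_masked = nrow(m$masked),
    n_removed_missingness = length(f1$removed),
    n_removed_rsd = length(f2$removed),
    n_imputed_cells = nrow(imp$imputed),
    n_fallback_cells = nrow(imp$fallback),
    retained_ids = rownames(imp$data),
    params = params), class = "preprocess_report")
  stopifnot(report$n_input - report$n_removed_missingness -
              report$n_removed_rsd == length(report$retained_ids))
  list(data = imp$data, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat(sprintf("  input metabolites        %d\n", x$n_input))
  cat(sprintf("  outlier cells masked     %d\n", x$n_outlier_cells_masked))
  cat(sprintf("  removed (missingness)    %d\n", x$n_removed_missingness))
  cat(sprintf("  removed (RSD)            %d\n", x$n_removed_rsd))
  cat(sprintf("  cells imputed            %d (%d by row-mean fallback)\n",
              x$n_imputed_cells, x$n_fallback_cells))
  cat(sprintf("  retained                 %d\n", length(x$retained_ids)))
  cat(sprintf("  params: outlier > mean + %g sd; missing > %g removed; RSD > p%g removed; knn k = %d (metabolite rows, unweighted donor mean)\n",
              x$params$outlier_sd_multiplier, x$params$missing_fraction_max,
              x$params$rsd_percentile, x$params$knn_k))
  invisible(x)
}

requireSingleTissue <- function(object, what) {
  tis <- unique(sampleData(object)$tissue)
  if (length(tis) != 1L)
    stop(what, " operates on a single tissue; found: ",
         paste(tis, collapse = ", "))
  invisible(tis)
}
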