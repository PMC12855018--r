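#' Classical one-way fixed-effects ANOVA
#'
#' @param values_by_group named list mapping group to a numeric vector;
#'   at least 2 groups with at least 2 observations each
#' @return list with \code{f_stat}, \code{p_anova} and a \code{degenerate}
#'   flag (zero within-group variance everywhere with unequal means, where
#'   p is reported as the 0 boundary)
#' @export
anovaOneway <- function(values_by_group) {
  checkGroups(values_by_group)
  v <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 1L)))
  ss_within <- sum(vapply(values_by_group,
                          function(x) sum((x - mean(x))^2), 0))
  means <- vapply(values_by_group, mean, 0)
  if (ss_within <= 0) {
    # zero within-group variance everywhere: boundary cases, flagged
    if (stats::var(means) > 0)
      return(list(f_stat = Inf, p_anova = 0, degenerate = TRUE))
    return(list(f_stat = 0, p_anova = 1, degenerate = FALSE))
  }
  fit <- stats::anova(stats::lm(v ~ g))
  list(f_stat = fit[["F value"]][1], p_anova = fit[["Pr(>F)"]][1],
       degenerate = FALSE)
}

#' Tukey honestly-significant-difference contrasts
#'
#' Studentized-range adjusted p-values for every unordered group pair;
#' unbalanced designs use the Tukey-Kramer form. Differences are reported
#' as (second minus first) in the pair label \code{"B-A"}.
#'
#' @inheritParams anovaOneway
#' @return data.frame with columns pair, group_a, group_b, diff, p_tukey
#' @export
tukeyContrasts <- function(values_by_group) {
  checkGroups(values_by_group)
  v <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 1L)),
              levels = names(values_by_group))
  hsd <- stats::TukeyHSD(stats::aov(v ~ g))$g
  pair <- rownames(hsd)
  parts <- strsplit(pair, "-", fixed = TRUE)
  data.frame(pair = pair,
             group_a = vapply(parts, `[`, "", 2L),
             group_b = vapply(parts, `[`, "", 1L),
             diff = unname(hsd[, "diff"]),
             p_tukey = unname(hsd[, "p adj"]))
}

checkGroups <- function(values_by_group) {
  if (!is.list(values_by_group) || is.null(names(values_by_group)))
    stop("values_by_group must be a named list")
  if (length(values_by_group) < 2L)
    stop("need at least 2 groups")
  n <- vapply(values_by_group, length, 1L)
  if (any(n < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(values_by_group)[n < 2L], collapse = ", "))
  invisible(TRUE)
}

#' Per-metabolite log2 fold change between two groups
#'
#' Group mean difference on the log-scale matrix converted to base-2 units.
#'
#' @param object log-scale, imputed \linkS4class{MetaboSet}
#' @param numerator_group,denominator_group group labels
#' @return named numeric vector per metabolite
#' @export
log2FoldChange <- function(object, numerator_group, denominator_group) {
  stopifnot(is(object, "MetaboSet"))
  if (valueScale(object) != "log") stop("log-scale matrix required")
  grp <- sampleData(object)$group
  if (!numerator_group %in% grp || !denominator_group %in% grp)
    stop("both groups must be present")
  v <- intensities(object)
  d <- rowMeans(v[, grp == numerator_group, drop = FALSE], na.rm = TRUE) -
    rowMeans(v[, grp == denominator_group, drop = FALSE], na.rm = TRUE)
  base <- metadata(object)$log_base
  if (is.null(base)) base <- "natural"
  d * log2(logBaseValue(base))
}

#' Per-tissue differential analysis (ANOVA + Tukey HSD)
#'
#' One row per metabolite: F statistic, ANOVA p and all pairwise Tukey
#' contrasts (columns \code{diff_B_A} / \code{p_B_A}), plus log2 fold
#' changes Cax/Ctrl and Cax/NonCax where those groups exist. Metabolites
#' with a group below 2 observations are skipped with a warning. No
#' across-metabolite multiplicity correction is applied; Tukey corrects
#' across contrasts only.
#'
#' @param object log-scale, imputed single-tissue \linkS4class{MetaboSet}
#' @return data.frame of per-metabolite results
#' @export
differentialAnalysis <- function(object) {
  stopifnot(is(object, "MetaboSet"))
  tissue <- requireSingleTissue(object, "differentialAnalysis")
  if (valueScale(object) != "log") stop("log-scale matrix required")
  v <- intensities(object)
  grp <- sampleData(object)$group
  groups <- intersect(GROUPS, unique(grp))
  out <- list(); skipped <- character()
  for (i in seq_len(nrow(v))) {
    vals <- lapply(groups, function(g) {
      x <- v[i, grp == g]; x[!is.na(x)]
    })
    names(vals) <- groups
    if (any(vapply(vals, length, 1L) < 2L)) {
      skipped <- c(skipped, rownames(v)[i]); next
    }
    an <- anovaOneway(vals)
    tk <- tukeyContrasts(vals)
    row <- data.frame(tissue = tissue, metabolite_id = rownames(v)[i],
                      f_stat = an$f_stat, p_anova = an$p_anova,
                      degenerate = an$degenerate)
    for (r in seq_len(nrow(tk))) {
      key <- paste0(tk$group_b[r], "_", tk$group_a[r])
      row[[paste0("diff_", key)]] <- tk$diff[r]
      row[[paste0("p_", key)]] <- tk$p_tukey[r]
    }
    out[[length(out) + 1L]] <- row
  }
  if (length(skipped))
    warning("skipped metabolite(s) with < 2 observations in a group: ",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  if (all(c("Cax", "Ctrl") %in% groups))
    res$log2fc_cax_ctrl <- log2FoldChange(object, "Cax", "Ctrl")[res$metabolite_id]
  if (all(c("Cax", "NonCax") %in% groups))
    res$log2fc_cax_noncax <- log2FoldChange(object, "Cax", "NonCax")[res$metabolite_id]
  rownames(res) <- NULL
  res
}

#' Cross-tissue cachexia signature
#'
#' A metabolite joins the up (down) signature iff, in at least two cachexia
#' target tissues (tumour excluded), both the Cax-Ctrl and Cax-NonCax Tukey
#' contrasts are significant at \code{alpha} and both differences are
#' positive (negative) in those same tissues. Direction agreement across
#' the two control comparisons is required by default; set
#' \code{require_direction = FALSE} to demand significance only.
#'
#' @param results data.frame rows from \code{\link{differentialAnalysis}}
#'   across tissues
#' @param alpha significance level, default 0.05
#' @param min_tissues minimum supporting tissues, default 2
#' @param require_direction require consistent sign in both contrasts
#' @return list with \code{up} and \code{down} data.frames
#'   (metabolite_id, tissues, n_tissues)
#' @export
crossTissueSignature <- function(results, alpha = 0.05, min_tissues = 2L,
                                 require_direction = TRUE) {
  stopifnot(is.data.frame(results))
  if (any(results$tissue == "tumour")) {
    warning("tumour results are excluded from the cross-tissue signature")
    results <- results[results$tissue != "tumour", , drop = FALSE]
  }
  need <- c("p_Cax_Ctrl", "diff_Cax_Ctrl", "p_Cax_NonCax", "diff_Cax_NonCax")
  if (!all(need %in% colnames(results)))
    stop("results must carry Cax-Ctrl and Cax-NonCax contrasts")
  sig <- results$p_Cax_Ctrl < alpha & results$p_Cax_NonCax < alpha
  up_dir <- results$diff_Cax_Ctrl > 0 & results$diff_Cax_NonCax > 0
  down_dir <- results$diff_Cax_Ctrl < 0 & results$diff_Cax_NonCax < 0
  if (!require_direction) {
    up_dir <- results$diff_Cax_Ctrl > 0
    down_dir <- results$diff_Cax_Ctrl < 0
  }
  collect <- function(flag) {
    hits <- results[sig & flag, c("metabolite_id", "tissue")]
    if (!nrow(hits))
      return(data.frame(metabolite_id = character(), tissues = character(),
                        n_tissues = integer()))
    spl <- split(hits$tissue, hits$metabolite_id)
    spl <- spl[vapply(spl, length, 1L) >= min_tissues]
    ids <- sort(names(spl))
    data.frame(metabolite_id = ids,
               tissues = vapply(ids, function(i)
                 paste(sort(spl[[i]]), collapse = ";"), ""),
               n_tissues = vapply(ids, function(i)
                 length(spl[[i]]), 1L),
               row.names = NULL)
  }
  list(up = collect(up_dir), down = collect(down_dir))
}
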