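#' Group-level isotopologue summaries
#'
#' Per (tissue, metabolite, group, mass shift): mean and standard error of
#' the isotopologue percentage across samples, plus the labelled total
#' (100 minus the mean M+0 percentage). Means of percentages equal
#' percentages of means only because each per-sample MDV sums to exactly
#' 100\%. Single-sample groups report SE 0 and are flagged.
#'
#' @param mdvs long data.frame (metabolite_id, sample_id, mass_shift,
#'   fraction) of corrected MDVs
#' @param samples data.frame with sample_id, tissue, group
#' @return list: \code{summary} (per-isotopologue table) and
#'   \code{labelled} (labelled-total table)
#' @export
summarizeLabelling <- function(mdvs, samples) {
  stopifnot(all(c("metabolite_id", "sample_id", "mass_shift", "fraction")
                %in% colnames(mdvs)))
  m <- merge(mdvs, samples[, c("sample_id", "tissue", "group")],
             by = "sample_id")
  if (anyNA(m$group))
    stop("sample(s) without group metadata")
  m$pct <- m$fraction * 100
  key <- list(tissue = m$tissue, metabolite_id = m$metabolite_id,
              group = m$group, mass_shift = m$mass_shift)
  agg <- stats::aggregate(m$pct, key, function(x)
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x)))
  summary <- data.frame(agg[, 1:4], mean_pct = agg$x[, "mean"],
                        sem = ifelse(agg$x[, "n"] > 1L, agg$x[, "sem"], 0),
                        n = as.integer(agg$x[, "n"]),
                        single_sample = agg$x[, "n"] == 1L)
  m0 <- summary[summary$mass_shift == 0L, ]
  labelled <- data.frame(m0[, c("tissue", "metabolite_id", "group")],
                         labelled_total = 100 - m0$mean_pct)
  ord <- order(summary$tissue, summary$metabolite_id, summary$group,
               summary$mass_shift)
  list(summary = summary[ord, ], labelled = labelled)
}

#' Per-isotopologue group comparisons versus the control
#'
#' For every (metabolite, mass shift), tests each group against the control
#' group. With more than two groups the parametric route is one-way ANOVA
#' with Dunnett's many-to-one adjustment; the non-parametric route is
#' Kruskal-Wallis with Dunn's rank comparisons versus control
#' (Bonferroni-adjusted). With exactly two groups a two-sample t test (or
#' rank-sum test) is used.
#'
#' @param mdvs long corrected MDV table (metabolite_id, sample_id,
#'   mass_shift, fraction)
#' @param samples data.frame with sample_id and group
#' @param control control group, default \code{"Ctrl"}
#' @param method \code{"dunnett"} (default) or \code{"kruskal"}
#' @return data.frame metabolite_id, mass_shift, group, p_value
#' @export
compareIsotopologues <- function(mdvs, samples, control = "Ctrl",
                                 method = c("dunnett", "kruskal")) {
  method <- match.arg(method)
  m <- merge(mdvs, samples[, c("sample_id", "group")], by = "sample_id")
  if (!control %in% m$group) stop("control group absent: ", control)
  out <- list()
  for (met in unique(m$metabolite_id)) {
    sub_met <- m[m$metabolite_id == met, ]
    for (k in unique(sub_met$mass_shift)) {
      sub <- sub_met[sub_met$mass_shift == k, ]
      tab <- table(sub$group)
      if (any(tab < 2L)) next
      g <- factor(sub$group,
                  levels = c(control, setdiff(unique(sub$group), control)))
      p <- if (method == "dunnett") dunnettP(sub$fraction, g)
           else dunnP(sub$fraction, g)
      out[[length(out) + 1L]] <- data.frame(
        metabolite_id = met, mass_shift = k,
        group = names(p), p_value = unname(p))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Dunnett many-to-one comparisons; control is the first factor level.
dunnettP <- function(v, g) {
  lev <- levels(g)
  if (length(lev) == 2L) {
    p <- stats::t.test(v[g == lev[2]], v[g == lev[1]],
                       var.equal = TRUE)$p.value
    return(stats::setNames(p, lev[2]))
  }
  if (stats::var(v) == 0)  # constant data: nothing to test
    return(stats::setNames(rep(1, length(lev) - 1L), lev[-1]))
  fit <- stats::aov(v ~ g, data = data.frame(v = v, g = g))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  s <- summary(gl, test = multcomp::adjusted("single-step"))
  p <- as.numeric(s$test$pvalues)
  stats::setNames(p, sub(" - .*$", "", names(s$test$coefficients)))
}

# Dunn's rank comparisons versus control after Kruskal-Wallis,
# Bonferroni-adjusted across the many-to-one family.
dunnP <- function(v, g) {
  lev <- levels(g)
  r <- rank(v)
  N <- length(v)
  ties <- table(v)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  z <- vapply(lev[-1], function(l)
    (mr[[l]] - mr[[lev[1]]]) /
      sqrt((N * (N + 1) / 12) * tie_corr * (1 / n[[l]] + 1 / n[[lev[1]]])),
    numeric(1))
  p <- pmin(1, 2 * stats::pnorm(-abs(z)) * (length(lev) - 1L))
  stats::setNames(p, lev[-1])
}

#' Aggregate labelled-isotopologue distribution per group
#'
#' Concatenates the labelled (k >= 1) isotopologue fractions of the chosen
#' metabolites, averages within group and renormalizes over the labelled
#' set, giving one distribution over (metabolite, k) per group.
#'
#' @param mdvs long corrected MDV table
#' @param samples data.frame with sample_id and group
#' @param metabolites metabolite ids to include; default all
#' @return data.frame group, metabolite_id, mass_shift, share (sums to 1
#'   per group); empty with a warning when nothing is labelled
#' @export
aggregateLabelledDistribution <- function(mdvs, samples,
                                          metabolites = unique(mdvs$metabolite_id)) {
  m <- merge(mdvs[mdvs$metabolite_id %in% metabolites &
                    mdvs$mass_shift >= 1L, ],
             samples[, c("sample_id", "group")], by = "sample_id")
  agg <- stats::aggregate(fraction ~ group + metabolite_id + mass_shift, m, mean)
  out <- do.call(rbind, lapply(split(agg, agg$group), function(d) {
    tot <- sum(d$fraction)
    if (tot == 0) return(NULL)
    d$share <- d$fraction / tot
    d[, c("group", "metabolite_id", "mass_shift", "share")]
  }))
  if (is.null(out) || !nrow(out)) {
    warning("no labelled isotopologues found")
    return(data.frame(group = character(), metabolite_id = character(),
                      mass_shift = integer(), share = numeric()))
  }
  out <- out[order(out$group, out$metabolite_id, out$mass_shift), ]
  rownames(out) <- NULL
  out
}
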