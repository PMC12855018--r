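#' FluxFit: result of a 13C flux fit
#'
#' Fluxes are on the reference-normalized scale (reference flux = 100).
#'
#' @slot fluxes named flux vector over all reactions
#' @slot free_flux_ids fitted free fluxes
#' @slot ssr weighted sum of squared residuals at the optimum
#' @slot dof degrees of freedom (fitted fractions minus free fluxes)
#' @slot chi2_p upper-tail chi-squared goodness-of-fit probability
#' @slot ci per-reaction confidence bounds (NA before
#'   \code{\link{monteCarloCI}})
#' @slot ci_level nominal level of the intervals
#' @slot n_monte_carlo Monte-Carlo draws behind the intervals
#' @slot ci_reliable FALSE when too many refits failed to converge
#' @slot converged optimizer convergence flag
#' @slot network the network fitted against
#' @export
setClass("FluxFit",
  slots = c(fluxes = "numeric", free_flux_ids = "character",
            ssr = "numeric", dof = "integer", chi2_p = "numeric",
            ci = "matrix", ci_level = "numeric",
            n_monte_carlo = "integer", ci_reliable = "logical",
            converged = "logical", network = "FluxNetwork"))

setMethod("show", "FluxFit", function(object) {
  cat("FluxFit:", length(object@fluxes), "fluxes (reference ",
      object@network@reference_flux_id, " = 100)\n", sep = "")
  cat(sprintf("  SSR = %.3f on %d dof, chi2 p = %.3g, converged = %s\n",
              object@ssr, object@dof, object@chi2_p, object@converged))
  tab <- data.frame(flux = round(object@fluxes, 2))
  if (!all(is.na(object@ci))) {
    tab$lower <- round(object@ci[, 1], 2)
    tab$upper <- round(object@ci[, 2], 2)
  }
  print(tab)
})

#' Fluxes of a fit
#' @param object a FluxFit
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname fluxes
#' @export
setMethod("fluxes", "FluxFit", function(object) object@fluxes)

#' Confidence intervals of a fit
#' @param object a FluxFit
#' @export
fluxCI <- function(object) {
  stopifnot(is(object, "FluxFit"))
  object@ci
}

flattenMDVs <- function(mdvs, order) {
  unlist(lapply(order, function(m) mdvs[[m]]), use.names = FALSE)
}

residualFactory <- function(network, measured, mdv_se, reference_value) {
  targets <- names(measured)
  meas <- flattenMDVs(measured, targets)
  n_res <- length(meas)
  function(theta) {
    names(theta) <- network@free_flux_ids
    v <- completeFluxes(network, theta, reference_value)
    viol <- -min(0, min(v))
    if (viol > 1e-9)    # infeasible: smooth uphill penalty
      return(rep(sqrt(1e4 * (1 + viol)), n_res))
    sim <- simulateMDVs(network, v, targets, check = FALSE)
    (flattenMDVs(sim, targets) - meas) / mdv_se
  }
}

drawFeasibleStarts <- function(network, n, lower, upper, reference_value) {
  nf <- length(network@free_flux_ids)
  starts <- list(); tries <- 0L
  while (length(starts) < n && tries < 200L * n) {
    tries <- tries + 1L
    theta <- stats::runif(nf, lower, upper)
    names(theta) <- network@free_flux_ids
    v <- try(completeFluxes(network, theta, reference_value), silent = TRUE)
    if (!inherits(v, "try-error") && all(v >= 0))
      starts[[length(starts) + 1L]] <- theta
  }
  if (!length(starts)) stop("no feasible flux vector found")
  starts
}

#' Fit fluxes to measured MDVs by weighted least squares
#'
#' Minimizes \eqn{\sum ((sim - meas)/se)^2} over the network's free fluxes
#' (non-negativity enforced, dependent fluxes from stoichiometric balance,
#' reference flux pinned at 100) with a Levenberg-Marquardt local search
#' from seeded random feasible multi-starts; the best optimum is kept, ties
#' resolved by the lowest start index. Reports SSR, degrees of freedom and
#' the chi-squared goodness-of-fit probability.
#'
#' @param network a \linkS4class{FluxNetwork}
#' @param measured named list of MDVs for network metabolites
#' @param mdv_se per-fraction standard error, default 0.03
#' @param n_starts random multi-starts, default 10
#' @param seed RNG seed for the starts
#' @param reference_value reported value of the reference flux, default 100
#' @param start optional named start values used as the first start
#' @param upper upper bound of the free fluxes, default
#'   \code{3 * reference_value}
#' @return a \linkS4class{FluxFit}
#' @export
fitFluxes <- function(network, measured, mdv_se = 0.03, n_starts = 10L,
                      seed = 1L, reference_value = 100, start = NULL,
                      upper = 3 * reference_value) {
  stopifnot(is(network, "FluxNetwork"), length(measured) >= 1L)
  bad <- setdiff(names(measured), names(network@carbons))
  if (length(bad))
    stop("measured metabolite(s) not in network: ", paste(bad, collapse = ", "))
  resid_fn <- residualFactory(network, measured, mdv_se, reference_value)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- drawFeasibleStarts(network, n_starts, 0, upper, reference_value)
  if (!is.null(start))
    starts <- c(list(stats::setNames(start[network@free_flux_ids],
                                     network@free_flux_ids)), starts)
  best <- NULL
  for (th in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = th, lower = rep(0, length(th)),
      upper = rep(upper, length(th)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  theta <- stats::setNames(best$par, network@free_flux_ids)
  v <- completeFluxes(network, theta, reference_value)
  n_frac <- length(flattenMDVs(measured, names(measured)))
  dof <- n_frac - length(theta)
  ssr <- best$deviance
  converged <- best$info %in% 1:4
  new("FluxFit", fluxes = v, free_flux_ids = network@free_flux_ids,
      ssr = ssr, dof = as.integer(dof),
      chi2_p = chi2GoodnessOfFit(ssr, dof),
      ci = matrix(NA_real_, length(v), 2L,
                  dimnames = list(names(v), c("lower", "upper"))),
      ci_level = NA_real_, n_monte_carlo = 0L, ci_reliable = NA,
      converged = converged, network = network)
}

#' Chi-squared goodness of fit
#'
#' Upper-tail probability of the chi-squared distribution with \code{dof}
#' degrees of freedom evaluated at the fit SSR.
#'
#' @param ssr weighted sum of squared residuals
#' @param dof degrees of freedom (must be >= 1: more fitted fractions than
#'   free fluxes)
#' @return probability
#' @export
chi2GoodnessOfFit <- function(ssr, dof) {
  if (dof < 1) stop("over-parameterized fit: dof must be >= 1")
  stats::pchisq(ssr, df = dof, lower.tail = FALSE)
}

#' Monte-Carlo confidence intervals for fitted fluxes
#'
#' Draws \code{n_draws} perturbed datasets (Gaussian noise of sd
#' \code{mdv_se} on each fraction, truncated at zero and renormalized),
#' refits each from the point estimate and takes per-flux percentile
#' intervals at the requested level on the reference-normalized scale.
#' Intervals are flagged unreliable when more than 20\% of refits fail to
#' converge.
#'
#' @param network a \linkS4class{FluxNetwork}
#' @param measured the measured MDVs that produced \code{fit}
#' @param fit a converged \linkS4class{FluxFit}
#' @param n_draws Monte-Carlo draws, default 500
#' @param level interval level, default 0.95
#' @param seed RNG seed
#' @param mdv_se per-fraction standard error, default 0.03
#' @return the fit with \code{ci}, \code{ci_level}, \code{n_monte_carlo}
#'   and \code{ci_reliable} filled in
#' @export
monteCarloCI <- function(network, measured, fit, n_draws = 500L,
                         level = 0.95, seed = 1L, mdv_se = 0.03) {
  stopifnot(is(fit, "FluxFit"))
  if (!fit@converged) stop("confidence intervals require a converged fit")
  theta0 <- fit@fluxes[fit@free_flux_ids]
  reference_value <- fit@fluxes[[network@reference_flux_id]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- matrix(NA_real_, n_draws, length(fit@fluxes),
                  dimnames = list(NULL, names(fit@fluxes)))
  n_fail <- 0L
  for (b in seq_len(n_draws)) {
    pert <- lapply(measured, function(m) {
      noisy <- m + stats::rnorm(length(m), 0, mdv_se)
      noisy[noisy < 0] <- 0
      if (sum(noisy) == 0) noisy <- m
      noisy / sum(noisy)
    })
    resid_fn <- residualFactory(network, pert, mdv_se, reference_value)
    refit <- try(minpack.lm::nls.lm(
      par = theta0, lower = rep(0, length(theta0)),
      upper = rep(3 * reference_value, length(theta0)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 50)), silent = TRUE)
    if (inherits(refit, "try-error") || !(refit$info %in% 1:4)) {
      n_fail <- n_fail + 1L
      next
    }
    th <- stats::setNames(refit$par, fit@free_flux_ids)
    draws[b, ] <- completeFluxes(network, th, reference_value)
  }
  ok <- stats::complete.cases(draws)
  alpha <- (1 - level) / 2
  ci <- t(apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE,
                type = RSD_QUANTILE_TYPE))
  colnames(ci) <- c("lower", "upper")
  out <- fit
  out@ci <- ci
  out@ci_level <- level
  out@n_monte_carlo <- as.integer(sum(ok))
  out@ci_reliable <- n_fail <= 0.2 * n_draws
  if (!out@ci_reliable)
    warning("more than 20% of Monte-Carlo refits failed to converge; ",
            "intervals flagged unreliable")
  out
}

#' Compare two fits by confidence-interval overlap
#'
#' Two fluxes differ significantly (P < 0.05 at 95\% intervals) iff their
#' intervals are disjoint.
#'
#' @param fit_a,fit_b \linkS4class{FluxFit} objects carrying intervals on
#'   the same network
#' @return data.frame reaction, estimate_a, estimate_b, significant
#' @export
compareFluxes <- function(fit_a, fit_b) {
  stopifnot(is(fit_a, "FluxFit"), is(fit_b, "FluxFit"))
  ids_a <- names(fit_a@fluxes); ids_b <- names(fit_b@fluxes)
  if (!identical(ids_a, ids_b))
    stop("fits are not on the same network")
  if (all(is.na(fit_a@ci)) || all(is.na(fit_b@ci)))
    stop("both fits must carry Monte-Carlo confidence intervals")
  disjoint <- fit_a@ci[, "upper"] < fit_b@ci[, "lower"] |
    fit_b@ci[, "upper"] < fit_a@ci[, "lower"]
  data.frame(reaction = ids_a,
             estimate_a = unname(fit_a@fluxes),
             estimate_b = unname(fit_b@fluxes),
             significant = unname(disjoint), row.names = NULL)
}
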