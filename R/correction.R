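#' Parse an elemental formula in Hill notation
#'
#' @param formula string such as \code{"C6H8O7"}; element symbols followed by
#'   optional counts. Isotopic labelling never appears in formulas.
#' @return named integer vector of element counts
#' @export
#' @examples
#' parseFormula("C6H12O6")
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  counts <- tapply(n, el, sum)
  structure(as.integer(counts), names = names(counts))
}

#' Carbon count of a formula string
#' @param formula Hill-notation formula
#' @export
carbonCount <- function(formula) {
  f <- parseFormula(formula)
  if ("C" %in% names(f)) unname(f[["C"]]) else 0L
}

#' Correction model for natural abundance and tracer purity
#'
#' @param formula Hill-notation elemental formula of the (unlabelled)
#'   metabolite
#' @param tracer_element element carrying the tracer (default \code{"C"})
#' @param tracer_purity isotopic purity of the tracer in (0, 1]; default 1
#' @param isotope_abundances per-element natural abundance vectors indexed by
#'   mass shift; defaults to \code{\link{ISOTOPE_ABUNDANCES}}
#' @return an object of class \code{correction_model}
#' @export
correctionModel <- function(formula, tracer_element = "C",
                            tracer_purity = 1.0,
                            isotope_abundances = ISOTOPE_ABUNDANCES) {
  counts <- parseFormula(formula)
  if (!tracer_element %in% names(counts) || counts[[tracer_element]] < 1L)
    stop("formula must contain at least one atom of tracer element ",
         tracer_element)
  if (!(tracer_purity > 0 && tracer_purity <= 1))
    stop("tracer_purity must be in (0, 1]")
  for (e in names(isotope_abundances)) {
    if (abs(sum(isotope_abundances[[e]]) - 1) > 1e-9)
      stop("abundance vector for ", e, " does not sum to 1")
  }
  unknown <- setdiff(names(counts), names(isotope_abundances))
  if (length(unknown))
    stop("no isotope abundance table for element(s): ",
         paste(unknown, collapse = ", "))
  structure(list(formula = formula, counts = counts,
                 tracer_element = tracer_element,
                 tracer_purity = tracer_purity,
                 isotope_abundances = isotope_abundances),
            class = "correction_model")
}

# n-fold self-convolution of a mass-shift distribution
convPower <- function(p, n) {
  out <- 1
  for (i in seq_len(n)) out <- convolve(out, rev(p), type = "open")
  # convolve() can leave tiny negative round-off
  out[out < 0] <- 0
  out
}

#' Build the isotopologue correction matrix
#'
#' Column \code{j} (0-based) is the expected measured mass-shift distribution
#' of a species carrying exactly \code{j} tracer-derived labels: the
#' convolution of (a) the natural-abundance mass-shift distribution of all
#' non-tracer elements, (b) the natural-abundance distribution of the
#' \code{C - j} unlabelled tracer-element positions and (c) the binomial
#' purity distribution of the \code{j} labelled positions. Rows beyond mass
#' shift \code{C} are truncated, so columns sum to at most 1. This is the
#' low-resolution regime in which every element contributes to the measured
#' mass shifts.
#'
#' @param model a \code{\link{correctionModel}}
#' @return dense (C+1) x (C+1) matrix
#' @export
correctionMatrix <- function(model) {
  stopifnot(inherits(model, "correction_model"))
  counts <- model$counts
  tr <- model$tracer_element
  C <- counts[[tr]]
  purity <- model$tracer_purity
  ab <- model$isotope_abundances
  # (a) all non-tracer elements
  nontracer <- 1
  for (e in setdiff(names(counts), tr)) {
    nontracer <- convolve(nontracer, rev(convPower(ab[[e]], counts[[e]])),
                          type = "open")
  }
  nontracer[nontracer < 0] <- 0
  M <- matrix(0, C + 1L, C + 1L)
  for (j in 0:C) {
    col <- nontracer
    if (C - j > 0)  # (b) unlabelled tracer positions
      col <- convolve(col, rev(convPower(ab[[tr]], C - j)), type = "open")
    if (j > 0)      # (c) labelled positions: binomial over shifts 0..j
      col <- convolve(col, rev(stats::dbinom(0:j, j, purity)), type = "open")
    col[col < 0] <- 0
    M[, j + 1L] <- col[seq_len(C + 1L)]  # truncate beyond mass shift C
  }
  dimnames(M) <- list(paste0("M+", 0:C), paste0("x", 0:C))
  M
}

#' Correct a measured isotopologue vector for natural abundance and purity
#'
#' Solves \code{raw = M x} for \code{x >= 0} by non-negative least squares
#' and returns the solution normalized to sum 1 (a mass isotopomer
#' distribution vector). Invariant to uniform scaling of the input.
#'
#' @param raw_intensities non-negative vector of length C+1 (M+0..M+C)
#' @param model a \code{\link{correctionModel}}
#' @return numeric MDV of length C+1 summing to 1
#' @export
correctMDV <- function(raw_intensities, model) {
  stopifnot(inherits(model, "correction_model"))
  C <- model$counts[[model$tracer_element]]
  if (length(raw_intensities) != C + 1L)
    stop("expected ", C + 1L, " intensities for formula ", model$formula)
  if (any(raw_intensities < 0)) stop("negative isotopologue intensity")
  if (all(raw_intensities == 0)) stop("all-zero isotopologue vector")
  M <- correctionMatrix(model)
  x <- pracma::lsqnonneg(M, as.numeric(raw_intensities))$x
  if (sum(x) <= 0) stop("correction produced an all-zero vector")
  x / sum(x)
}

#' Mean fractional enrichment of an MDV
#'
#' \eqn{\sum_k k f_k / C}: 0 for unlabelled, 1 for fully labelled.
#'
#' @param mdv fractional MDV of length C+1
#' @return fraction in [0, 1]
#' @export
meanEnrichment <- function(mdv) {
  assertMDV(mdv)
  C <- length(mdv) - 1L
  sum((0:C) * mdv) / C
}

#' Isotopologue percentages of an MDV
#' @param mdv fractional MDV
#' @return vector of percentages summing to 100
#' @export
percentIsotopologues <- function(mdv) {
  assertMDV(mdv)
  mdv * 100
}

assertMDV <- function(mdv) {
  if (any(mdv < 0)) stop("MDV fractions must be non-negative")
  if (abs(sum(mdv) - 1) > 1e-6) stop("MDV fractions must sum to 1")
  invisible(mdv)
}

#' Correct all vectors of an IsotopologueSet
#'
#' @param iso an \linkS4class{IsotopologueSet}
#' @param metabolites data.frame with columns metabolite_id and formula
#' @param tracer_purity tracer purity, default 1
#' @return long data.frame (metabolite_id, sample_id, mass_shift, fraction)
#' @export
correctIsotopologues <- function(iso, metabolites, tracer_purity = 1.0) {
  stopifnot(is(iso, "IsotopologueSet"))
  d <- isoTable(iso)
  pairs <- unique(d[, c("metabolite_id", "sample_id")])
  models <- new.env(parent = emptyenv())
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    met <- pairs$metabolite_id[i]
    if (is.null(models[[met]])) {
      f <- metabolites$formula[match(met, metabolites$metabolite_id)]
      if (is.na(f)) stop("no formula for metabolite ", met)
      models[[met]] <- correctionModel(f, tracer_purity = tracer_purity)
    }
    v <- isoVector(iso, met, pairs$sample_id[i])
    mdv <- correctMDV(v, models[[met]])
    data.frame(metabolite_id = met, sample_id = pairs$sample_id[i],
               mass_shift = seq_along(mdv) - 1L, fraction = mdv)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
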