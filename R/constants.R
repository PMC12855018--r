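#' @title Pipeline constants
#' @description Enumerations and natural-isotope abundance tables shared by
#'   the whole package. All tunable defaults that mirror the study design
#'   (thresholds, reference flux, measurement error) live here so tests can
#'   pin them in one place.
#' @name constants
NULL

#' Recognised tissues, in canonical order
#' @export
TISSUES <- c("plasma", "liver", "eWAT", "iWAT", "heart",
             "gastrocnemius", "soleus", "tumour")

#' Experimental groups in pseudo-time order
#' @export
GROUPS <- c("Ctrl", "NonCax", "PreCax", "Cax")

#' Metabolite classes
#' @export
METABOLITE_CLASSES <- c("amino acids", "carbohydrates", "energy", "lipids",
                        "nucleosides", "organoheterocyclic", "other")

# Cachexia target tissues = all non-tumour tissues
targetTissues <- function() setdiff(TISSUES, "tumour")

#' Natural isotope abundance tables
#'
#' Per element, a vector of fractional abundances indexed by mass shift
#' (element 1 = shift 0). Values are the standard terrestrial abundances;
#' carbon-13 is 0.0107.
#'
#' @export
ISOTOPE_ABUNDANCES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  P = c(1.0),
  S = c(0.9499, 0.0075, 0.0425, 0.0, 0.0001)
)

# Quantile convention used by the RSD filter and its test oracle:
# linear interpolation between order statistics (stats::quantile type 7).
RSD_QUANTILE_TYPE <- 7L

# Scenario labels for the eight trajectory clusters, fixed order.
SCENARIO_LABELS <- c("early-up", "late-up", "gradual-up", "up-down",
                     "early-down", "late-down", "gradual-down", "down-up")

# Raw 3-point shapes (baseline, pre-cachectic, cachectic) for each scenario;
# standardized before use.
scenarioTemplates <- function() {
  shapes <- rbind(
    "early-up"     = c(0, 1, 1),
    "late-up"      = c(0, 0, 1),
    "gradual-up"   = c(0, 0.5, 1),
    "up-down"      = c(0, 1, 0),
    "early-down"   = c(1, 0, 0),
    "late-down"    = c(1, 1, 0),
    "gradual-down" = c(1, 0.5, 0),
    "down-up"      = c(1, 0, 1)
  )
  t(apply(shapes, 1L, zStandardize))
}

# z-standardize a vector to mean 0, sd 1 (sample sd).
zStandardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant profile")
  (x - mean(x)) / s
}
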