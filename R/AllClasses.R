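#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assays<- assayNames rowData colData
NULL

# ---------------------------------------------------------------------------
# MetaboSet: metabolites x samples intensities with sample/metabolite metadata
# ---------------------------------------------------------------------------

#' MetaboSet: a metabolite intensity matrix with metadata
#'
#' Extends \linkS4class{SummarizedExperiment}; rows are metabolites, columns
#' samples. The \code{"intensity"} assay holds the working values (raw or
#' log scale, see \code{valueScale}); after log transformation the raw-scale
#' matrix is carried alongside as assay \code{"raw"} because the
#' relative-standard-deviation filter is defined on raw values.
#'
#' Column data must provide \code{sample_id}, \code{tissue}, \code{group}
#' and \code{replicate}; row data must provide \code{metabolite_id},
#' \code{name}, \code{formula} (Hill notation), \code{cls} and optionally
#' \code{one_carbon_id}. Missing measurements are \code{NA}; zero is a
#' legitimate intensity, distinct from missing.
#'
#' @slot valueScale either \code{"raw"} or \code{"log"}
#' @export
setClass("MetaboSet",
  contains = "SummarizedExperiment",
  slots = c(valueScale = "character"),
  prototype = prototype(valueScale = "raw")
)

setValidity("MetaboSet", function(object) {
  msg <- character()
  if (!object@valueScale %in% c("raw", "log"))
    msg <- c(msg, "valueScale must be 'raw' or 'log'")
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  cd <- colData(object)
  need <- c("sample_id", "tissue", "group", "replicate")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  } else {
    if (!all(cd$tissue %in% TISSUES))
      msg <- c(msg, "unknown tissue in colData")
    if (!all(cd$group %in% GROUPS))
      msg <- c(msg, "unknown group in colData")
    key <- paste(cd$tissue, cd$group, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "(tissue, group, replicate) triples must be unique")
    if (any(cd$tissue == "tumour" & cd$group == "Ctrl"))
      msg <- c(msg, "tumour tissue cannot carry group Ctrl")
    if (any(cd$replicate < 1))
      msg <- c(msg, "replicate must be a positive integer")
  }
  rd <- rowData(object)
  rneed <- c("metabolite_id", "name", "formula", "cls")
  if (!all(rneed %in% colnames(rd))) {
    msg <- c(msg, paste("rowData must contain:", paste(rneed, collapse = ", ")))
  } else {
    if (anyDuplicated(rd$metabolite_id))
      msg <- c(msg, "duplicate metabolite_id in rowData")
    if (!all(rd$cls %in% METABOLITE_CLASSES))
      msg <- c(msg, "unknown metabolite class in rowData")
    if ("one_carbon_id" %in% colnames(rd)) {
      oc <- rd$one_carbon_id
      bad <- !is.na(oc) & (oc < 1 | oc > 18)
      if (any(bad)) msg <- c(msg, "one_carbon_id must be in 1..18")
    }
  }
  if (object@valueScale == "raw") {
    v <- assay(object, "intensity")
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, "raw-scale intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboSet
#'
#' @param values numeric matrix, metabolites x samples; \code{NA} marks
#'   missing cells
#' @param samples data.frame of sample metadata (sample_id, tissue, group,
#'   replicate), one row per column of \code{values}
#' @param metabolites data.frame of metabolite metadata (metabolite_id, name,
#'   formula, cls, optionally one_carbon_id), one row per row of \code{values}
#' @param scale \code{"raw"} (default) or \code{"log"}
#' @return a validated \linkS4class{MetaboSet}
#' @export
MetaboSet <- function(values, samples, metabolites, scale = "raw") {
  values <- as.matrix(values)
  samples <- as.data.frame(samples)
  metabolites <- as.data.frame(metabolites)
  if (nrow(values) != nrow(metabolites))
    stop("values rows must match metabolite metadata rows")
  if (ncol(values) != nrow(samples))
    stop("values columns must match sample metadata rows")
  rownames(values) <- metabolites$metabolite_id
  colnames(values) <- samples$sample_id
  se <- SummarizedExperiment(
    assays = list(intensity = values),
    rowData = DataFrame(metabolites, row.names = metabolites$metabolite_id),
    colData = DataFrame(samples, row.names = samples$sample_id)
  )
  new("MetaboSet", se, valueScale = scale)
}

#' @describeIn MetaboSet scale of the intensity assay ("raw" or "log")
#' @param object,x a MetaboSet
#' @export
setGeneric("valueScale", function(object) standardGeneric("valueScale"))

#' @rdname MetaboSet
#' @export
setMethod("valueScale", "MetaboSet", function(object) object@valueScale)

#' Intensity matrix accessor
#' @param object a MetaboSet
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname MetaboSet
#' @export
setMethod("intensities", "MetaboSet", function(object) assay(object, "intensity"))

#' Sample metadata as a plain data.frame
#' @param object a MetaboSet
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname MetaboSet
#' @export
setMethod("sampleData", "MetaboSet",
          function(object) as.data.frame(colData(object)))

#' Metabolite metadata as a plain data.frame
#' @param object a MetaboSet
#' @export
setGeneric("metaboliteData", function(object) standardGeneric("metaboliteData"))

#' @rdname MetaboSet
#' @export
setMethod("metaboliteData", "MetaboSet",
          function(object) as.data.frame(rowData(object)))

setMethod("show", "MetaboSet", function(object) {
  cat("MetaboSet:", nrow(object), "metabolites x", ncol(object), "samples\n")
  cat("  scale:", object@valueScale,
      " tissues:", paste(unique(colData(object)$tissue), collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(assay(object, "intensity"))), "\n")
})

#' Subset a MetaboSet to one tissue
#' @param object a MetaboSet
#' @param tissue tissue name
#' @return MetaboSet restricted to that tissue's samples
#' @export
tissueSubset <- function(object, tissue) {
  stopifnot(is(object, "MetaboSet"))
  if (!tissue %in% colData(object)$tissue)
    stop("tissue not present: ", tissue)
  object[, colData(object)$tissue == tissue]
}

# ---------------------------------------------------------------------------
# IsotopologueSet: per (metabolite, sample) dense M+0..M+C intensity vectors
# ---------------------------------------------------------------------------

#' IsotopologueSet: isotopologue intensities per metabolite and sample
#'
#' Stores a dense long table (metabolite_id, sample_id, mass_shift,
#' intensity): for every (metabolite, sample) pair present, all mass shifts
#' M+0..M+C appear, where C is the metabolite's carbon count.
#'
#' @slot data long-format data.frame
#' @slot carbons named integer vector of carbon counts per metabolite
#' @export
setClass("IsotopologueSet",
  slots = c(data = "data.frame", carbons = "integer"))

setValidity("IsotopologueSet", function(object) {
  d <- object@data
  need <- c("metabolite_id", "sample_id", "mass_shift", "intensity")
  if (!all(need %in% colnames(d)))
    return(paste("data must contain:", paste(need, collapse = ", ")))
  if (any(d$intensity < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  if (!all(d$metabolite_id %in% names(object@carbons)))
    return("metabolite without carbon count")
  cmax <- object@carbons[d$metabolite_id]
  if (any(d$mass_shift > cmax))
    return("mass_shift exceeds carbon count")
  # density: each (met, sample) pair has exactly C+1 rows
  n <- tapply(d$mass_shift, paste(d$metabolite_id, d$sample_id, sep = "\r"),
              length)
  met <- sub("\r.*$", "", names(n))
  if (any(n != object@carbons[met] + 1L))
    return("each (metabolite, sample) pair must carry mass shifts 0..C")
  TRUE
})

#' Construct an IsotopologueSet from a long table
#'
#' Absent mass shifts are densified to zero intensity.
#'
#' @param data data.frame with metabolite_id, sample_id, mass_shift, intensity
#' @param carbons named integer vector of per-metabolite carbon counts
#' @export
IsotopologueSet <- function(data, carbons) {
  data <- as.data.frame(data)
  carbons <- structure(as.integer(carbons), names = names(carbons))
  miss <- setdiff(unique(data$metabolite_id), names(carbons))
  if (length(miss))
    stop("no carbon count for metabolite(s): ", paste(miss, collapse = ", "))
  bad <- data$mass_shift > carbons[data$metabolite_id]
  if (any(bad))
    stop("mass_shift exceeds carbon count for metabolite(s): ",
         paste(unique(data$metabolite_id[bad]), collapse = ", "))
  pairs <- unique(data[, c("metabolite_id", "sample_id")])
  dense <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(metabolite_id = pairs$metabolite_id[i],
               sample_id = pairs$sample_id[i],
               mass_shift = 0:carbons[[pairs$metabolite_id[i]]])
  }))
  m <- merge(dense, data, by = c("metabolite_id", "sample_id", "mass_shift"),
             all.x = TRUE, sort = FALSE)
  m$intensity[is.na(m$intensity)] <- 0
  m <- m[order(m$metabolite_id, m$sample_id, m$mass_shift), ]
  rownames(m) <- NULL
  new("IsotopologueSet", data = m,
      carbons = carbons[intersect(names(carbons), unique(m$metabolite_id))])
}

#' Extract one isotopologue intensity vector
#' @param object an IsotopologueSet
#' @param metabolite,sample identifiers
#' @return numeric vector of length C+1 (M+0..M+C)
#' @export
isoVector <- function(object, metabolite, sample) {
  stopifnot(is(object, "IsotopologueSet"))
  d <- object@data
  rows <- d$metabolite_id == metabolite & d$sample_id == sample
  if (!any(rows)) stop("no entry for (", metabolite, ", ", sample, ")")
  v <- d$intensity[rows][order(d$mass_shift[rows])]
  v
}

#' Long-format accessor
#' @param object an IsotopologueSet
#' @export
isoTable <- function(object) {
  stopifnot(is(object, "IsotopologueSet"))
  object@data
}

#' Carbon counts accessor
#' @param object an IsotopologueSet
#' @export
isoCarbons <- function(object) object@carbons

setMethod("show", "IsotopologueSet", function(object) {
  d <- object@data
  cat("IsotopologueSet:", length(unique(d$metabolite_id)), "metabolites x",
      length(unique(d$sample_id)), "samples,", nrow(d), "rows\n")
})
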