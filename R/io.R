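#' Read a wide intensity table with its metadata
#'
#' The intensity file is a wide CSV/TSV with a \code{metabolite_id} first
#' column and one column per sample; empty cells and \code{"NA"} are missing.
#' Metadata files are keyed by \code{sample_id} / \code{metabolite_id}.
#'
#' @param path intensity matrix file (.csv or .tsv)
#' @param sample_meta_path sample metadata file
#' @param metabolite_meta_path metabolite metadata file
#' @param scale scale of the stored values, default \code{"raw"}
#' @return a \linkS4class{MetaboSet}
#' @export
readIntensityTable <- function(path, sample_meta_path, metabolite_meta_path,
                               scale = "raw") {
  tab <- readDelim(path)
  samples <- readDelim(sample_meta_path)
  metabolites <- readDelim(metabolite_meta_path)
  if (anyDuplicated(tab$metabolite_id))
    stop("duplicate metabolite_id in ", path, ": ",
         paste(unique(tab$metabolite_id[duplicated(tab$metabolite_id)]),
               collapse = ", "))
  if (anyDuplicated(metabolites$metabolite_id))
    stop("duplicate metabolite_id in metadata: ",
         paste(unique(metabolites$metabolite_id[
           duplicated(metabolites$metabolite_id)]), collapse = ", "))
  sample_cols <- setdiff(colnames(tab), "metabolite_id")
  unmatched <- setdiff(sample_cols, samples$sample_id)
  if (length(unmatched))
    stop("sample column(s) absent from metadata: ",
         paste(unmatched, collapse = ", "))
  extra_meta <- setdiff(samples$sample_id, sample_cols)
  if (length(extra_meta))
    message("metadata samples not present in matrix: ",
            paste(extra_meta, collapse = ", "))
  miss_meta <- setdiff(tab$metabolite_id, metabolites$metabolite_id)
  if (length(miss_meta))
    stop("metabolite(s) absent from metadata: ",
         paste(miss_meta, collapse = ", "))
  samples <- samples[match(sample_cols, samples$sample_id), , drop = FALSE]
  metabolites <- metabolites[
    match(tab$metabolite_id, metabolites$metabolite_id), , drop = FALSE]
  values <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(values) <- "double"
  MetaboSet(values, samples, metabolites, scale = scale)
}

#' Write a MetaboSet as a wide table plus metadata files
#'
#' Sample columns are ordered by (tissue, group, replicate) for stable
#' diffs; missing cells are written as \code{NA}.
#'
#' @param object a \linkS4class{MetaboSet}
#' @param path,sample_meta_path,metabolite_meta_path output files
#' @return invisibly, the paths written
#' @export
writeIntensityTable <- function(object, path, sample_meta_path,
                                metabolite_meta_path) {
  stopifnot(is(object, "MetaboSet"))
  sd <- sampleData(object)
  ord <- order(match(sd$tissue, TISSUES), match(sd$group, GROUPS),
               sd$replicate)
  sd <- sd[ord, , drop = FALSE]
  v <- intensities(object)[, ord, drop = FALSE]
  tab <- data.frame(metabolite_id = rownames(v), v, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  utils::write.csv(sd, sample_meta_path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  utils::write.csv(metaboliteData(object), metabolite_meta_path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(c(path, sample_meta_path, metabolite_meta_path))
}

#' Read a long isotopologue table
#'
#' Expects columns metabolite_id, sample_id, mass_shift, intensity; absent
#' mass shifts are densified to zero, and shifts beyond a metabolite's carbon
#' count are a hard error.
#'
#' @param path long-format file
#' @param metabolite_meta_path metadata file providing formulas
#' @return an \linkS4class{IsotopologueSet}
#' @export
readIsotopologueTable <- function(path, metabolite_meta_path) {
  d <- readDelim(path)
  meta <- readDelim(metabolite_meta_path)
  need <- c("metabolite_id", "sample_id", "mass_shift", "intensity")
  if (!all(need %in% colnames(d)))
    stop("isotopologue table must contain columns: ",
         paste(need, collapse = ", "))
  miss <- setdiff(unique(d$metabolite_id), meta$metabolite_id)
  if (length(miss))
    stop("metabolite(s) absent from metadata: ", paste(miss, collapse = ", "))
  carbons <- vapply(meta$formula, carbonCount, integer(1))
  names(carbons) <- meta$metabolite_id
  IsotopologueSet(d, carbons)
}

# Delimiter-sniffing reader: .tsv/.txt -> tab, otherwise comma.
readDelim <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    na.strings = c("", "NA"), stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

#' Write a collection of result tables as CSV files
#'
#' One CSV per table, deterministic column order (as given), \code{NA} for
#' missing. Re-running with identical inputs produces byte-identical files.
#'
#' @param tables named list of data.frames
#' @param out_dir output directory, created if needed
#' @return manifest data.frame (file, rows)
#' @export
writeResults <- function(tables, out_dir) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("tables must be named")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  manifest <- data.frame(file = character(), rows = integer())
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE, quote = FALSE,
                     na = "NA")
    manifest <- rbind(manifest,
                      data.frame(file = basename(f),
                                 rows = nrow(tables[[nm]])))
  }
  manifest
}
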