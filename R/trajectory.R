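#' FuzzyClustering: variance-sensitive fuzzy c-means result
#'
#' @slot centroids clusters x timepoints matrix
#' @slot memberships profiles x clusters matrix; rows sum to 1
#' @slot fuzzifier fuzzifier m > 1
#' @slot xie_beni Xie-Beni validity index of the solution
#' @slot scenario_labels cluster labels
#' @slot profile_ids metabolite ids of the clustered profiles
#' @slot dispersions final per-cluster dispersion weights
#' @export
setClass("FuzzyClustering",
  slots = c(centroids = "matrix", memberships = "matrix",
            fuzzifier = "numeric", xie_beni = "numeric",
            scenario_labels = "character", profile_ids = "character",
            dispersions = "numeric"))

setValidity("FuzzyClustering", function(object) {
  msg <- character()
  if (nrow(object@centroids) != length(object@scenario_labels))
    msg <- c(msg, "one scenario label per centroid required")
  if (ncol(object@memberships) != nrow(object@centroids))
    msg <- c(msg, "membership columns must match centroids")
  if (nrow(object@memberships) &&
      any(abs(rowSums(object@memberships) - 1) > 1e-9))
    msg <- c(msg, "membership rows must sum to 1")
  if (any(object@memberships < 0 | object@memberships > 1))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (object@fuzzifier <= 1) msg <- c(msg, "fuzzifier must exceed 1")
  if (length(msg)) msg else TRUE
})

#' @rdname FuzzyClustering
#' @param object a FuzzyClustering
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @rdname FuzzyClustering
#' @export
setMethod("memberships", "FuzzyClustering", function(object) {
  m <- object@memberships
  dimnames(m) <- list(object@profile_ids, object@scenario_labels)
  m
})

#' @rdname FuzzyClustering
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname FuzzyClustering
#' @export
setMethod("centroids", "FuzzyClustering", function(object) {
  m <- object@centroids
  rownames(m) <- object@scenario_labels
  m
})

#' @rdname FuzzyClustering
#' @export
setGeneric("xieBeni", function(object) standardGeneric("xieBeni"))

#' @rdname FuzzyClustering
#' @export
setMethod("xieBeni", "FuzzyClustering", function(object) object@xie_beni)

setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering:", nrow(object@memberships), "profiles,",
      nrow(object@centroids), "clusters (m =", object@fuzzifier, ")\n")
  cat("  Xie-Beni index:", format(object@xie_beni, digits = 4), "\n")
  tab <- table(factor(object@scenario_labels[hardAssignments(object)],
                      levels = object@scenario_labels))
  print(tab)
})

#' Hard cluster assignment (argmax membership)
#' @param object a FuzzyClustering
#' @return integer cluster index per profile
#' @export
hardAssignments <- function(object) {
  stopifnot(is(object, "FuzzyClustering"))
  apply(object@memberships, 1L, which.max)
}

#' Build pseudo-time trajectory profiles for one tissue
#'
#' Per metabolite, the 3-vector of group means over the pseudo-time
#' (baseline, pre-cachectic, cachectic); the tumour tissue uses NonCax as
#' baseline instead of Ctrl. Profiles are z-standardized across the three
#' points by default; constant profiles are dropped with a warning.
#'
#' @param object log-scale, imputed single-tissue \linkS4class{MetaboSet}
#' @param standardize z-standardize profiles (default TRUE)
#' @return data.frame metabolite_id, tissue, baseline, precax, cax
#' @export
buildProfiles <- function(object, standardize = TRUE) {
  stopifnot(is(object, "MetaboSet"))
  tissue <- requireSingleTissue(object, "buildProfiles")
  grp <- sampleData(object)$group
  baseline_group <- if (tissue == "tumour") "NonCax" else "Ctrl"
  need <- c(baseline_group, "PreCax", "Cax")
  missing_grp <- setdiff(need, unique(grp))
  if (length(missing_grp))
    stop("required group(s) absent: ", paste(missing_grp, collapse = ", "))
  v <- intensities(object)
  prof <- sapply(need, function(g)
    rowMeans(v[, grp == g, drop = FALSE], na.rm = TRUE))
  prof <- matrix(prof, nrow = nrow(v),
                 dimnames = list(rownames(v), c("baseline", "precax", "cax")))
  if (standardize) {
    sds <- apply(prof, 1L, stats::sd)
    const <- sds == 0 | !is.finite(sds)
    if (any(const)) {
      warning("dropped constant profile(s): ",
              paste(rownames(prof)[const], collapse = ", "))
      prof <- prof[!const, , drop = FALSE]
    }
    prof <- t(apply(prof, 1L, zStandardize))
  }
  data.frame(metabolite_id = rownames(prof), tissue = tissue,
             baseline = prof[, 1], precax = prof[, 2], cax = prof[, 3],
             row.names = NULL)
}

profileMatrix <- function(profiles) {
  m <- as.matrix(profiles[, c("baseline", "precax", "cax")])
  rownames(m) <- paste(profiles$tissue, profiles$metabolite_id, sep = ":")
  m
}

#' Variance-sensitive fuzzy c-means over trajectory profiles
#'
#' Fuzzy c-means with c = 8, centroids initialized at the eight canonical
#' scenario templates (so cluster k keeps its scenario label). Variance
#' sensitivity: each cluster's squared distances are scaled by its current
#' membership-weighted within-cluster dispersion (floored at a small
#' epsilon), so tight clusters pull harder. Iteration stops when the
#' maximal centroid movement falls below \code{tol}. Deterministic given
#' inputs: template initialization, no random restarts. A profile at zero
#' distance from a centroid receives membership 1 there.
#'
#' @param profiles data.frame from \code{\link{buildProfiles}} (possibly
#'   concatenated across tissues)
#' @param fuzzifier m > 1, default 2
#' @param max_iter default 300
#' @param tol centroid-movement tolerance, default 1e-6
#' @param variance_sensitive scale distances by cluster dispersion
#'   (default TRUE)
#' @param dispersion_floor lower bound of the dispersion weights
#' @return a \linkS4class{FuzzyClustering}
#' @export
fuzzyCluster <- function(profiles, fuzzifier = 2, max_iter = 300L,
                         tol = 1e-6, variance_sensitive = TRUE,
                         dispersion_floor = 1e-4) {
  x <- profileMatrix(profiles)
  templates <- scenarioTemplates()
  c_k <- nrow(templates)
  if (nrow(x) < c_k)
    stop("need at least ", c_k, " profiles to form ", c_k, " clusters")
  if (fuzzifier <= 1) stop("fuzzifier must exceed 1")
  v <- templates
  sig <- rep(1, c_k)
  expo <- 1 / (fuzzifier - 1)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(seq_len(nrow(x)), seq_len(c_k), Vectorize(function(i, k)
      sum((x[i, ] - v[k, ])^2)))
    d2w <- sweep(d2, 2L, sig, "/")
    u <- membershipsFromDistances(d2w, expo)
    um <- u^fuzzifier
    v_new <- (t(um) %*% x) / colSums(um)
    if (variance_sensitive) {
      sig <- vapply(seq_len(c_k), function(k)
        sum(um[, k] * d2[, k]) / sum(um[, k]), numeric(1))
      sig <- pmax(sig, dispersion_floor)
      sig <- sig / mean(sig)   # relative weighting only
    }
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) break
  }
  cl <- new("FuzzyClustering", centroids = unname(v), memberships = unname(u),
            fuzzifier = fuzzifier, xie_beni = NA_real_,
            scenario_labels = SCENARIO_LABELS,
            profile_ids = rownames(x), dispersions = sig)
  cl@xie_beni <- xieBeniIndex(x, cl)
  validObject(cl)
  cl
}

membershipsFromDistances <- function(d2, expo) {
  u <- matrix(0, nrow(d2), ncol(d2))
  for (i in seq_len(nrow(d2))) {
    zero <- d2[i, ] <= .Machine$double.eps
    if (any(zero)) {
      u[i, zero] <- 1 / sum(zero)   # zero-distance convention
    } else {
      w <- (1 / d2[i, ])^expo
      u[i, ] <- w / sum(w)
    }
  }
  u
}

#' Xie-Beni validity index
#'
#' \deqn{XB = \sum_k \sum_i u_{ik}^m \|x_i - v_k\|^2 /
#'   (n \min_{j \ne l} \|v_j - v_l\|^2)}
#' Lower is better. Coincident centroids make the index undefined and are
#' reported as a degenerate clustering.
#'
#' @param x profile matrix or the data.frame from \code{\link{buildProfiles}}
#' @param clustering a \linkS4class{FuzzyClustering}
#' @return positive scalar
#' @export
xieBeniIndex <- function(x, clustering) {
  stopifnot(is(clustering, "FuzzyClustering"))
  if (is.data.frame(x)) x <- profileMatrix(x)
  v <- clustering@centroids
  u <- clustering@memberships
  m <- clustering@fuzzifier
  d2 <- outer(seq_len(nrow(x)), seq_len(nrow(v)), Vectorize(function(i, k)
    sum((x[i, ] - v[k, ])^2)))
  num <- sum((u^m) * d2)
  sep <- as.matrix(stats::dist(v))^2
  diag(sep) <- Inf
  min_sep <- min(sep)
  if (min_sep <= .Machine$double.eps)
    stop("degenerate clustering: coincident centroids")
  num / (nrow(x) * min_sep)
}

#' Rank profiles by membership within each cluster
#'
#' Ties are broken by profile id lexicographic order, making the output
#' stable across runs.
#'
#' @param clustering a \linkS4class{FuzzyClustering}
#' @param top_n per-cluster list length, default 10
#' @return data.frame cluster, rank, profile_id, membership
#' @export
rankMembers <- function(clustering, top_n = 10L) {
  stopifnot(is(clustering, "FuzzyClustering"))
  u <- clustering@memberships
  ids <- clustering@profile_ids
  hard <- hardAssignments(clustering)
  out <- list()
  for (k in seq_len(ncol(u))) {
    in_k <- which(hard == k)
    ord <- in_k[order(-u[in_k, k], ids[in_k])]
    take <- utils::head(ord, top_n)
    if (!length(take)) next
    out[[k]] <- data.frame(cluster = clustering@scenario_labels[k],
                           rank = seq_along(take), profile_id = ids[take],
                           membership = u[take, k])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tissue and class contribution tables for Sankey-style reporting
#'
#' Each profile is hard-assigned to its maximal-membership cluster and
#' optionally gated by a minimum membership; counts are tabulated by tissue
#' and by metabolite class.
#'
#' @param clustering a \linkS4class{FuzzyClustering}
#' @param profiles the clustered profile data.frame (provides tissue)
#' @param metabolite_meta data.frame with metabolite_id and cls
#' @param min_membership reporting gate on the best membership, default 0.5
#' @return list with \code{tissue_by_cluster} and \code{cluster_by_class}
#'   contingency tables and \code{n_assigned}
#' @export
contributionTables <- function(clustering, profiles, metabolite_meta,
                               min_membership = 0.5) {
  stopifnot(is(clustering, "FuzzyClustering"))
  hard <- hardAssignments(clustering)
  best <- clustering@memberships[cbind(seq_along(hard), hard)]
  keep <- best >= min_membership
  lab <- factor(clustering@scenario_labels[hard[keep]],
                levels = clustering@scenario_labels)
  tis <- factor(profiles$tissue[keep], levels = TISSUES)
  cls <- metabolite_meta$cls[match(profiles$metabolite_id[keep],
                                   metabolite_meta$metabolite_id)]
  cls <- factor(cls, levels = METABOLITE_CLASSES)
  list(tissue_by_cluster = table(tissue = tis, cluster = lab),
       cluster_by_class = table(cluster = lab, class = cls),
       n_assigned = sum(keep))
}
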