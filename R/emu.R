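# Steady-state MDV simulation by EMU (elementary metabolite unit)
# decomposition. An EMU is a subset of one metabolite's carbon atoms; the
# decomposition backtracks from the measured metabolites' full-carbon EMUs
# through the atom maps, producing per-size linear balance systems whose
# inputs are substrate EMUs and convolutions of smaller EMUs. Symmetric
# molecules are handled by splitting each producing reaction into two
# half-flux orientation variants (50:50 averaging at the point of
# production). The decomposition is compiled once per (network, target set)
# into flat index arrays so repeated evaluation inside fitting loops stays
# cheap.

emuKey <- function(met, pos) paste0(met, "|", paste(sort(pos), collapse = ","))

emuMet <- function(key) sub("\\|.*$", "", key)

emuPos <- function(key)
  as.integer(strsplit(sub("^.*\\|", "", key), ",")[[1]])

# Expand reactions into orientation variants for symmetric products.
normalizedReactions <- function(network) {
  out <- list()
  for (r in network@reactions) {
    variants <- list(list(weight = 1, products = r$products))
    for (pi in seq_along(r$products)) {
      met <- r$products[[pi]]$met
      if (met %in% network@symmetric) {
        variants <- unlist(lapply(variants, function(v) {
          flip <- v$products
          flip[[pi]]$atoms <- rev(flip[[pi]]$atoms)
          list(list(weight = v$weight / 2, products = v$products),
               list(weight = v$weight / 2, products = flip))
        }), recursive = FALSE)
      }
    }
    for (v in variants)
      out[[length(out) + 1L]] <- list(id = r$id, weight = v$weight,
                                      reactants = r$reactants,
                                      products = v$products)
  }
  out
}

# Consumption terms per metabolite: reaction id -> stoichiometric count.
consumptionOf <- function(network, met) {
  counts <- integer()
  for (r in network@reactions) {
    n <- sum(vapply(r$reactants, function(sp) sp$met == met, TRUE))
    if (n > 0) counts[r$id] <- n
  }
  counts
}

productionIdsOf <- function(network, met) {
  counts <- integer()
  for (r in network@reactions) {
    n <- sum(vapply(r$products, function(sp) sp$met == met, TRUE))
    if (n > 0) counts[r$id] <- n
  }
  counts
}

# EMU MDV of a substrate: positions are exchangeable given only a full MDV,
# so the size-s marginal is a hypergeometric mixture.
substrateEMUMDV <- function(full_mdv, C, s) {
  out <- numeric(s + 1L)
  for (K in 0:C) {
    if (full_mdv[K + 1L] == 0) next
    out <- out + full_mdv[K + 1L] * stats::dhyper(0:s, K, C - K, s)
  }
  out
}

# Open convolution of two short MDVs; plain loop beats fft at this size.
convMDV <- function(a, b) {
  la <- length(a); lb <- length(b)
  out <- numeric(la + lb - 1L)
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Decompose and compile: backtrack the EMU graph from the targets, then
# flatten every per-size balance system into integer index arrays against
# a fixed EMU-value table and a fixed reaction order.
emuCompile <- function(network, targets) {
  roles <- network@roles
  nr <- normalizedReactions(network)
  rxn_ids <- reactionIds(network)
  todo <- vapply(targets, function(m)
    emuKey(m, seq_len(network@carbons[[m]])), "")
  seen <- character()
  prod_terms <- list()
  while (length(todo)) {
    key <- todo[[1]]; todo <- todo[-1]
    if (key %in% seen) next
    seen <- c(seen, key)
    met <- emuMet(key); pos <- emuPos(key)
    if (roles[[met]] == "substrate") next
    terms <- list()
    for (r in nr) {
      for (p in r$products) {
        if (p$met != met) next
        letters <- p$atoms[pos]
        sources <- character()
        remaining <- letters
        for (q in r$reactants) {
          qpos <- which(q$atoms %in% remaining)
          if (length(qpos)) {
            sources <- c(sources, emuKey(q$met, qpos))
            remaining <- setdiff(remaining, q$atoms[qpos])
          }
        }
        stopifnot(length(remaining) == 0L)
        terms[[length(terms) + 1L]] <-
          list(flux = r$id, weight = r$weight, sources = sources)
        for (s in sources)
          if (roles[[emuMet(s)]] != "substrate" && !(s %in% seen))
            todo <- c(todo, s)
      }
    }
    if (!length(terms)) stop("EMU pool without producers: ", key)
    prod_terms[[key]] <- terms
  }
  all_keys <- unique(c(seen, unlist(lapply(prod_terms, function(tl)
    unlist(lapply(tl, `[[`, "sources"))))))
  kidx <- stats::setNames(seq_along(all_keys), all_keys)
  values0 <- vector("list", length(all_keys))
  for (k in all_keys) {
    met <- emuMet(k)
    if (roles[[met]] == "substrate")
      values0[[kidx[[k]]]] <- substrateEMUMDV(
        network@substrate_mdvs[[met]], network@carbons[[met]],
        length(emuPos(k)))
  }
  unknowns <- all_keys[vapply(all_keys, function(k)
    roles[[emuMet(k)]] != "substrate", TRUE)]
  sizes <- vapply(unknowns, function(k) length(emuPos(k)), 1L)
  systems <- list()
  for (s in sort(unique(sizes))) {
    keys <- unknowns[sizes == s]
    n <- length(keys)
    diag_row <- integer(); diag_flux <- integer(); diag_coef <- numeric()
    off_row <- integer(); off_col <- integer()
    off_flux <- integer(); off_weight <- numeric()
    bterms <- list()
    for (i in seq_len(n)) {
      met <- emuMet(keys[i])
      den <- consumptionOf(network, met)
      if (!length(den)) den <- productionIdsOf(network, met)
      diag_row <- c(diag_row, rep(i, length(den)))
      diag_flux <- c(diag_flux, match(names(den), rxn_ids))
      diag_coef <- c(diag_coef, as.numeric(den))
      for (tm in prod_terms[[keys[i]]]) {
        fi <- match(tm$flux, rxn_ids)
        same <- length(tm$sources) == 1L && tm$sources %in% keys
        if (same) {
          off_row <- c(off_row, i)
          off_col <- c(off_col, match(tm$sources, keys))
          off_flux <- c(off_flux, fi)
          off_weight <- c(off_weight, tm$weight)
        } else {
          bterms[[length(bterms) + 1L]] <-
            list(row = i, flux = fi, weight = tm$weight,
                 src = unname(kidx[tm$sources]))
        }
      }
    }
    systems[[length(systems) + 1L]] <- list(
      size = s, n = n, idx = unname(kidx[keys]),
      diag_row = diag_row, diag_flux = diag_flux, diag_coef = diag_coef,
      off_row = off_row, off_col = off_col, off_flux = off_flux,
      off_weight = off_weight, bterms = bterms)
  }
  target_idx <- vapply(targets, function(m)
    kidx[[emuKey(m, seq_len(network@carbons[[m]]))]], 1L)
  list(rxn_ids = rxn_ids, values0 = values0, systems = systems,
       target_idx = target_idx, targets = targets)
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Solves the size-ordered EMU balance systems of the network at the given
#' fluxes and returns the full-carbon MDV of each requested metabolite.
#' The compiled decomposition is cached on the network object per target
#' set.
#'
#' @param network a \linkS4class{FluxNetwork}
#' @param fluxes named, balanced, non-negative flux vector
#' @param metabolites metabolites to report; default the measured set
#' @param check check flux balance first (default TRUE); skipped inside
#'   fitting loops where the parameterization guarantees balance
#' @return named list of MDVs (numeric vectors of length C+1 summing to 1)
#' @export
simulateMDVs <- function(network, fluxes,
                         metabolites = measuredMetabolites(network),
                         check = TRUE) {
  if (!length(metabolites)) stop("no metabolites requested")
  bad <- setdiff(metabolites, names(network@carbons))
  if (length(bad))
    stop("unknown metabolite(s): ", paste(bad, collapse = ", "))
  if (check) checkFluxBalance(network, fluxes)
  ckey <- paste("emu", paste(sort(metabolites), collapse = ";"))
  plan <- network@cache[[ckey]]
  if (is.null(plan)) {
    plan <- emuCompile(network, metabolites)
    network@cache[[ckey]] <- plan
  }
  fv <- as.numeric(fluxes[plan$rxn_ids])
  out <- lapply(emuEvalCpp(plan, fv), function(v) v / sum(v))
  names(out) <- plan$targets
  out
}
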