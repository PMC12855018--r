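#' FluxNetwork: an atom-transition metabolic network
#'
#' Parsed from the plain-text reaction grammar (see
#' \code{\link{parseNetwork}}). Carbon counts are inferred from atom maps;
#' roles are derived: a metabolite only consumed is a substrate (and must
#' carry an input MDV), one only produced is a sink, anything else an
#' intermediate.
#'
#' @slot reactions list of parsed reactions (id, reactants, products)
#' @slot carbons named integer carbon counts
#' @slot roles named character roles
#' @slot substrate_mdvs named list of input MDVs
#' @slot symmetric names of rotationally symmetric metabolites
#' @slot reference_flux_id reference reaction (reported as 100)
#' @slot free_flux_ids free fluxes of the parameterization
#' @slot measured metabolites whose MDVs are fitted
#' @slot cache environment holding the EMU decomposition
#' @export
setClass("FluxNetwork",
  slots = c(reactions = "list", carbons = "integer", roles = "character",
            substrate_mdvs = "list", symmetric = "character",
            reference_flux_id = "character", free_flux_ids = "character",
            measured = "character", cache = "environment"))

setMethod("show", "FluxNetwork", function(object) {
  cat("FluxNetwork:", length(object@reactions), "reactions,",
      length(object@carbons), "metabolites\n")
  cat("  reference:", object@reference_flux_id,
      " free:", paste(object@free_flux_ids, collapse = ", "), "\n")
  cat("  measured:", paste(object@measured, collapse = ", "), "\n")
})

#' Reaction ids of a network
#' @param network a FluxNetwork
#' @export
reactionIds <- function(network) {
  vapply(network@reactions, `[[`, "", "id")
}

#' Metabolite carbon counts
#' @param network a FluxNetwork
#' @export
metaboliteCarbons <- function(network) network@carbons

#' Measured metabolites
#' @param network a FluxNetwork
#' @export
measuredMetabolites <- function(network) network@measured

parseSide <- function(txt, line) {
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    p <- trimws(p)
    m <- regmatches(p, regexec("^([A-Za-z0-9_]+)\\s*\\(([a-z]+)\\)$", p))[[1]]
    if (length(m) != 3L)
      stop("cannot parse species '", p, "' in line: ", line)
    list(met = m[2], atoms = strsplit(m[3], "")[[1]])
  })
}

#' Parse an atom-transition network file
#'
#' One reaction per line, e.g. \code{V10: PYR (abc) -> CO2 (a) + AcCoA (bc)};
#' lowercase letters track carbon atoms and must map bijectively from
#' reactants to products (carbon conservation). \code{<->} marks a
#' reversible reaction, which is split into forward and \code{_rev}
#' irreversible halves. Directive lines:
#' \describe{
#'   \item{\code{substrate NAME f0 f1 ...}}{input MDV of a substrate}
#'   \item{\code{symmetric NAME ...}}{rotationally symmetric metabolites
#'     (label scrambling by 50:50 orientation averaging at production)}
#'   \item{\code{reference ID}}{reference flux, reported as 100}
#'   \item{\code{free ID ...}}{free fluxes of the parameterization}
#'   \item{\code{measured NAME ...}}{metabolites fitted against data}
#' }
#' Comments start with \code{#}.
#'
#' @param path network file; alternatively pass the file content via
#'   \code{text}
#' @param text character vector of lines (overrides \code{path})
#' @return a validated \linkS4class{FluxNetwork}
#' @export
parseNetwork <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n")) else {
    if (!file.exists(path)) stop("network file does not exist: ", path)
    readLines(path)
  }
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  reactions <- list(); substrate_mdvs <- list()
  symmetric <- character(); reference <- character()
  free_ids <- character(); measured <- character()
  for (ln in lines) {
    low <- tolower(ln)
    if (startsWith(low, "substrate ")) {
      tok <- strsplit(ln, "\\s+")[[1]]
      substrate_mdvs[[tok[2]]] <- as.numeric(tok[-(1:2)])
    } else if (startsWith(low, "symmetric ")) {
      symmetric <- c(symmetric, strsplit(ln, "\\s+")[[1]][-1])
    } else if (startsWith(low, "reference ")) {
      reference <- strsplit(ln, "\\s+")[[1]][2]
    } else if (startsWith(low, "free ")) {
      free_ids <- c(free_ids, strsplit(ln, "\\s+")[[1]][-1])
    } else if (startsWith(low, "measured ")) {
      measured <- c(measured, strsplit(ln, "\\s+")[[1]][-1])
    } else {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.+?)\\s*(<->|->)\\s*(.+)$",
                                  ln, perl = TRUE))[[1]]
      if (length(m) != 5L) stop("cannot parse reaction line: ", ln)
      id <- m[2]; lhs <- parseSide(m[3], ln); rhs <- parseSide(m[5], ln)
      rl <- unlist(lapply(lhs, `[[`, "atoms"))
      pl <- unlist(lapply(rhs, `[[`, "atoms"))
      if (length(rl) != length(pl) || !setequal(rl, pl) ||
          anyDuplicated(rl) || anyDuplicated(pl))
        stop("atom map is not a carbon-conserving bijection in line: ", ln)
      reactions[[length(reactions) + 1L]] <-
        list(id = id, reactants = lhs, products = rhs)
      if (m[4] == "<->")
        reactions[[length(reactions) + 1L]] <-
          list(id = paste0(id, "_rev"), reactants = rhs, products = lhs)
    }
  }
  if (!length(reactions)) stop("no reactions found")
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction id: ", ids[duplicated(ids)][1])
  # infer carbon counts, check consistency
  carbons <- integer(); occurs_react <- character(); occurs_prod <- character()
  for (r in reactions) {
    for (side in c("reactants", "products")) {
      for (sp in r[[side]]) {
        n <- length(sp$atoms)
        if (!is.null(carbons[sp$met]) && !is.na(carbons[sp$met]) &&
            carbons[[sp$met]] != n)
          stop("inconsistent carbon count for metabolite ", sp$met)
        carbons[sp$met] <- n
        if (side == "reactants") occurs_react <- c(occurs_react, sp$met)
        else occurs_prod <- c(occurs_prod, sp$met)
      }
    }
  }
  roles <- vapply(names(carbons), function(m) {
    inn <- m %in% occurs_prod; out <- m %in% occurs_react
    if (out && !inn) "substrate" else if (inn && !out) "sink" else "intermediate"
  }, "")
  for (s in names(substrate_mdvs)) {
    if (!s %in% names(carbons)) stop("unknown metabolite in directive: ", s)
    mdv <- substrate_mdvs[[s]]
    if (length(mdv) != carbons[[s]] + 1L)
      stop("substrate MDV for ", s, " must have length ", carbons[[s]] + 1L)
    if (abs(sum(mdv) - 1) > 1e-9)
      stop("substrate MDV for ", s, " must sum to 1")
  }
  no_mdv <- setdiff(names(roles)[roles == "substrate"], names(substrate_mdvs))
  if (length(no_mdv))
    stop("substrate(s) without an input MDV: ", paste(no_mdv, collapse = ", "))
  for (s in c(symmetric, measured))
    if (!s %in% names(carbons)) stop("unknown metabolite in directive: ", s)
  if (length(reference) && !reference %in% ids)
    stop("unknown reference flux: ", reference)
  bad_free <- setdiff(free_ids, ids)
  if (length(bad_free))
    stop("unknown free flux id(s): ", paste(bad_free, collapse = ", "))
  net <- new("FluxNetwork", reactions = reactions, carbons = carbons,
             roles = roles, substrate_mdvs = substrate_mdvs,
             symmetric = unique(symmetric),
             reference_flux_id = reference, free_flux_ids = unique(free_ids),
             measured = unique(measured),
             cache = new.env(parent = emptyenv()))
  # the free/reference parameterization must determine all fluxes
  if (length(free_ids) || length(reference)) {
    S <- stoichMatrix(net)
    fixed <- c(net@free_flux_ids, net@reference_flux_id)
    dep <- setdiff(colnames(S), fixed)
    if (length(dep) != nrow(S))
      stop("free-flux parameterization does not determine the network: ",
           nrow(S), " balances vs ", length(dep), " dependent fluxes")
    if (abs(det(S[, dep, drop = FALSE])) < 1e-12)
      stop("stoichiometric system is singular for the chosen free fluxes")
  }
  net
}

#' Stoichiometric matrix over intermediates
#'
#' Rows are intermediate metabolites, columns reactions; entries count
#' production minus consumption. Steady state requires S v = 0.
#'
#' @param network a \linkS4class{FluxNetwork}
#' @export
stoichMatrix <- function(network) {
  ints <- names(network@roles)[network@roles == "intermediate"]
  ids <- reactionIds(network)
  S <- matrix(0, length(ints), length(ids), dimnames = list(ints, ids))
  for (r in network@reactions) {
    for (sp in r$reactants)
      if (sp$met %in% ints) S[sp$met, r$id] <- S[sp$met, r$id] - 1
    for (sp in r$products)
      if (sp$met %in% ints) S[sp$met, r$id] <- S[sp$met, r$id] + 1
  }
  S
}

#' Complete a flux vector from free fluxes and the reference value
#'
#' Dependent fluxes are solved from the intermediate balance system
#' \code{S v = 0} with the free fluxes and the reference flux fixed.
#'
#' @param network a \linkS4class{FluxNetwork}
#' @param free named values of the free fluxes
#' @param reference_value value of the reference flux, default 100
#' @return full named flux vector
#' @export
completeFluxes <- function(network, free, reference_value = 100) {
  P <- network@cache[["flux_projection"]]
  if (is.null(P)) {
    S <- stoichMatrix(network)
    fixed_ids <- c(network@free_flux_ids, network@reference_flux_id)
    dep <- setdiff(colnames(S), fixed_ids)
    ids <- reactionIds(network)
    # v = P f with f the fixed (free + reference) fluxes
    P <- matrix(0, length(ids), length(fixed_ids),
                dimnames = list(ids, fixed_ids))
    P[cbind(fixed_ids, fixed_ids)] <- 1
    P[dep, ] <- -solve(S[, dep, drop = FALSE],
                       S[, fixed_ids, drop = FALSE])
    network@cache[["flux_projection"]] <- P
  }
  fixed <- c(free[network@free_flux_ids],
             stats::setNames(reference_value, network@reference_flux_id))
  if (anyNA(fixed)) stop("missing free flux value(s)")
  stats::setNames(as.numeric(P %*% fixed[colnames(P)]), rownames(P))
}

#' Check flux balance and non-negativity
#'
#' @param network a \linkS4class{FluxNetwork}
#' @param fluxes named flux vector over all reactions
#' @param tol balance tolerance, default 1e-8
#' @return invisibly TRUE; hard error citing the violated balance otherwise
#' @export
checkFluxBalance <- function(network, fluxes, tol = 1e-8) {
  ids <- reactionIds(network)
  miss <- setdiff(ids, names(fluxes))
  if (length(miss))
    stop("missing flux value(s): ", paste(miss, collapse = ", "))
  if (any(fluxes < -tol))
    stop("negative flux: ",
         paste(names(fluxes)[fluxes < -tol], collapse = ", "))
  S <- stoichMatrix(network)
  resid <- S %*% fluxes[colnames(S)]
  bad <- abs(resid) > tol
  if (any(bad))
    stop("flux balance violated at metabolite(s): ",
         paste(rownames(S)[bad], collapse = ", "))
  invisible(TRUE)
}

#' The default glycolysis-TCA atom-transition network
#'
#' Lumped glycolysis feeding the TCA cycle from uniformly labelled glucose:
#' pyruvate carboxylase (V9) and pyruvate dehydrogenase (V10) entries, an
#' unlabelled acetyl-CoA inflow standing for fatty-acid oxidation and
#' ketogenic amino acids (V11), citrate synthase (V12, the reference flux),
#' aconitase/isocitrate dehydrogenase lumped (V13), unlabelled glutamine
#' entry (V16/V17), 2-oxoglutarate dehydrogenase (V18), succinate
#' dehydrogenase, fumarate hydratase and malate dehydrogenase (V19-V21,
#' with succinate and fumarate treated as symmetric), plus a cataplerotic
#' oxaloacetate efflux closing the balance. Measured metabolites default to
#' citrate, succinate, fumarate and malate.
#'
#' @return a \linkS4class{FluxNetwork}
#' @export
defaultNetwork <- function() {
  path <- system.file("extdata", "network_glycolysis_tca.txt",
                      package = "TraceMet", mustWork = TRUE)
  parseNetwork(path)
}
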