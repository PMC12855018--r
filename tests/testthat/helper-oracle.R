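# Independent oracles used across the suite.

# Full-isotopomer fixed-point simulator: tracks the complete 2^C positional
# isotopomer distribution of every metabolite and iterates the steady-state
# balance to convergence. Entirely independent of the EMU decomposition;
# symmetric molecules are orientation-averaged at production from the
# network's symmetric declaration.
oracleSimulateMDVs <- function(network, fluxes, metabolites,
                               tol = 1e-13, max_iter = 100000L) {
  carbons <- metaboliteCarbons(network)
  roles <- network@roles
  sym <- network@symmetric
  mets <- names(carbons)
  popcount <- function(idx, C)
    vapply(idx, function(i) sum(bitwAnd(i, bitwShiftL(1L, 0:(C - 1L))) > 0L), 1L)
  iso <- list()
  for (m in mets) {
    C <- carbons[[m]]
    if (roles[[m]] == "substrate") {
      mdv <- network@substrate_mdvs[[m]]
      k <- popcount(0:(2^C - 1L), C)
      iso[[m]] <- mdv[k + 1L] / choose(C, k)
    } else {
      iso[[m]] <- c(1, numeric(2^C - 1L))
    }
  }
  # per (reaction, product occurrence): aggregation matrix T mapping the
  # joint reactant isotopomer distribution to the product distribution,
  # orientation-averaged for symmetric products
  plans <- list()
  for (r in network@reactions) {
    react_sizes <- vapply(r$reactants, function(q) length(q$atoms), 1L)
    combos <- expand.grid(lapply(react_sizes, function(s) 0:(2^s - 1L)))
    # labelled-or-not of each atom letter, per combo row
    letter_state <- list()
    for (qi in seq_along(r$reactants)) {
      q <- r$reactants[[qi]]
      for (ai in seq_along(q$atoms))
        letter_state[[q$atoms[ai]]] <-
          bitwAnd(combos[[qi]], bitwShiftL(1L, ai - 1L)) > 0L
    }
    for (p in r$products) {
      C <- length(p$atoms)
      orientations <- if (p$met %in% sym)
        list(p$atoms, rev(p$atoms)) else list(p$atoms)
      T <- matrix(0, 2^C, nrow(combos))
      for (atoms in orientations) {
        pat <- rep(0L, nrow(combos))
        for (ai in seq_len(C))
          pat <- pat + bitwShiftL(1L, ai - 1L) *
            as.integer(letter_state[[atoms[ai]]])
        T[cbind(pat + 1L, seq_len(nrow(combos)))] <-
          T[cbind(pat + 1L, seq_len(nrow(combos)))] + 1 / length(orientations)
      }
      plans[[length(plans) + 1L]] <-
        list(flux = r$id, met = p$met,
             reactant_mets = vapply(r$reactants, `[[`, "", "met"), T = T)
    }
  }
  cons <- vapply(mets, function(m) {
    tot <- 0
    for (r in network@reactions)
      for (sp in r$reactants) if (sp$met == m) tot <- tot + fluxes[[r$id]]
    tot
  }, 0)
  prod_tot <- vapply(mets, function(m) {
    tot <- 0
    for (r in network@reactions)
      for (sp in r$products) if (sp$met == m) tot <- tot + fluxes[[r$id]]
    tot
  }, 0)
  intermediates <- mets[roles != "substrate"]
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (m in intermediates) {
      den <- if (cons[[m]] > 0) cons[[m]] else prod_tot[[m]]
      if (den == 0) next
      acc <- numeric(2^carbons[[m]])
      for (pl in plans) {
        if (pl$met != m) next
        v <- fluxes[[pl$flux]]
        if (v == 0) next
        probs <- Reduce(function(a, b) as.numeric(outer(a, b)),
                        lapply(pl$reactant_mets, function(rm) iso[[rm]]))
        acc <- acc + v * as.numeric(pl$T %*% probs)
      }
      new_p <- acc / den
      delta <- max(delta, max(abs(new_p - iso[[m]])))
      iso[[m]] <- new_p   # Gauss-Seidel update
    }
    if (delta < tol) break
  }
  out <- lapply(metabolites, function(m) {
    C <- carbons[[m]]
    k <- popcount(0:(2^C - 1L), C)
    mdv <- vapply(0:C, function(kk) sum(iso[[m]][k == kk]), 0)
    mdv / sum(mdv)
  })
  names(out) <- metabolites
  out
}

# Monte-Carlo studentized-range oracle for balanced Tukey HSD: simulates
# the null distribution of the maximal standardized pairwise mean
# difference and returns P(q >= q_obs).
tukeyRangeOracleP <- function(values_by_group, pair, n_sim = 20000L,
                              seed = 404L) {
  stopifnot(length(unique(lengths(values_by_group))) == 1L)
  n <- length(values_by_group[[1]])
  g <- length(values_by_group)
  v <- unlist(values_by_group)
  grp <- rep(seq_len(g), each = n)
  s2 <- sum(tapply(v, grp, function(x) sum((x - mean(x))^2))) / (g * (n - 1))
  means <- tapply(v, grp, mean)
  i <- match(pair[1], names(values_by_group))
  j <- match(pair[2], names(values_by_group))
  q_obs <- abs(means[i] - means[j]) / sqrt(s2 / n)
  set.seed(seed)
  q_null <- replicate(n_sim, {
    x <- matrix(rnorm(g * n), n, g)
    m <- colMeans(x)
    s2s <- sum(apply(x, 2, function(cc) sum((cc - mean(cc))^2))) /
      (g * (n - 1))
    (max(m) - min(m)) / sqrt(s2s / n)
  })
  mean(q_null >= q_obs)
}

# Monte-Carlo many-to-one oracle for Dunnett: null distribution of the
# maximal |t| of the contrasts versus control.
dunnettOracleP <- function(v, g, group, n_sim = 20000L, seed = 405L) {
  lev <- levels(g)
  ns <- table(g)
  t_of <- function(vv) {
    s2 <- sum(tapply(vv, g, function(x) sum((x - mean(x))^2))) /
      (length(vv) - length(lev))
    m <- tapply(vv, g, mean)
    abs(m[-1] - m[1]) / sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  }
  t_obs <- t_of(v)[match(group, lev[-1])]
  set.seed(seed)
  t_null <- replicate(n_sim, max(t_of(rnorm(length(v)))))
  mean(t_null >= t_obs)
}
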