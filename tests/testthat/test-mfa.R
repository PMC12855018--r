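test_that("the network parser enforces the atom-map grammar", {
  net <- parseNetwork(text = "
substrate PYR 0 0 0 1
reference V10
measured AcCoA
V10: PYR (abc) -> CO2 (a) + AcCoA (bc)
Vs: AcCoA (ab) -> AcOut (ab)
")
  expect_s4_class(net, "FluxNetwork")
  expect_equal(metaboliteCarbons(net)[["AcCoA"]], 2L)
  expect_equal(net@roles[["PYR"]], "substrate")
  expect_equal(net@roles[["AcCoA"]], "intermediate")
  expect_equal(net@roles[["CO2"]], "sink")
  # carbon-count mismatch is caught with the offending line
  expect_error(parseNetwork(text = "V1: PYR (abc) -> CO2 (ab)"),
               "bijection.*PYR")
  expect_error(parseNetwork(text = "
substrate A 1 0
reference V1
V1: A (a) -> B (a)
symmetric ZZZ
"), "unknown metabolite")
  # substrates must carry an input MDV of the right length
  expect_error(parseNetwork(text = "
substrate A 1 0 0
reference V1
V1: A (a) -> B (a)
"), "length 2")
})

test_that("the shipped default network passes all structural invariants", {
  net <- defaultNetwork()
  expect_setequal(net@free_flux_ids, c("V9", "V11", "V16"))
  expect_equal(net@reference_flux_id, "V12")
  expect_setequal(measuredMetabolites(net), c("CIT", "SUC", "FUM", "MAL"))
  # every reaction conserves carbon (enforced at parse; spot-check counts)
  expect_equal(metaboliteCarbons(net)[c("GLC", "PYR", "CIT", "OGA", "SUC")],
               c(GLC = 6L, PYR = 3L, CIT = 6L, OGA = 5L, SUC = 4L))
  S <- stoichMatrix(net)
  expect_equal(qr(S)$rank, nrow(S))   # full row rank over intermediates
  v <- completeFluxes(net, defaultTestFluxes)
  expect_silent(checkFluxBalance(net, v))
  expect_equal(v[["V12"]], 100)
  expect_equal(v[["V10"]], 100 - 40)          # AcCoA balance
  expect_equal(v[["V18"]], 100 + 20)          # OGA balance
  expect_equal(v[["V22"]], 25 + 20)           # OAA closure
  expect_error(checkFluxBalance(net, v * c(2, rep(1, 12))), "PYR")
  expect_error(checkFluxBalance(net, replace(v, "V9", -5)), "negative")
})

test_that("unlabelled substrates give fully unlabelled steady states", {
  net <- parseNetwork(text = "
substrate GLC 1 0 0 0 0 0 0
substrate CO2in 1 0
substrate AcCoAin 1 0 0
substrate GLNin 1 0 0 0 0 0
symmetric SUC FUM
reference V12
free V9 V11 V16
measured CIT SUC FUM MAL
V1:  GLC (abcdef) -> PYR (cba) + PYR (def)
V9:  PYR (abc) + CO2in (d) -> OAA (abcd)
V10: PYR (abc) -> CO2 (a) + AcCoA (bc)
V11: AcCoAin (ab) -> AcCoA (ab)
V12: OAA (abcd) + AcCoA (ef) -> CIT (dcbafe)
V13: CIT (abcdef) -> OGA (abcde) + CO2 (f)
V16: GLNin (abcde) -> GLU (abcde)
V17: GLU (abcde) -> OGA (abcde)
V18: OGA (abcde) -> SUC (bcde) + CO2 (a)
V19: SUC (abcd) -> FUM (abcd)
V20: FUM (abcd) -> MAL (abcd)
V21: MAL (abcd) -> OAA (abcd)
V22: OAA (abcd) -> OAAout (abcd)
")
  mdvs <- simulateMDVs(net, completeFluxes(net, defaultTestFluxes))
  for (m in names(mdvs)) {
    expect_equal(mdvs[[m]][1], 1, tolerance = 1e-9)
    expect_equal(sum(mdvs[[m]]), 1, tolerance = 1e-9)
  }
})

test_that("a closed fully-labelled carbon supply labels citrate completely", {
  net <- defaultNetwork()
  v <- completeFluxes(net, c(V9 = 0, V11 = 0, V16 = 0))
  mdvs <- simulateMDVs(net, v)
  expect_equal(mdvs$CIT, c(0, 0, 0, 0, 0, 0, 1), tolerance = 1e-9)
  expect_equal(mdvs$MAL, c(0, 0, 0, 0, 1), tolerance = 1e-9)
})

test_that("a 50:50 acetyl-CoA mix gives the hand-solved citrate M+2", {
  net <- parseNetwork(text = "
substrate GLC 0 0 0 0 0 0 1
substrate AcCoAin 1 0 0
substrate OAAin 1 0 0 0 0
reference V12
free V10
measured CIT
V1:  GLC (abcdef) -> PYR (cba) + PYR (def)
V10: PYR (abc) -> CO2 (a) + AcCoA (bc)
V11: AcCoAin (ab) -> AcCoA (ab)
V12: OAA (abcd) + AcCoA (ef) -> CIT (dcbafe)
Vo:  OAAin (abcd) -> OAA (abcd)
Vs:  CIT (abcdef) -> CITout (abcdef)
")
  # V10 = 50, V11 = V12 - V10 = 50: half the acetyl pool is labelled M+2
  v <- completeFluxes(net, c(V10 = 50))
  mdv <- simulateMDVs(net, v)$CIT
  expect_equal(mdv[3], 0.5, tolerance = 1e-9)   # M+2 = labelled-acetyl share
  expect_equal(mdv[1], 0.5, tolerance = 1e-9)
  oracle <- oracleSimulateMDVs(net, v, "CIT")
  expect_equal(mdv, oracle$CIT, tolerance = 1e-8)
})

test_that("symmetric scrambling matches the hand solution and the oracle", {
  net <- toySymmetricNetwork()
  v <- completeFluxes(net, numeric(0))
  mdvs <- simulateMDVs(net, v)
  expect_equal(mdvs$P, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(mdvs$Q, c(0, 0.5, 0.5), tolerance = 1e-9)
  oracle <- oracleSimulateMDVs(net, v, c("P", "Q", "S"))
  for (m in c("P", "Q", "S"))
    expect_equal(mdvs[[m]], oracle[[m]], tolerance = 1e-8)
})

test_that("the EMU simulator matches full isotopomer enumeration", {
  # small dilution network
  netL <- toyLinearNetwork()
  vL <- completeFluxes(netL, c(R2 = 35))
  expect_equal(simulateMDVs(netL, vL)$B,
               oracleSimulateMDVs(netL, vL, "B")$B, tolerance = 1e-8)
  # full default network (6-carbon pools, cycle, symmetric molecules)
  net <- defaultNetwork()
  for (free in list(defaultTestFluxes, c(V9 = 80, V11 = 10, V16 = 5),
                    c(V9 = 5, V11 = 90, V16 = 60))) {
    v <- completeFluxes(net, free)
    emu <- simulateMDVs(net, v)
    oracle <- oracleSimulateMDVs(net, v, names(emu))
    for (m in names(emu))
      expect_equal(emu[[m]], oracle[[m]], tolerance = 1e-7,
                   label = paste(m, paste(free, collapse = "/")))
  }
})

test_that("labelled carbon is conserved at steady state", {
  net <- defaultNetwork()
  v <- completeFluxes(net, defaultTestFluxes)
  mdvs <- simulateMDVs(net, v, c("CO2", "OAA"))
  # inflow of labelled carbon: only glucose is labelled (M+6, 6 carbons)
  inflow <- v[["V1"]] * 6
  # outflow: CO2 sink (V10 + V13 + V18) and cataplerotic OAA efflux (V22)
  e_co2 <- meanEnrichment(mdvs$CO2) * 1
  e_oaa <- meanEnrichment(mdvs$OAA) * 4
  outflow <- (v[["V10"]] + v[["V13"]] + v[["V18"]]) * e_co2 + v[["V22"]] * e_oaa
  expect_equal(outflow, inflow, tolerance = 1e-8)
})

test_that("flux fitting recovers exact data to numerical precision", {
  net <- defaultNetwork()
  truth <- completeFluxes(net, defaultTestFluxes)
  measured <- simulateMDVs(net, truth)
  fit <- fitFluxes(net, measured, n_starts = 5, seed = 3)
  expect_true(fit@converged)
  expect_equal(fluxes(fit)[["V12"]], 100)
  for (f in names(defaultTestFluxes))
    expect_equal(fluxes(fit)[[f]], truth[[f]], tolerance = 1e-4)
  expect_lt(fit@ssr, 1e-6)
  expect_equal(fit@dof, 22L - 3L)   # 7+5+5+5 fractions minus 3 free fluxes
  expect_equal(fit@chi2_p, 1, tolerance = 1e-6)
})

test_that("SSR at the optimum is chi-squared calibrated", {
  net <- defaultNetwork()
  truth <- completeFluxes(net, defaultTestFluxes)
  clean <- simulateMDVs(net, truth)
  set.seed(17)
  ssr <- replicate(100, {
    noisy <- lapply(clean, function(m) m + rnorm(length(m), 0, 0.03))
    fitFluxes(net, noisy, mdv_se = 0.03, n_starts = 1, seed = 1,
              start = defaultTestFluxes)@ssr
  })
  dof <- 19
  # mean of n chi2(dof) draws: se = sqrt(2 dof / n)
  expect_lt(abs(mean(ssr) - dof), 3 * sqrt(2 * dof / 100) + 1)
})

test_that("chi-squared goodness of fit behaves at its limits", {
  expect_equal(chi2GoodnessOfFit(0, 10), 1)
  expect_lt(chi2GoodnessOfFit(1e6, 10), 1e-12)
  expect_equal(chi2GoodnessOfFit(qchisq(0.5, 200), 200), 0.5,
               tolerance = 1e-12)
  expect_lt(abs(chi2GoodnessOfFit(200, 200) - 0.5), 0.02)
  expect_error(chi2GoodnessOfFit(1, 0), "over-parameterized")
})

test_that("Monte-Carlo intervals collapse without noise and cover the estimate", {
  net <- defaultNetwork()
  truth <- completeFluxes(net, defaultTestFluxes)
  lab <- generateLabelling(net, truth, mdv_noise_sd = 0.03, n_samples = 4,
                           seed = 23)
  mm <- groupMeanMDVs(lab$mdv_noisy)
  fit <- fitFluxes(net, mm, n_starts = 3, seed = 5)
  fit_ci <- monteCarloCI(net, mm, fit, n_draws = 100, seed = 6)
  ci <- fluxCI(fit_ci)
  expect_true(all(ci[, "lower"] <= fluxes(fit_ci) + 1e-6))
  expect_true(all(ci[, "upper"] >= fluxes(fit_ci) - 1e-6))
  expect_equal(unname(ci["V12", ]), c(100, 100))
  expect_true(fit_ci@ci_reliable)
  # zero-noise draws collapse onto the point estimate
  tight <- monteCarloCI(net, mm, fit, n_draws = 20, seed = 7,
                        mdv_se = 1e-10)
  expect_lt(max(fluxCI(tight)[, "upper"] - fluxCI(tight)[, "lower"]), 1e-4)
})

test_that("interval-overlap comparison flags only disjoint fluxes", {
  net <- defaultNetwork()
  truth <- completeFluxes(net, defaultTestFluxes)
  mm <- simulateMDVs(net, truth)
  fit <- fitFluxes(net, mm, n_starts = 2, seed = 1)
  fit_a <- monteCarloCI(net, mm, fit, n_draws = 50, seed = 2)
  expect_true(all(!compareFluxes(fit_a, fit_a)$significant))
  nfl <- length(fluxes(fit_a))
  fit_b <- fit_a
  fit_b@ci[] <- cbind(rep(1, nfl), rep(2, nfl))  # [1,2] vs [3,4]: disjoint
  fit_c <- fit_a
  fit_c@ci[] <- cbind(rep(3, nfl), rep(4, nfl))
  expect_true(all(compareFluxes(fit_b, fit_c)$significant))
  fit_d <- fit_a
  fit_d@ci[] <- cbind(rep(1, nfl), rep(3, nfl))  # [1,3] vs [2,4]: overlap
  fit_e <- fit_a
  fit_e@ci[] <- cbind(rep(2, nfl), rep(4, nfl))
  expect_true(all(!compareFluxes(fit_d, fit_e)$significant))
})

test_that("reversible reactions split into forward and reverse halves", {
  net <- parseNetwork(text = "
substrate A 0 1
reference R1
free R2_rev
measured C
R1: A (a) -> B (a)
R2: B (a) <-> C (a)
R3: C (a) -> D (a)
")
  expect_true(all(c("R2", "R2_rev") %in% reactionIds(net)))
  v <- completeFluxes(net, c(R2_rev = 30))
  expect_silent(checkFluxBalance(net, v))
  expect_equal(v[["R2"]], 130)   # net forward flux stays 100
})
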