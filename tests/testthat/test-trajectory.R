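# Generate standardized profiles from the scenario templates plus noise.
templateProfiles <- function(n_per = 25L, noise = 0.05, seed = 7L,
                             tissue = "liver") {
  set.seed(seed)
  tpl <- TraceMet:::scenarioTemplates()
  rows <- list(); truth <- character()
  for (k in seq_len(nrow(tpl))) {
    for (i in seq_len(n_per)) {
      p <- tpl[k, ] + rnorm(3, 0, noise)
      p <- (p - mean(p)) / sd(p)
      rows[[length(rows) + 1L]] <- p
      truth <- c(truth, rownames(tpl)[k])
    }
  }
  m <- do.call(rbind, rows)
  list(profiles = data.frame(
         metabolite_id = sprintf("m%03d", seq_len(nrow(m))),
         tissue = tissue, baseline = m[, 1], precax = m[, 2], cax = m[, 3]),
       truth = truth)
}

test_that("profiles use the tumour baseline substitution and standardize", {
  v <- matrix(exp(seq(0.1, 4.8, length.out = 48)), 3, 16, byrow = TRUE)
  v[2, ] <- 100   # constant profile
  ms <- logTransform(toyMetaboSet(v))
  expect_warning(prof <- buildProfiles(ms), "constant")
  expect_equal(nrow(prof), 2L)
  expect_equal(rowMeans(as.matrix(prof[, 3:5])), c(0, 0),
               ignore_attr = TRUE, tolerance = 1e-12)
  # strictly increasing means stay strictly increasing after z-scaling
  expect_true(all(apply(as.matrix(prof[, 3:5]), 1, function(x)
    all(diff(x) > 0))))
  # tumour: baseline from NonCax, and Ctrl is absent by design
  vt <- matrix(exp(rnorm(36, 5, 0.1)), 3, 12)
  mt <- MetaboSet(vt, toySampleMeta(c("NonCax", "PreCax", "Cax"), 4,
                                    "tumour"),
                  toyMetaboliteMeta(sprintf("t%d", 1:3)))
  mt <- logTransform(mt)
  pt <- suppressWarnings(buildProfiles(mt))
  vL <- intensities(mt)
  grp <- sampleData(mt)$group
  manual <- rowMeans(vL[, grp == "NonCax"])
  z <- t(apply(cbind(manual, rowMeans(vL[, grp == "PreCax"]),
                     rowMeans(vL[, grp == "Cax"])), 1,
               function(x) (x - mean(x)) / sd(x)))
  expect_equal(pt$baseline, unname(z[, 1]), tolerance = 1e-12)
  # non-tumour tissue without Ctrl is an error
  expect_error(buildProfiles(
    logTransform(MetaboSet(vt, toySampleMeta(c("NonCax", "PreCax", "Cax"),
                                             4, "liver"),
                           toyMetaboliteMeta(sprintf("t%d", 1:3))))),
    "Ctrl")
})

test_that("fuzzy clustering recovers the generating templates", {
  tp <- templateProfiles(n_per = 25, noise = 0.05)
  cl <- fuzzyCluster(tp$profiles)
  expect_s4_class(cl, "FuzzyClustering")
  u <- memberships(cl)
  expect_equal(unname(rowSums(u)), rep(1, nrow(u)), tolerance = 1e-9)
  expect_true(all(u >= 0 & u <= 1))
  assigned <- SCENARIO_LABELS[hardAssignments(cl)]
  expect_gte(mean(assigned == tp$truth), 0.95)
  # noise-free template profiles: centroids converge onto the templates
  tp0 <- templateProfiles(n_per = 10, noise = 0)
  cl0 <- fuzzyCluster(tp0$profiles)
  expect_equal(unname(centroids(cl0)),
               unname(TraceMet:::scenarioTemplates()), tolerance = 1e-6)
  # a profile identical to a centroid has membership 1 there
  idx <- which(tp0$truth == "late-up")[1]
  expect_equal(unname(memberships(cl0)[idx, "late-up"]), 1, tolerance = 1e-9)
})

test_that("clustering is deterministic and needs enough profiles", {
  tp <- templateProfiles(n_per = 3, noise = 0.1, seed = 9)
  a <- fuzzyCluster(tp$profiles)
  b <- fuzzyCluster(tp$profiles)
  expect_identical(centroids(a), centroids(b))
  expect_identical(memberships(a), memberships(b))
  expect_error(fuzzyCluster(tp$profiles[1:5, ]), "at least 8")
})

test_that("Xie-Beni index equals the hand formula on a 4-point instance", {
  # two well-separated point masses, crisp memberships
  x <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(5, 5, 5), c(5.2, 5, 5))
  cl <- new("FuzzyClustering",
            centroids = rbind(c(0.1, 0, 0), c(5.1, 5, 5)),
            memberships = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
            fuzzifier = 2, xie_beni = NA_real_,
            scenario_labels = c("lo", "hi"),
            profile_ids = sprintf("p%d", 1:4), dispersions = c(1, 1))
  # numerator: 4 points each at squared distance 0.01 from their centroid;
  # denominator: n = 4 times squared centroid separation
  sep <- sum((c(0.1, 0, 0) - c(5.1, 5, 5))^2)
  expect_equal(xieBeniIndex(x, cl), (4 * 0.01) / (4 * sep),
               tolerance = 1e-12)
  # homogeneity: scaling points and centroids leaves XB unchanged
  cl2 <- cl
  cl2@centroids <- cl@centroids * 3
  expect_equal(xieBeniIndex(x * 3, cl2), xieBeniIndex(x, cl),
               tolerance = 1e-12)
  # moving clusters apart at fixed memberships lowers XB
  cl3 <- cl
  cl3@centroids[2, ] <- c(50.1, 50, 50)
  x3 <- x; x3[3:4, ] <- x[3:4, ] + 45
  expect_lt(xieBeniIndex(x3, cl3), xieBeniIndex(x, cl))
  # coincident centroids are degenerate
  cl4 <- cl
  cl4@centroids[2, ] <- cl4@centroids[1, ]
  expect_error(xieBeniIndex(x, cl4), "degenerate")
})

test_that("membership ranking is stable and respects ties", {
  tp <- templateProfiles(n_per = 20, noise = 0.08, seed = 13)
  cl <- fuzzyCluster(tp$profiles)
  rk <- rankMembers(cl, top_n = 10)
  expect_true(all(table(rk$cluster) <= 10))
  for (k in unique(rk$cluster)) {
    sub <- rk[rk$cluster == k, ]
    expect_true(all(diff(sub$membership) <= 1e-12))
    expect_equal(sub$rank, seq_len(nrow(sub)))
  }
  # a membership-1 profile ranks first in its cluster
  tp0 <- templateProfiles(n_per = 10, noise = 0)
  cl0 <- fuzzyCluster(tp0$profiles)
  rk0 <- rankMembers(cl0, top_n = 3)
  expect_true(all(abs(rk0$membership[rk0$rank == 1] - 1) < 1e-9))
  # top_n larger than the cluster returns the full sorted list
  rk_all <- rankMembers(cl, top_n = 1e6)
  expect_equal(nrow(rk_all), nrow(tp$profiles))
  expect_identical(rankMembers(cl, 10), rk)
})

test_that("contribution tables conserve counts and add across tissues", {
  tp1 <- templateProfiles(n_per = 6, noise = 0.05, seed = 3,
                          tissue = "liver")
  tp2 <- templateProfiles(n_per = 6, noise = 0.05, seed = 4,
                          tissue = "heart")
  meta <- toyMetaboliteMeta(unique(c(tp1$profiles$metabolite_id,
                                     tp2$profiles$metabolite_id)))
  both <- rbind(tp1$profiles, tp2$profiles)
  cl <- fuzzyCluster(both)
  ct <- contributionTables(cl, both, meta, min_membership = 0)
  expect_equal(sum(ct$tissue_by_cluster), nrow(both))
  expect_equal(sum(ct$cluster_by_class), nrow(both))
  expect_equal(ct$n_assigned, nrow(both))
  # additivity over tissue subsets at fixed clustering
  keep_liver <- both$tissue == "liver"
  u <- cl@memberships
  hard <- hardAssignments(cl)
  t_liver <- table(factor(both$tissue[keep_liver], levels = TISSUES),
                   factor(SCENARIO_LABELS[hard[keep_liver]],
                          levels = SCENARIO_LABELS))
  t_heart <- table(factor(both$tissue[!keep_liver], levels = TISSUES),
                   factor(SCENARIO_LABELS[hard[!keep_liver]],
                          levels = SCENARIO_LABELS))
  expect_equal(unclass(ct$tissue_by_cluster), unclass(t_liver + t_heart),
               ignore_attr = TRUE)
  # a single profile yields a single 1 in both tables
  one <- tp1$profiles[1, , drop = FALSE]
  u1 <- matrix(0, 1, 8); u1[1, 2] <- 1
  cl1 <- new("FuzzyClustering", centroids = TraceMet:::scenarioTemplates(),
             memberships = u1, fuzzifier = 2, xie_beni = 1,
             scenario_labels = SCENARIO_LABELS,
             profile_ids = paste0(one$tissue, ":", one$metabolite_id),
             dispersions = rep(1, 8))
  ct1 <- contributionTables(cl1, one, meta, min_membership = 0)
  expect_equal(sum(ct1$tissue_by_cluster), 1L)
  expect_equal(sum(ct1$cluster_by_class), 1L)
})

test_that("without variance weighting the solver matches reference fuzzy c-means", {
  tp <- templateProfiles(n_per = 20, noise = 0.1, seed = 17)
  x <- as.matrix(tp$profiles[, c("baseline", "precax", "cax")])
  ours <- fuzzyCluster(tp$profiles, variance_sensitive = FALSE)
  tpl <- TraceMet:::scenarioTemplates()
  cm <- e1071::cmeans(x, centers = tpl, m = 2, iter.max = 500)
  expect_equal(unname(centroids(ours)[rownames(tpl), ]),
               unname(cm$centers), tolerance = 1e-4)
  expect_equal(unname(memberships(ours)), unname(cm$membership),
               tolerance = 1e-4)
})

test_that("the Xie-Beni index is minimized at the true cluster number", {
  tp <- templateProfiles(n_per = 15, noise = 0.03, seed = 21)
  x <- as.matrix(tp$profiles[, c("baseline", "precax", "cax")])
  xb <- sapply(c(2, 4, 6, 8, 10, 12), function(cc) {
    set.seed(31)
    km <- kmeans(x, centers = cc, nstart = 10)
    d2 <- as.matrix(dist(rbind(km$centers, x)))^2
    d2 <- d2[-(1:cc), 1:cc, drop = FALSE]
    u <- t(apply(d2, 1, function(dd) {
      if (any(dd <= .Machine$double.eps)) as.numeric(dd == min(dd))
      else { w <- (1 / dd); w / sum(w) }
    }))
    num <- sum((u^2) * d2)
    sep <- as.matrix(dist(km$centers))^2
    diag(sep) <- Inf
    num / (nrow(x) * min(sep))
  })
  expect_equal(which.min(xb), 4L)   # c = 8 among {2,4,6,8,10,12}
})
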