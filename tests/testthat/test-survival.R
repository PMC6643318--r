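test_that("survival records derive from volume-threshold crossings", {
  ds <- toyDataset(list(
    list(arm = "treatment", volumes = 100 * exp(log(3) / 10 * c(0, 7, 14, 21))),
    list(arm = "vehicle", volumes = c(100, 80, 60, 50)),
    list(arm = "vehicle", volumes = c(100, 250, 600, 1500))))
  os <- deriveSurvival(ds, "tripling")
  expect_equal(nrow(os), 3L)
  m1 <- os[os$mouse_id == "m1", ]
  expect_equal(m1$event, 1L)
  expect_lt(abs(m1$time - 10), 1.5)  # linear interpolation of exact exp
  m2 <- os[os$mouse_id == "m2", ]
  expect_equal(m2$event, 0L)
  expect_equal(m2$time, 21)
  pfsRec <- deriveSurvival(ds, "doubling")
  expect_lte(pfsRec$time[1], os$time[1])
})

test_that("Cox fit is symmetric and honest under the null", {
  sim <- simulateSurvival(survSimConfig(nClusters = 150, micePerArm = 2,
                                        sigma2 = 0, tau2 = 0, w = 0),
                          seed = 3)
  cf <- fitCox(sim$records)
  expect_gt(cf@ci[2], 1)
  expect_lt(cf@ci[1], 1)
  # arm swap negates the log hazard exactly
  swapped <- sim$records
  swapped$treatment <- 1 - swapped$treatment
  cf2 <- fitCox(swapped)
  expect_equal(cf2@logHR, -cf@logHR, tolerance = 1e-8)
  # complete separation is refused
  r <- sim$records
  r$event[r$treatment == 1] <- 0
  expect_error(fitCox(r), "monotone")
})

test_that("frailty fit reduces to Cox when frailty variances vanish", {
  sim <- simulateSurvival(survSimConfig(nClusters = 40, micePerArm = 3,
                                        sigma2 = 0, tau2 = 0,
                                        w = log(0.6)), seed = 8)
  cf <- fitCox(sim$records)
  ff <- fitFrailty(sim$records, rhoFixed = 0)
  expect_lt(abs(ff@w - cf@logHR), 2 * cf@se)
  expect_lt(ff@sigma2, 0.1)
  expect_lt(ff@tau2, 0.1)
})

test_that("adaptive quadrature is stable in the number of nodes", {
  sim <- simulateSurvival(survSimConfig(nClusters = 25, micePerArm = 3),
                          seed = 9)
  f9 <- fitFrailty(sim$records, nodes = 9)
  f15 <- fitFrailty(sim$records, nodes = 15)
  expect_lt(abs(f9@logLik - f15@logLik), 1e-4)
  expect_equal(f9@w, f15@w, tolerance = 1e-4)
})

test_that("the marginal-likelihood gradient vanishes at the optimum", {
  sim <- simulateSurvival(survSimConfig(nClusters = 40, micePerArm = 3),
                          seed = 10)
  ff <- fitFrailty(sim$records)
  fd <- MCTrials:::.frailtyData(sim$records, character())
  g1 <- MCTrials:::.ghNorm(9L)
  gh <- list(z1 = rep(g1$z, times = 9), z2 = rep(g1$z, each = 9),
             w = as.vector(outer(g1$w, g1$w)))
  th <- c(ff@w, log(ff@weibullShape), log(ff@weibullScale),
          log(sqrt(ff@sigma2)),
          ff@rho * sqrt(ff@tau2),
          log(sqrt(pmax(ff@tau2 * (1 - ff@rho^2), 1e-300))))
  f0 <- MCTrials:::.frailtyNegLogLik(th, fd, gh, NULL, FALSE)
  grad <- vapply(seq_along(th), function(k) {
    h <- 1e-5
    tp <- th; tm <- th
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (MCTrials:::.frailtyNegLogLik(tp, fd, gh, NULL, FALSE) -
       MCTrials:::.frailtyNegLogLik(tm, fd, gh, NULL, FALSE)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(grad)), 0.05)
})

test_that("rescaling time only rescales the Weibull scale", {
  sim <- simulateSurvival(survSimConfig(nClusters = 30, micePerArm = 3),
                          seed = 11)
  f1 <- fitFrailty(sim$records)
  r3 <- sim$records
  r3$time <- r3$time * 3
  f3 <- fitFrailty(r3)
  expect_equal(f3@w, f1@w, tolerance = 1e-4)
  expect_equal(f3@sigma2, f1@sigma2, tolerance = 1e-4)
  expect_equal(f3@tau2, f1@tau2, tolerance = 1e-4)
  expect_equal(f3@weibullShape, f1@weibullShape, tolerance = 1e-4)
  expect_equal(f3@weibullScale, 3 * f1@weibullScale, tolerance = 1e-3)
})

test_that("size-1 clusters with tau2 = 0 approach the Weibull PH fit", {
  sim <- simulateSurvival(survSimConfig(nClusters = 300, micePerArm = 1,
                                        sigma2 = 0, tau2 = 0,
                                        w = log(0.5), shape = 1.3),
                          seed = 12)
  ff <- fitFrailty(sim$records, tau2Zero = TRUE)
  sr <- survival::survreg(survival::Surv(time, event) ~ treatment,
                          data = sim$records, dist = "weibull")
  wPH <- -coef(sr)[["treatment"]] / sr$scale
  expect_equal(ff@w, wPH, tolerance = 0.02)
  expect_equal(ff@weibullShape, 1 / sr$scale, tolerance = 0.02)
})

test_that("covariate effects are recovered", {
  sim <- simulateSurvival(survSimConfig(nClusters = 120, micePerArm = 2,
                                        sigma2 = 0.3, tau2 = 0.1,
                                        covariateEffect = 0.5), seed = 13)
  ff <- fitFrailty(sim$records, covariates = "x", rhoFixed = 0)
  expect_lt(abs(ff@beta[["x"]] - 0.5), 3 * ff@betaSe[["x"]])
})

test_that("variance Wald tests detect real frailty heterogeneity", {
  sim <- simulateSurvival(survSimConfig(nClusters = 80, micePerArm = 3,
                                        sigma2 = 0.5, tau2 = 0.2),
                          seed = 14)
  ff <- fitFrailty(sim$records, rhoFixed = 0)
  vt <- ff@varTests
  expect_true(all(vt$p[vt$component == "sigma2"] < 0.05))
  expect_false(any(vt$boundary))
  expect_true(ff@hrCI[1] < ff@hazardRatio & ff@hazardRatio < ff@hrCI[2])
})

test_that("baseline frailty tracks vehicle growth rates by construction", {
  # growth rates spread across models; event hazard rises with growth:
  # simulate volumes, derive tripling-time records, fit the frailty model
  cfg <- mctSimConfig(nModels = 40, micePerArm = 3,
                      modelCov = diag(c(0, 0.02^2)), residualSd = 0.15)
  sim <- simulateMCT(cfg, seed = 15)
  rec <- deriveSurvival(sim$dataset, "tripling")
  ff <- fitFrailty(rec, rhoFixed = 0)
  kc <- vehicleGrowthRates(sim$dataset)
  res <- frailtyGrowthCorrelation(ff, kc)
  expect_gt(res$r, 0)
  expect_gt(res$rSquared, 0.3)
  # permuting the model labels collapses the correlation
  set.seed(16)
  kcPerm <- setNames(sample(kc), names(kc))
  rPerm <- replicate(30, {
    kcp <- setNames(sample(kc), names(kc))
    frailtyGrowthCorrelation(ff, kcp)$r
  })
  expect_lt(abs(mean(rPerm)), 0.2)
  expect_error(frailtyGrowthCorrelation(ff, kc[1:2]), "at least 3")
})
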