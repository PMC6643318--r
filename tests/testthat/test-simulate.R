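test_that("the generator is deterministic given the seed", {
  a <- simulateMCT(mctSimConfig(nModels = 5, micePerArm = 2), seed = 42)
  b <- simulateMCT(mctSimConfig(nModels = 5, micePerArm = 2), seed = 42)
  expect_identical(mctVolumes(a$dataset), mctVolumes(b$dataset))
  expect_identical(a$truth$mouse, b$truth$mouse)
  c <- simulateMCT(mctSimConfig(nModels = 5, micePerArm = 2), seed = 43)
  expect_false(identical(mctVolumes(a$dataset), mctVolumes(c$dataset)))
  # seeding does not clobber the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(simulateMCT(mctSimConfig(nModels = 2), seed = 9))
  expect_identical(runif(1), x)
})

test_that("the deterministic limit reproduces the fixed effects exactly", {
  cfg <- mctSimConfig(nModels = 3, micePerArm = 2, beta1 = 0.06,
                      beta2 = -0.012, modelCov = diag(c(0, 0)),
                      mouseCov = diag(c(0, 0)), residualSd = 0,
                      initRange = NULL, beta0 = log(150))
  sim <- simulateMCT(cfg, seed = 1)
  vol <- mctVolumes(sim$dataset)
  slope <- ifelse(vol$arm == "treatment", 0.06 - 0.012, 0.06)
  expect_equal(log(vol$volume_mm3), log(150) + slope * vol$day,
               tolerance = 1e-12)
})

test_that("simulated random-effect moments match the configuration", {
  cfg <- mctSimConfig(nModels = 800, micePerArm = 1,
                      modelCov = diag(c(0, 0.02^2)),
                      mouseCov = diag(c(0.1^2, 0.012^2)))
  sim <- simulateMCT(cfg, seed = 77)
  u1 <- sim$truth$model$u1_model
  expect_lt(abs(sd(u1) - 0.02), 3 * 0.02 / sqrt(2 * 799))
  expect_lt(abs(mean(u1)), 3 * 0.02 / sqrt(800))
  # per-mouse vehicle slopes = beta1 + u1_model + u1_mouse
  veh <- sim$truth$mouse[sim$truth$mouse$arm == "vehicle", ]
  sdTot <- sqrt(0.02^2 + 0.012^2)
  expect_lt(abs(sd(veh$slope) - sdTot), 3 * sdTot / sqrt(2 * 799))
  # initial volumes log-uniform on [100, 300]
  expect_true(all(exp(sim$truth$model$baseline) >= 100 - 1e-9))
  expect_true(all(exp(sim$truth$model$baseline) <= 300 + 1e-9))
})

test_that("dropout truncates measurements after the threshold crossing", {
  cfg <- mctSimConfig(nModels = 30, micePerArm = 2, beta1 = 0.25,
                      dropoutThreshold = 3000, residualSd = 0.1)
  sim <- simulateMCT(cfg, seed = 5)
  curves <- growthCurves(sim$dataset)
  trunc <- vapply(curves, function(cu) length(cu@days) <
                    length(cfg$schedule), logical(1))
  expect_true(any(trunc))  # fast growth must hit 3000 mm^3
  for (cu in curves[trunc]) {
    # everything before the last retained day is at or below threshold
    expect_true(all(cu@volumes[-length(cu@volumes)] <= 3000))
  }
  # no truncation when the threshold is effectively infinite
  cfg2 <- mctSimConfig(nModels = 10, micePerArm = 2, beta1 = 0.25,
                       dropoutThreshold = 1e9, residualSd = 0.1)
  sim2 <- simulateMCT(cfg2, seed = 5)
  expect_true(all(vapply(growthCurves(sim2$dataset), function(cu)
    length(cu@days) == length(cfg2$schedule), logical(1))))
})

test_that("expression embeds one causal gene among standard-normal noise", {
  cfg <- mctSimConfig(nModels = 50, micePerArm = 2,
                      geneGrowthEffect = -0.015, geneTreatmentEffect = 0.015)
  sim <- simulateMCT(cfg, seed = 8)
  ex <- simulateExpression(sim$truth, nGenes = 40, seed = 9)
  expect_equal(dim(ex$expression), c(40L, 50L))
  expect_true(ex$causalGene %in% rownames(ex$expression))
  expect_identical(ex$expression[ex$causalGene, ],
                   setNames(sim$truth$model$gene, sim$truth$model$model_id))
  # planted effects shift the mouse-level slopes as configured (exactly,
  # once the latent random effects are subtracted)
  tr <- merge(sim$truth$mouse,
              sim$truth$model[c("model_id", "gene", "u1_model")])
  resid <- tr$slope - 0.06 - tr$u1_mouse - tr$u1_model -
    with(tr, ifelse(arm == "treatment",
                    cfg$beta2 + 0.015 * gene, 0))
  expect_equal(resid, -0.015 * tr$gene, tolerance = 1e-10)
})

test_that("simulated survival times follow the configured Weibull law", {
  cfg <- survSimConfig(nClusters = 1000, micePerArm = 1, sigma2 = 0,
                       tau2 = 0, w = 0, shape = 1.5, scale = 12,
                       horizon = 1e6)
  sim <- simulateSurvival(cfg, seed = 14)
  ks <- suppressWarnings(
    ks.test(sim$records$time, pweibull, shape = 1.5, scale = 12))
  expect_gt(ks$p.value, 0.01)
  # hazard ratio round trip without frailty at finite horizon
  cfg2 <- survSimConfig(nClusters = 400, micePerArm = 2, sigma2 = 0,
                        tau2 = 0, w = log(0.5))
  cf <- fitCox(simulateSurvival(cfg2, seed = 15)$records)
  expect_gt(hazardRatio(cf), 0.4)
  expect_lt(hazardRatio(cf), 0.6)
  # degenerate horizon: everything censored, with a warning
  expect_warning(s0 <- simulateSurvival(
    survSimConfig(nClusters = 3, horizon = 0), seed = 1), "horizon")
  expect_true(all(s0$records$event == 0))
})

test_that("different seeds give effectively independent replicates", {
  ms <- vapply(1:40, function(s)
    mean(log(mctVolumes(simulateMCT(mctSimConfig(nModels = 4,
      micePerArm = 1), seed = s)$dataset)$volume_mm3)), numeric(1))
  ms2 <- vapply(41:80, function(s)
    mean(log(mctVolumes(simulateMCT(mctSimConfig(nModels = 4,
      micePerArm = 1), seed = s)$dataset)$volume_mm3)), numeric(1))
  expect_gt(cor.test(ms, ms2)$p.value, 0.001)
})
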