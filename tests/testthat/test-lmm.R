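nearNoiselessConfig <- function() {
  mctSimConfig(nModels = 8, micePerArm = 2, beta1 = 0.06, beta2 = -0.012,
               modelCov = diag(c(0, 0)), mouseCov = diag(c(0, 0)),
               residualSd = 1e-6, initRange = NULL, beta0 = log(150))
}

test_that("fitLMM recovers the truth on near-noiseless data", {
  sim <- simulateMCT(nearNoiselessConfig(), seed = 2)
  fit <- fitLMM(sim$dataset)
  fe <- fixedEffects(fit)
  expect_equal(fe$estimate[fe$term == "(Intercept)"], log(150),
               tolerance = 1e-5)
  expect_equal(fe$estimate[fe$term == "Day"], 0.06, tolerance = 1e-5)
  expect_equal(fe$estimate[fe$term == "Day:Treatment"], -0.012,
               tolerance = 1e-5)
  expect_lt(fit@modelRanefCov[2, 2], 1e-8)
  expect_lt(fit@mouseRanefCov[2, 2], 1e-8)
  expect_lt(fit@residualSd, 1e-4)
})

test_that("rescaling volumes shifts only the intercept", {
  sim <- simulateMCT(mctSimConfig(nModels = 10, micePerArm = 2), seed = 4)
  f1 <- fitLMM(sim$dataset)
  vol <- mctVolumes(sim$dataset)
  vol$volume_mm3 <- vol$volume_mm3 * 37
  f2 <- fitLMM(MCTDataset(vol, modelCovariates(sim$dataset)))
  a <- fixedEffects(f1); b <- fixedEffects(f2)
  expect_equal(b$estimate[b$term == "(Intercept)"],
               a$estimate[a$term == "(Intercept)"] + log(37),
               tolerance = 1e-5)
  for (tm in c("Day", "Day:Treatment")) {
    expect_equal(b$estimate[b$term == tm], a$estimate[a$term == tm],
                 tolerance = 1e-4)
    expect_equal(b$p[b$term == tm], a$p[a$term == tm], tolerance = 1e-3)
  }
  expect_equal(f2@modelRanefCov[2, 2], f1@modelRanefCov[2, 2],
               tolerance = 1e-3)
})

test_that("swapping arm labels negates the treatment effect", {
  sim <- simulateMCT(mctSimConfig(nModels = 10, micePerArm = 3,
                                  beta2 = -0.02), seed = 6)
  f1 <- fitLMM(sim$dataset)
  vol <- mctVolumes(sim$dataset)
  vol$arm <- ifelse(vol$arm == "treatment", "vehicle", "treatment")
  f2 <- fitLMM(MCTDataset(vol, modelCovariates(sim$dataset)))
  b1 <- fixedEffects(f1); b2 <- fixedEffects(f2)
  expect_equal(b2$estimate[b2$term == "Day:Treatment"],
               -b1$estimate[b1$term == "Day:Treatment"], tolerance = 1e-4)
  expect_equal(b2$estimate[b2$term == "Day"],
               b1$estimate[b1$term == "Day"] +
                 b1$estimate[b1$term == "Day:Treatment"], tolerance = 1e-4)
})

test_that("with independent mice the fit agrees with a two-level oracle", {
  cfg <- mctSimConfig(nModels = 40, micePerArm = 1,
                      modelCov = diag(c(0, 0)),
                      mouseCov = diag(c(0.1^2, 0.015^2)),
                      beta2 = -0.02)
  sim <- simulateMCT(cfg, seed = 12)
  fit <- fitLMM(sim$dataset)
  # oracle: two-level model, mice independent (no model level)
  vol <- mctVolumes(sim$dataset)
  vol <- vol[vol$volume_mm3 > 0, ]
  d <- data.frame(y = log(vol$volume_mm3), Day = vol$day,
                  DayTrt = vol$day * (vol$arm == "treatment"),
                  mouse = paste(vol$model_id, vol$mouse_id))
  oracle <- lme4::lmer(y ~ Day + DayTrt + (Day | mouse), data = d,
                       control = lme4::lmerControl(calc.derivs = FALSE,
                         check.conv.singular = "ignore"))
  ob <- lme4::fixef(oracle)[["DayTrt"]]
  ose <- sqrt(diag(as.matrix(vcov(oracle))))[3]
  fe <- fixedEffects(fit)
  expect_lt(abs(fe$estimate[fe$term == "Day:Treatment"] - ob), 2 * ose)
})

test_that("cancer-type covariates enter as growth-rate interactions", {
  cfg <- mctSimConfig(nModels = 30, micePerArm = 2, residualSd = 0.1,
                      cancerTypes = c("ES", "GA", "LU"),
                      cancerTypeEffects = c(GA = 0.01, LU = 0.03))
  sim <- simulateMCT(cfg, seed = 21)
  fit <- fitLMM(sim$dataset, covariates = "cancer_type",
                covariateByTreatment = TRUE, referenceLevel = "ES")
  fe <- fixedEffects(fit)
  expect_true(all(c("Day:cancer_typeGA", "Day:cancer_typeLU",
                    "Day:cancer_typeGA:Treatment",
                    "Day:cancer_typeLU:Treatment") %in% fe$term))
  est <- function(tm) fe$estimate[fe$term == tm]
  se <- function(tm) fe$se[fe$term == tm]
  expect_lt(abs(est("Day:cancer_typeLU") - 0.03),
            3 * se("Day:cancer_typeLU"))
  expect_lt(abs(est("Day:cancer_typeGA") - 0.01),
            3 * se("Day:cancer_typeGA"))
})

test_that("a biomarker fit with an all-zero gene reduces to the base model", {
  sim <- simulateMCT(mctSimConfig(nModels = 8, micePerArm = 2), seed = 31)
  base <- fitLMM(sim$dataset)
  cov <- modelCovariates(sim$dataset)
  cov$gene0 <- 0
  ds <- MCTDataset(mctVolumes(sim$dataset), cov)
  suppressMessages(suppressWarnings(
    aug <- fitLMM(ds, covariates = "gene0", covariateByTreatment = TRUE)))
  fb <- fixedEffects(base); fa <- fixedEffects(aug)
  for (tm in c("(Intercept)", "Day", "Day:Treatment"))
    expect_equal(fa$estimate[fa$term == tm], fb$estimate[fb$term == tm],
                 tolerance = 1e-8)
})

test_that("the biomarker scan finds a strongly planted gene", {
  cfg <- mctSimConfig(nModels = 20, micePerArm = 3,
                      geneGrowthEffect = -0.015,
                      geneTreatmentEffect = 0.015)
  sim <- simulateMCT(cfg, seed = 41)
  ex <- simulateExpression(sim$truth, nGenes = 25, seed = 42)
  scan <- biomarkerScan(sim$dataset, ex$expression)
  expect_equal(scan$rank[scan$gene == ex$causalGene], 1L)
  expect_equal(order(scan$p)[1], which(scan$gene == ex$causalGene))
  expect_true(all(scan$padj >= scan$p, na.rm = TRUE))
  # constant genes are skipped and unranked
  ex2 <- ex$expression
  ex2[3, ] <- 1
  scan2 <- biomarkerScan(sim$dataset, ex2)
  expect_true(scan2$skipped[3])
  expect_true(is.na(scan2$rank[3]))
})

test_that("scan p-values are null-uniform when expression is permuted", {
  cfg <- mctSimConfig(nModels = 20, micePerArm = 3,
                      geneGrowthEffect = -0.015,
                      geneTreatmentEffect = 0.015)
  sim <- simulateMCT(cfg, seed = 51)
  ex <- simulateExpression(sim$truth, nGenes = 40, seed = 52)
  perm <- ex$expression
  set.seed(53)
  colnames(perm) <- sample(colnames(perm))  # break the model link
  scan <- biomarkerScan(sim$dataset, perm)
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the naive Spearman scan behaves on monotone genes", {
  set.seed(61)
  tgi <- setNames(runif(12), sprintf("M%02d", 1:12))
  ex <- rbind(mono = rank(tgi), anti = -rank(tgi) + 0.1 * rnorm(12) * 0,
              noise = rnorm(12), const = rep(1, 12))
  colnames(ex) <- names(tgi)
  scan <- naiveCorrelationScan(ex, tgi)
  expect_equal(scan$rho[scan$gene == "mono"], 1)
  expect_equal(scan$rho[scan$gene == "anti"], -1)
  expect_true(scan$skipped[scan$gene == "const"])
  expect_true(scan$rank[scan$gene == "mono"] <= 2)
})

test_that("gene-effect interpretation separates prognosis from benefit", {
  cfg <- mctSimConfig(nModels = 25, micePerArm = 3, residualSd = 0.15,
                      geneGrowthEffect = -0.02, geneTreatmentEffect = 0.02)
  sim <- simulateMCT(cfg, seed = 71)
  cov <- modelCovariates(sim$dataset)
  cov$Gene <- sim$truth$model$gene[match(cov$model_id,
                                         sim$truth$model$model_id)]
  ds <- MCTDataset(mctVolumes(sim$dataset), cov)
  fit <- fitLMM(ds, covariates = "Gene", covariateByTreatment = TRUE)
  rep <- interpretGeneEffects(fit)
  expect_match(rep$narrative, "slower untreated growth")
  expect_match(rep$narrative, "smaller treatment benefit")
  expect_lt(rep$growthEffect$estimate, 0)
  expect_gt(rep$treatmentModification$estimate, 0)
  # mean curves: high expression grows slower under vehicle
  mc <- rep$meanCurves
  vehHigh <- mc$log_tv[mc$arm == "vehicle" & mc$gene_level == "high"]
  vehLow <- mc$log_tv[mc$arm == "vehicle" & mc$gene_level == "low"]
  expect_lt(vehHigh[length(vehHigh)], vehLow[length(vehLow)])
  # a null fit yields a neutral narrative
  cfg0 <- mctSimConfig(nModels = 15, micePerArm = 2)
  sim0 <- simulateMCT(cfg0, seed = 72)
  cov0 <- modelCovariates(sim0$dataset)
  set.seed(73); cov0$Gene <- rnorm(nrow(cov0))
  fit0 <- fitLMM(MCTDataset(mctVolumes(sim0$dataset), cov0),
                 covariates = "Gene", covariateByTreatment = TRUE)
  expect_match(interpretGeneEffects(fit0)$narrative,
               "no clear effect.*no clear effect")
})
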