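## Run code under a seed without clobbering the caller's RNG stream.
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.checkCov2 <- function(m, what) {
  if (!is.matrix(m) || !identical(dim(m), c(2L, 2L)) ||
      any(abs(m - t(m)) > 1e-12) ||
      any(eigen(m, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop(what, " must be a symmetric positive semi-definite 2x2 matrix")
}

.rmvnorm2 <- function(n, cov) {
  ## 2-d normal draws via Cholesky-like factor robust to zero variances
  e <- eigen(cov, symmetric = TRUE)
  l <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2L)
  matrix(stats::rnorm(2L * n), n, 2L) %*% t(l)
}

#' Configuration of the synthetic-MCT generator
#'
#' Returns the parameter set driving [simulateMCT()]. The defaults are a
#' "cisplatin-like" reference preset for a balanced n:n trial of
#' subcutaneous xenografts: exponential growth at \code{beta1} = 0.06/day
#' (doubling time about 11.5 days, the order of magnitude of the vehicle
#' growth rate reported for gastric/esophageal PDX panels), a 21-day trial
#' measured twice a week (8 measurements), initial volumes log-uniform on
#' 100-300 mm^3 (the usual dosing-start range), residual SD 0.25 on log
#' volume (about 25\% caliper measurement CV), model-level growth-rate SD
#' 0.02/day and mouse-within-model slope SD 0.012/day, and euthanasia
#' (dropout) once a measured volume exceeds 3000 mm^3.
#'
#' @param nModels number of mouse models (clusters).
#' @param micePerArm mice per model in each of the vehicle and treatment
#'   arms (balanced n:n design).
#' @param schedule measurement days; day 0 is treatment initiation.
#' @param beta0 mean log initial volume, used only when
#'   \code{initRange = NULL}.
#' @param beta1 vehicle log-scale growth rate (per day).
#' @param beta2 treatment effect on the growth rate (per day); the effect
#'   ratio of a design is \code{beta2/beta1}.
#' @param modelCov 2x2 covariance of the model-level (intercept, day-slope)
#'   random effects. The default has zero intercept variance because the
#'   baseline spread comes from \code{initRange}.
#' @param mouseCov 2x2 covariance of the mouse-within-model (intercept,
#'   day-slope) random effects.
#' @param residualSd SD of the iid residual on log volume.
#' @param initRange range (mm^3) of log-uniform initial volumes, or NULL to
#'   use \code{beta0} plus the model/mouse intercept effects only.
#' @param dropoutThreshold volume (mm^3) above which subsequent
#'   measurements are truncated (the mouse is euthanized).
#' @param geneGrowthEffect,geneTreatmentEffect effect (per day, per SD of
#'   expression) of a planted causal gene on the growth slope and on the
#'   treatment-specific slope. The defaults, -0.015 and +0.015, mirror the
#'   opposite-signed, comparable-magnitude prognostic/predictive pattern of
#'   DNA-repair expression under platinum treatment; both 0 disables the
#'   plant.
#' @param nGenes number of genes in the simulated expression matrix.
#' @param cancerTypes optional character vector of cancer-type labels to
#'   assign models (uniformly); NULL gives a single unlabeled type.
#' @param cancerTypeEffects optional named growth-slope offsets (per day)
#'   by cancer type, reference type omitted or 0.
#' @return A list of class \code{mct_sim_config}.
#' @export
mctSimConfig <- function(nModels = 20L, micePerArm = 3L,
                         schedule = c(0, 3, 6, 9, 12, 15, 18, 21),
                         beta0 = log(150), beta1 = 0.06, beta2 = -0.012,
                         modelCov = diag(c(0, 0.02^2)),
                         mouseCov = diag(c(0.1^2, 0.012^2)),
                         residualSd = 0.25,
                         initRange = c(100, 300),
                         dropoutThreshold = 3000,
                         geneGrowthEffect = 0, geneTreatmentEffect = 0,
                         nGenes = 500L,
                         cancerTypes = NULL, cancerTypeEffects = NULL) {
  .checkCov2(modelCov, "modelCov"); .checkCov2(mouseCov, "mouseCov")
  stopifnot(nModels >= 1, micePerArm >= 1, length(schedule) >= 2,
            schedule[1] == 0, !is.unsorted(schedule, strictly = TRUE),
            residualSd >= 0, dropoutThreshold > 0)
  if (!is.null(initRange)) {
    stopifnot(length(initRange) == 2L, all(initRange > 0),
              initRange[1] <= initRange[2])
    if (dropoutThreshold <= initRange[2])
      stop("dropoutThreshold must exceed the largest initial volume")
  }
  structure(list(
    nModels = as.integer(nModels), micePerArm = as.integer(micePerArm),
    schedule = as.numeric(schedule), beta0 = beta0, beta1 = beta1,
    beta2 = beta2, modelCov = modelCov, mouseCov = mouseCov,
    residualSd = residualSd, initRange = initRange,
    dropoutThreshold = dropoutThreshold,
    geneGrowthEffect = geneGrowthEffect,
    geneTreatmentEffect = geneTreatmentEffect,
    nGenes = as.integer(nGenes),
    cancerTypes = cancerTypes, cancerTypeEffects = cancerTypeEffects),
    class = "mct_sim_config")
}

#' Simulate a mouse clinical trial with known ground truth
#'
#' Generates clustered longitudinal tumor volumes from the three-level
#' model
#' \deqn{\log TV_{tij} = \beta_0 + \beta_1 Day_t + \beta_2 Day_t
#'   Treatment_{ij} + u_{0j} + u_{1j} Day_t + u_{0i|j} + u_{1i|j} Day_t +
#'   \varepsilon_{tij}}
#' with model- and mouse-level random effects drawn from their configured
#' bivariate normal distributions, iid normal residuals, volumes
#' exponentiated back to mm^3, log-uniform initial volumes, and truncation
#' of measurements after a mouse's volume exceeds the dropout threshold.
#' When gene effects are configured, a per-model causal covariate
#' \eqn{g_j \sim N(0,1)} additionally shifts the growth slope by
#' \code{geneGrowthEffect * g_j} and the treatment slope by
#' \code{geneTreatmentEffect * g_j}; [simulateExpression()] embeds it into
#' an expression matrix.
#'
#' @param config an [mctSimConfig()] list.
#' @param seed integer seed (required; the generator is fully
#'   deterministic given the seed).
#' @return A list with \code{dataset} (an [MCTDataset-class]) and
#'   \code{truth}, a list holding every latent value (per-model gene value
#'   and random effects, per-mouse slopes and intercepts, the config).
#' @export
simulateMCT <- function(config = mctSimConfig(), seed) {
  stopifnot(inherits(config, "mct_sim_config"))
  .withSeed(seed, {
    G <- config$nModels; n <- config$micePerArm
    days <- config$schedule
    modelId <- sprintf("M%03d", seq_len(G))
    gene <- stats::rnorm(G)
    uModel <- .rmvnorm2(G, config$modelCov)
    ctype <- if (is.null(config$cancerTypes)) rep(NA_character_, G)
             else sample(config$cancerTypes, G, replace = TRUE)
    ctEff <- rep(0, G)
    if (!is.null(config$cancerTypeEffects)) {
      hit <- ctype %in% names(config$cancerTypeEffects)
      ctEff[hit] <- unlist(config$cancerTypeEffects)[ctype[hit]]
    }
    baseline <- if (is.null(config$initRange)) rep(config$beta0, G)
                else stats::runif(G, log(config$initRange[1]),
                                  log(config$initRange[2]))
    rows <- vector("list", G)
    mouseTruth <- vector("list", G)
    for (j in seq_len(G)) {
      arm <- rep(c("vehicle", "treatment"), each = n)
      trt <- as.numeric(arm == "treatment")
      nm <- 2L * n
      uMouse <- .rmvnorm2(nm, config$mouseCov)
      slope <- config$beta1 + ctEff[j] +
        config$geneGrowthEffect * gene[j] + uModel[j, 2L] + uMouse[, 2L] +
        (config$beta2 + config$geneTreatmentEffect * gene[j]) * trt
      icept <- baseline[j] + uModel[j, 1L] + uMouse[, 1L]
      mouseId <- sprintf("%s_%s%02d", arm, "m", c(seq_len(n), seq_len(n)))
      nd <- length(days)
      logv <- rep(icept, each = nd) + rep(slope, each = nd) * days +
        stats::rnorm(nm * nd, 0, config$residualSd)
      v <- exp(logv)
      keep <- unlist(lapply(seq_len(nm), function(i) {
        vi <- v[(i - 1L) * nd + seq_len(nd)]
        over <- which(vi > config$dropoutThreshold)
        kp <- rep(TRUE, nd)
        if (length(over) && over[1L] < nd) kp[(over[1L] + 1L):nd] <- FALSE
        kp
      }))
      rows[[j]] <- data.frame(
        model_id = modelId[j],
        mouse_id = rep(mouseId, each = nd)[keep],
        arm = rep(arm, each = nd)[keep],
        day = rep(days, nm)[keep],
        volume_mm3 = v[keep],
        stringsAsFactors = FALSE)
      mouseTruth[[j]] <- data.frame(
        model_id = modelId[j], mouse_id = mouseId, arm = arm,
        intercept = icept, slope = slope,
        u0_mouse = uMouse[, 1L], u1_mouse = uMouse[, 2L],
        stringsAsFactors = FALSE)
    }
    vol <- do.call(rbind, rows)
    cov <- data.frame(model_id = modelId, cancer_type = ctype,
                      stringsAsFactors = FALSE)
    truth <- list(
      config = config, seed = seed,
      model = data.frame(model_id = modelId, cancer_type = ctype,
                         gene = gene, baseline = baseline,
                         u0_model = uModel[, 1L], u1_model = uModel[, 2L],
                         stringsAsFactors = FALSE),
      mouse = do.call(rbind, mouseTruth))
    list(dataset = MCTDataset(vol, cov), truth = truth)
  })
}

#' Simulate a gene-by-model expression matrix with a planted biomarker
#'
#' Builds an expression matrix whose rows are marginally standard normal
#' across models. One row (the causal gene, at a random position) is the
#' per-model covariate value that drove the growth/treatment slopes in
#' [simulateMCT()]; the remaining genes are iid noise.
#'
#' @param truth the truth record returned by [simulateMCT()].
#' @param nGenes number of genes; defaults to the config's \code{nGenes}.
#' @param seed integer seed.
#' @return A list with \code{expression} (matrix, genes x models) and
#'   \code{causalGene} (its row name).
#' @export
simulateExpression <- function(truth, nGenes = NULL, seed) {
  stopifnot(is.list(truth), !is.null(truth$model))
  if (is.null(nGenes)) nGenes <- truth$config$nGenes
  nGenes <- as.integer(nGenes)
  stopifnot(nGenes >= 1)
  .withSeed(seed, {
    G <- nrow(truth$model)
    ex <- matrix(stats::rnorm(nGenes * G), nGenes, G,
                 dimnames = list(sprintf("gene%04d", seq_len(nGenes)),
                                 truth$model$model_id))
    pos <- sample.int(nGenes, 1L)
    ex[pos, ] <- truth$model$gene
    list(expression = ex, causalGene = rownames(ex)[pos])
  })
}

#' Configuration of the clustered survival-data generator
#'
#' Parameters for [simulateSurvival()], drawing event times from the
#' additive frailty model
#' \eqn{h_{ij}(t) = h_0(t)\exp(u_i + (w + v_i)T_{ij} + \beta x_i)} with
#' Weibull baseline \eqn{h_0(t) = (a/b)(t/b)^{a-1}}. Defaults give vehicle
#' median event times around 10 days (tumor tripling on the scale of the
#' growth preset) with administrative censoring at 60 days.
#'
#' @param nClusters number of mouse models (clusters).
#' @param micePerArm mice per cluster per arm.
#' @param w treatment log-hazard effect (hazard ratio \code{exp(w)}).
#' @param sigma2,tau2,rho variances of the baseline frailty \eqn{u_i} and
#'   treatment frailty \eqn{v_i}, and their correlation.
#' @param shape,scale Weibull baseline parameters (a, b above).
#' @param horizon administrative censoring time (days).
#' @param covariateEffect optional fixed effect of a model-level standard
#'   normal covariate \eqn{x_i}; 0 omits the covariate.
#' @return A list of class \code{mct_surv_config}.
#' @export
survSimConfig <- function(nClusters = 100L, micePerArm = 3L, w = log(0.5),
                          sigma2 = 0.5, tau2 = 0.2, rho = 0,
                          shape = 1.5, scale = 12, horizon = 60,
                          covariateEffect = 0) {
  stopifnot(nClusters >= 1, micePerArm >= 1, sigma2 >= 0, tau2 >= 0,
            abs(rho) <= 1, shape > 0, scale > 0, horizon >= 0)
  structure(list(nClusters = as.integer(nClusters),
                 micePerArm = as.integer(micePerArm), w = w,
                 sigma2 = sigma2, tau2 = tau2, rho = rho, shape = shape,
                 scale = scale, horizon = horizon,
                 covariateEffect = covariateEffect),
            class = "mct_surv_config")
}

#' Simulate clustered survival records with known frailties
#'
#' Event times are drawn by inverse transform from the cluster-conditional
#' Weibull hazard: with linear predictor \eqn{\eta}, \eqn{T = b(E /
#' e^{\eta})^{1/a}} for \eqn{E \sim Exp(1)}. Records are administratively
#' censored at the horizon.
#'
#' @param config a [survSimConfig()] list.
#' @param seed integer seed.
#' @return A list with \code{records} (data.frame with columns
#'   \code{model_id}, \code{mouse_id}, \code{treatment}, \code{time},
#'   \code{event}, and \code{x} when a covariate is configured) and
#'   \code{truth} (per-cluster \code{u}, \code{v}, the config).
#' @export
simulateSurvival <- function(config = survSimConfig(), seed) {
  stopifnot(inherits(config, "mct_surv_config"))
  .withSeed(seed, {
    G <- config$nClusters; n <- config$micePerArm
    cv <- config$rho * sqrt(config$sigma2 * config$tau2)
    uv <- .rmvnorm2(G, matrix(c(config$sigma2, cv, cv, config$tau2), 2L))
    x <- if (config$covariateEffect != 0) stats::rnorm(G) else rep(0, G)
    modelId <- sprintf("M%03d", seq_len(G))
    nm <- 2L * n
    trt <- rep(rep(c(0, 1), each = n), G)
    cluster <- rep(seq_len(G), each = nm)
    eta <- uv[cluster, 1L] + (config$w + uv[cluster, 2L]) * trt +
      config$covariateEffect * x[cluster]
    e <- stats::rexp(G * nm)
    t <- config$scale * (e / exp(eta))^(1 / config$shape)
    event <- t <= config$horizon
    time <- pmin(t, config$horizon)
    if (config$horizon <= 0) {
      warning("censoring horizon is 0: all records censored at the ",
              "smallest representable positive time")
      time <- rep(.Machine$double.eps, length(time))
      event <- rep(FALSE, length(event))
    }
    records <- data.frame(
      model_id = modelId[cluster],
      mouse_id = sprintf("%s_m%02d", c("vehicle", "treatment")[trt + 1L],
                         rep(c(seq_len(n), seq_len(n)), G)),
      treatment = trt, time = time, event = as.integer(event),
      stringsAsFactors = FALSE)
    if (config$covariateEffect != 0) records$x <- x[cluster]
    truth <- list(config = config, seed = seed,
                  cluster = data.frame(model_id = modelId, u = uv[, 1L],
                                       v = uv[, 2L], x = x,
                                       stringsAsFactors = FALSE))
    list(records = records, truth = truth)
  })
}
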