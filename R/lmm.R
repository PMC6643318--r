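## Assemble the long-format analysis frame for log-volume LMMs.
## Zero-volume observations cannot enter a log-scale fit and are dropped
## with a count (complete responses are handled by the categorical layer).
.lmmFrame <- function(dataset) {
  vol <- dataset@volumes
  drop0 <- vol$volume_mm3 <= 0
  vol <- vol[!drop0, , drop = FALSE]
  df <- data.frame(
    logTV = log(vol$volume_mm3),
    Day = vol$day,
    Treatment = as.numeric(vol$arm == "treatment"),
    model_id = vol$model_id,
    mouse_uid = paste(vol$model_id, vol$mouse_id, sep = "."),
    stringsAsFactors = FALSE)
  attr(df, "nDroppedZero") <- as.integer(sum(drop0))
  df
}

## lmer with deterministic optimizer restarts on non-convergence
.fitLmerRobust <- function(formula, data, optCtrl = list()) {
  ctrl <- function(opt) lme4::lmerControl(
    optimizer = opt, calc.derivs = FALSE,
    check.conv.singular = "ignore",
    optCtrl = if (opt == "nloptwrap") optCtrl else list())
  fit <- NULL; ok <- FALSE
  for (opt in c("nloptwrap", "bobyqa", "Nelder_Mead")) {
    fit <- withCallingHandlers(
      suppressMessages(lme4::lmer(formula, data = data, REML = TRUE,
                                  control = ctrl(opt))),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          invokeRestart("muffleWarning")
      })
    ok <- length(fit@optinfo$conv$lme4) == 0L &&
      isTRUE(fit@optinfo$conv$opt == 0L)
    if (ok) break
  }
  attr(fit, "mctConverged") <- ok
  fit
}

.lmmExtract <- function(fit, frame, termMap = NULL) {
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- b / se
  terms <- names(b)
  if (!is.null(termMap)) {
    hit <- terms %in% names(termMap)
    terms[hit] <- unlist(termMap)[terms[hit]]
  }
  fe <- data.frame(term = terms, estimate = unname(b), se = unname(se),
                   z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
                   stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  getCov <- function(name) {
    m <- matrix(0, 2, 2, dimnames = list(c("intercept", "Day"),
                                         c("intercept", "Day")))
    if (name %in% names(vc)) {
      v <- vc[[name]]
      m[seq_len(nrow(v)), seq_len(ncol(v))] <- as.matrix(v)[]
    }
    m
  }
  new("MCTLmmFit",
      fixedEffects = fe,
      modelRanefCov = getCov("model_id"),
      mouseRanefCov = getCov("mouse_uid"),
      residualSd = stats::sigma(fit),
      logLik = as.numeric(stats::logLik(fit)),
      nModels = length(unique(frame$model_id)),
      nMice = length(unique(frame$mouse_uid)),
      nObs = nrow(frame),
      nDroppedZero = attr(frame, "nDroppedZero"),
      converged = isTRUE(attr(fit, "mctConverged")),
      singular = lme4::isSingular(fit),
      fit = fit)
}

#' Fit a three-level linear mixed model to a mouse clinical trial
#'
#' Treats the MCT as a clustered longitudinal study: observations nested
#' in mice nested in models. The response is log tumor volume; the fixed
#' structure is an intercept, a day slope, and day-interactions with the
#' treatment indicator and any model-level covariates (covariates enter
#' only through day-interactions, i.e. they modify growth rates, matching
#' how cancer type and gene expression act on exponential kinetics).
#' Random structure: intercept + day-slope with unstructured 2x2
#' covariance at the model level and at the mouse-within-model level,
#' independent across levels, iid residuals. Estimation is REML; fixed
#' effects are tested by large-sample Wald z-tests.
#'
#' @param dataset an [MCTDataset-class].
#' @param covariates character vector of model-level covariate names (from
#'   [modelCovariates()]) entering day-interactions. Character/factor
#'   covariates are expanded to dummies against \code{referenceLevel}.
#' @param includeTreatment include the Day x Treatment effect.
#' @param covariateByTreatment also include Day x covariate x Treatment
#'   interactions.
#' @param referenceLevel reference level for categorical covariates
#'   (default: first sorted level).
#' @param fast use looser optimizer stopping tolerances (1e-4 instead of
#'   1e-6), shifting Wald z statistics by at most about 0.02; intended for
#'   simulation loops (power, type-I error) where thousands of fits are
#'   needed.
#' @return An [MCTLmmFit-class]. Term names follow the structure, e.g.
#'   \code{"Day:Treatment"}, \code{"Day:cancer_typeGA"},
#'   \code{"Day:cancer_typeGA:Treatment"}.
#' @examples
#' sim <- simulateMCT(mctSimConfig(nModels = 6, micePerArm = 2), seed = 1)
#' fit <- fitLMM(sim$dataset)
#' fixedEffects(fit)
#' @export
fitLMM <- function(dataset, covariates = character(),
                   includeTreatment = TRUE, covariateByTreatment = FALSE,
                   referenceLevel = NULL, fast = FALSE) {
  stopifnot(is(dataset, "MCTDataset"))
  frame <- .lmmFrame(dataset)
  cov <- dataset@modelCovariates
  covCols <- character(); termMap <- list()
  for (cn in covariates) {
    if (!cn %in% names(cov))
      stop("covariate '", cn, "' not found in modelCovariates")
    val <- cov[[cn]][match(frame$model_id, cov$model_id)]
    if (is.numeric(val)) {
      nm <- paste0("Day_", cn)
      frame[[nm]] <- frame$Day * val
      termMap[[nm]] <- paste0("Day:", cn)
      covCols <- c(covCols, nm)
    } else {
      val <- as.character(val)
      lev <- sort(unique(val))
      ref <- if (is.null(referenceLevel)) lev[1L] else referenceLevel
      if (!ref %in% lev)
        stop("referenceLevel '", ref, "' is not a level of ", cn)
      for (lv in setdiff(lev, ref)) {
        nm <- paste0("Day_", cn, "_", lv)
        frame[[nm]] <- frame$Day * (val == lv)
        termMap[[nm]] <- paste0("Day:", cn, lv)
        covCols <- c(covCols, nm)
      }
    }
  }
  fixed <- c("Day", covCols)
  if (includeTreatment) {
    frame$Day_Treatment <- frame$Day * frame$Treatment
    termMap[["Day_Treatment"]] <- "Day:Treatment"
    fixed <- c(fixed, "Day_Treatment")
  }
  if (covariateByTreatment) {
    for (nm in covCols) {
      nmi <- paste0(nm, "_Trt")
      frame[[nmi]] <- frame[[nm]] * frame$Treatment
      termMap[[nmi]] <- paste0(termMap[[nm]], ":Treatment")
      fixed <- c(fixed, nmi)
    }
  }
  mice <- unique(frame$mouse_uid)
  nPerMouse <- table(frame$mouse_uid)
  if (any(nPerMouse < 2))
    warning(sum(nPerMouse < 2),
            " mice have fewer than 2 positive-volume observations")
  fml <- stats::as.formula(paste(
    "logTV ~", paste(fixed, collapse = " + "),
    "+ (Day | model_id) + (Day | mouse_uid)"))
  optCtrl <- if (fast) list(xtol_abs = 1e-4, ftol_abs = 1e-4) else list()
  fit <- .fitLmerRobust(fml, frame, optCtrl)
  .lmmExtract(fit, frame, termMap)
}

#' @rdname fit-accessors
#' @export
setMethod("fixedEffects", "MCTLmmFit", function(x) x@fixedEffects)

setMethod("show", "MCTLmmFit", function(object) {
  cat(sprintf(
    "MCTLmmFit (REML): %d obs, %d mice, %d models%s%s\n",
    object@nObs, object@nMice, object@nModels,
    if (object@singular) " [singular]" else "",
    if (!object@converged) " [non-converged]" else ""))
  fe <- object@fixedEffects
  fe$estimate <- signif(fe$estimate, 4); fe$se <- signif(fe$se, 3)
  fe$z <- signif(fe$z, 3); fe$p <- signif(fe$p, 2)
  print(fe, row.names = FALSE)
  cat(sprintf("model-level SDs (icept, Day): %.4g, %.4g | mouse-level: %.4g, %.4g | resid: %.4g\n",
              sqrt(object@modelRanefCov[1, 1]), sqrt(object@modelRanefCov[2, 2]),
              sqrt(object@mouseRanefCov[1, 1]), sqrt(object@mouseRanefCov[2, 2]),
              object@residualSd))
})

#' Single-gene biomarker scan by linear mixed models
#'
#' For each gene, fits the three-level LMM
#' \deqn{\log TV = \beta_0 + \beta_1 Day + \beta_2 Day \cdot Gene +
#'   \beta_3 Day \cdot Treatment + \beta_4 Day \cdot Gene \cdot Treatment
#'   + random effects + \varepsilon}
#' where \eqn{Gene} is the model-level expression value (standardized
#' across models by default, for cross-gene comparability). \eqn{\beta_2}
#' captures the gene's prognostic effect on growth; \eqn{\beta_4} its
#' predictive effect on treatment benefit. Genes are ranked ascending by
#' the Wald p-value of \eqn{\beta_4}; Benjamini-Hochberg adjusted p-values
#' are appended. Genes constant across models are skipped and flagged.
#'
#' @param dataset an [MCTDataset-class] containing both arms.
#' @param expression genes-x-models matrix; defaults to the dataset's
#'   expression slot.
#' @param standardize standardize each gene to mean 0, SD 1 across models.
#' @param genes optional subset of gene names to scan.
#' @details Every gene is fitted by the same REML criterion as
#'   [fitLMM()]; the scan reuses the parsed model structure across genes,
#'   warm-starts each gene's variance parameters at the previous gene's
#'   optimum, and stops the optimizer at tolerance 1e-4 (z statistics
#'   stable to about 0.02), which makes genome-scale scans tractable.
#' @return \code{data.frame} with columns \code{gene}, \code{beta4},
#'   \code{se}, \code{z}, \code{p}, \code{padj}, \code{rank},
#'   \code{skipped}, ordered as the input genes.
#' @export
biomarkerScan <- function(dataset, expression = expressionMatrix(dataset),
                          standardize = TRUE, genes = NULL) {
  stopifnot(is(dataset, "MCTDataset"))
  if (is.null(expression))
    stop("no expression matrix supplied or attached to the dataset")
  frame <- .lmmFrame(dataset)
  models <- unique(frame$model_id)
  if (!all(models %in% colnames(expression)))
    stop("expression must cover every model in the dataset")
  if (!all(c(0, 1) %in% frame$Treatment))
    stop("biomarker scan needs both vehicle and treatment arms")
  if (!is.null(genes)) expression <- expression[genes, , drop = FALSE]
  frame$Day_Treatment <- frame$Day * frame$Treatment
  ## placeholder gene column keeps the full rank of the model matrix while
  ## the shared structure is parsed once; real values are swapped in below
  ph <- sin(seq_len(nrow(frame)))
  frame$Day_Gene <- ph
  frame$Day_Gene_Trt <- ph * frame$Treatment
  fml <- logTV ~ Day + Day_Gene + Day_Treatment + Day_Gene_Trt +
    (Day | model_id) + (Day | mouse_uid)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  lf <- lme4::lFormula(fml, data = frame, REML = TRUE, control = ctrl)
  n <- nrow(lf$X); pX <- ncol(lf$X)
  iB4 <- match("Day_Gene_Trt", colnames(lf$X))
  mIdx <- match(frame$model_id, colnames(expression))
  out <- data.frame(gene = rownames(expression),
                    beta4 = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, padj = NA_real_, rank = NA_integer_,
                    skipped = FALSE, stringsAsFactors = FALSE)
  theta <- NULL
  for (g in seq_len(nrow(expression))) {
    gv <- expression[g, ]
    if (stats::sd(gv) == 0) { out$skipped[g] <- TRUE; next }
    if (standardize) gv <- (gv - mean(gv)) / stats::sd(gv)
    gobs <- gv[mIdx]
    lf$X[, "Day_Gene"] <- frame$Day * gobs
    lf$X[, "Day_Gene_Trt"] <- frame$Day_Treatment * gobs
    res <- tryCatch({
      devfun <- do.call(lme4::mkLmerDevfun, lf)
      opt <- lme4::optimizeLmer(devfun, optimizer = "nloptwrap",
                                start = theta,
                                control = list(xtol_abs = 1e-4,
                                               ftol_abs = 1e-4))
      rho <- environment(devfun)
      beta <- rho$pp$beta(1)
      s2 <- (rho$resp$wrss() + rho$pp$sqrL(1)) / (n - pX)
      V <- s2 * rho$pp$unsc()
      list(theta = opt$par, est = beta[iB4], se = sqrt(V[iB4, iB4]))
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$se) || res$se <= 0) {
      out$skipped[g] <- TRUE; next
    }
    theta <- res$theta
    z <- res$est / res$se
    out$beta4[g] <- res$est; out$se[g] <- res$se; out$z[g] <- z
    out$p[g] <- 2 * stats::pnorm(-abs(z))
  }
  keep <- !out$skipped
  out$rank[keep] <- rank(out$p[keep], ties.method = "first")
  out$padj[keep] <- stats::p.adjust(out$p[keep], method = "BH")
  out
}

#' Naive correlation scan of expression against TGI
#'
#' The simple biomarker-discovery comparator: the Spearman rank
#' correlation of each gene's expression with a per-model efficacy readout
#' (typically TGI), ranked by absolute correlation, descending. Prone to
#' false positives relative to [biomarkerScan()], which uses the full
#' longitudinal data.
#'
#' @param expression genes-x-models numeric matrix.
#' @param tgiByModel named numeric vector of per-model TGI (names are
#'   model ids, must be covered by the expression columns).
#' @return \code{data.frame} with columns \code{gene}, \code{rho},
#'   \code{rank}, \code{skipped} (constant inputs, correlation undefined).
#' @export
naiveCorrelationScan <- function(expression, tgiByModel) {
  stopifnot(is.matrix(expression), length(tgiByModel) >= 3)
  if (is.null(names(tgiByModel)) ||
      !all(names(tgiByModel) %in% colnames(expression)))
    stop("tgiByModel must be named by model ids present in expression")
  ex <- expression[, names(tgiByModel), drop = FALSE]
  rho <- rep(NA_real_, nrow(ex))
  skipped <- apply(ex, 1L, stats::sd) == 0 | stats::sd(tgiByModel) == 0
  if (any(!skipped))
    rho[!skipped] <- suppressWarnings(
      as.numeric(stats::cor(t(ex[!skipped, , drop = FALSE]), tgiByModel,
                            method = "spearman")))
  out <- data.frame(gene = rownames(ex), rho = rho,
                    rank = NA_integer_, skipped = skipped,
                    stringsAsFactors = FALSE)
  out$rank[!skipped] <- rank(-abs(rho[!skipped]), ties.method = "first")
  out
}

#' Interpret prognostic vs predictive gene effects from a biomarker LMM
#'
#' Separates a gene's effect on untreated growth (the Day x Gene
#' coefficient, prognostic) from its effect on treatment benefit (the
#' Day x Gene x Treatment coefficient, predictive), and reconstructs mean
#' growth curves at low/high expression for both arms from the fixed
#' effects. A gene can slow untreated growth yet shrink the treatment
#' benefit (opposite-signed coefficients of comparable magnitude), which
#' is how a marker of better prognosis can coincide with less drug
#' benefit.
#'
#' @param fit an [MCTLmmFit-class] with \code{"Day:Gene"} and
#'   \code{"Day:Gene:Treatment"} terms (e.g. from [fitLMM()] with a gene
#'   covariate and \code{covariateByTreatment = TRUE}, terms named
#'   accordingly), or the internal fit produced for one gene.
#' @param geneTerm,geneTreatmentTerm term names of the prognostic and
#'   predictive coefficients in \code{fixedEffects(fit)}.
#' @param geneLevels expression values (in SD units for standardized
#'   genes) at which to draw the mean curves.
#' @param days day grid for the curves.
#' @param alpha significance level calling an effect present.
#' @return A list with \code{growthEffect}, \code{treatmentModification}
#'   (rows of the coefficient table), \code{narrative} (character), and
#'   \code{meanCurves} (data.frame: day, arm, gene_level, log_tv).
#' @export
interpretGeneEffects <- function(fit, geneTerm = "Day:Gene",
                                 geneTreatmentTerm = "Day:Gene:Treatment",
                                 geneLevels = c(low = -2, high = 2),
                                 days = seq(0, 21, by = 0.5),
                                 alpha = 0.05) {
  stopifnot(is(fit, "MCTLmmFit"))
  fe <- fit@fixedEffects
  pick <- function(term) {
    i <- match(term, fe$term)
    if (is.na(i)) stop("term '", term, "' not found in the fit")
    fe[i, , drop = FALSE]
  }
  b2 <- pick(geneTerm); b4 <- pick(geneTreatmentTerm)
  coefOr0 <- function(term) {
    i <- match(term, fe$term); if (is.na(i)) 0 else fe$estimate[i]
  }
  b0 <- coefOr0("(Intercept)"); b1 <- coefOr0("Day")
  b3 <- coefOr0("Day:Treatment")
  grid <- expand.grid(day = days, arm = c("vehicle", "treatment"),
                      gene_level = names(geneLevels),
                      stringsAsFactors = FALSE)
  g <- geneLevels[grid$gene_level]
  trt <- as.numeric(grid$arm == "treatment")
  grid$log_tv <- b0 + (b1 + b2$estimate * g +
                         (b3 + b4$estimate * g) * trt) * grid$day
  describe <- function(row, up, down) {
    if (row$p >= alpha) "no clear effect"
    else if (row$estimate > 0) up else down
  }
  narrative <- paste0(
    "Prognostic (growth) effect: ",
    describe(b2, "higher expression, faster untreated growth",
             "higher expression, slower untreated growth"),
    "; predictive (treatment) effect: ",
    describe(b4, "higher expression, smaller treatment benefit",
             "higher expression, larger treatment benefit"), ".")
  list(growthEffect = b2, treatmentModification = b4,
       narrative = narrative, meanCurves = grid)
}
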