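#' @import methods
NULL

.ARMS <- c("vehicle", "treatment")

#' GrowthCurve: one mouse's tumor-volume series
#'
#' A single mouse's longitudinal tumor-volume measurements, anchored at
#' treatment initiation (day 0). Volumes are in mm^3; a volume of exactly 0
#' encodes disappearance of measurable tumor mass (used by the CR/MCR
#' response categories).
#'
#' @slot mouseId character(1) mouse identifier, unique within its model.
#' @slot modelId character(1) mouse-model (e.g. PDX) identifier.
#' @slot arm character(1), \code{"vehicle"} or \code{"treatment"}.
#' @slot days integer-valued numeric vector, strictly increasing, starting
#'   at 0 (days since treatment initiation).
#' @slot volumes numeric vector of tumor volumes (mm^3), same length as
#'   \code{days}, non-negative.
#'
#' @seealso [GrowthCurve()] for the constructor, [fitExponential()],
#'   [timeToMultiple()], [rtv()].
#' @export
setClass("GrowthCurve",
  slots = c(
    mouseId = "character",
    modelId = "character",
    arm = "character",
    days = "numeric",
    volumes = "numeric"
  )
)

setValidity("GrowthCurve", function(object) {
  msg <- character()
  if (length(object@mouseId) != 1L) msg <- c(msg, "mouseId must be length 1")
  if (length(object@modelId) != 1L) msg <- c(msg, "modelId must be length 1")
  if (length(object@arm) != 1L || !object@arm %in% .ARMS)
    msg <- c(msg, "arm must be 'vehicle' or 'treatment'")
  d <- object@days; v <- object@volumes
  if (length(d) != length(v))
    msg <- c(msg, "days and volumes must have equal length")
  if (length(d) > 0L) {
    if (anyNA(d) || anyNA(v)) msg <- c(msg, "days/volumes must not contain NA")
    else {
      if (d[1L] != 0) msg <- c(msg, "first day must be 0 (treatment initiation)")
      if (any(d < 0)) msg <- c(msg, "days must be non-negative")
      if (length(d) > 1L && any(diff(d) <= 0))
        msg <- c(msg, "days must be strictly increasing")
      if (any(v < 0)) msg <- c(msg, "volumes must be non-negative")
    }
  }
  if (length(msg)) msg else TRUE
})

#' MCTDataset: a mouse clinical trial
#'
#' Container for one mouse clinical trial (MCT): a clustered collection of
#' [GrowthCurve-class] series (mice nested in mouse models), model-level
#' covariates, and an optional gene-by-model expression matrix.
#'
#' Internally the curves are stored as a long-format \code{data.frame} with
#' columns \code{model_id}, \code{mouse_id}, \code{arm}, \code{day},
#' \code{volume_mm3}, sorted by model, mouse and day. Missing measurements
#' are simply absent rows; no imputation is performed.
#'
#' @slot volumes long-format \code{data.frame} of measurements (see above).
#' @slot modelCovariates \code{data.frame} with one row per model; columns
#'   \code{model_id}, \code{cancer_type} and any additional covariates.
#' @slot expression either \code{NULL} or a numeric matrix with genes as rows
#'   and model ids as columns (log2-scale expression by convention).
#'
#' @seealso [MCTDataset()], [readMCT()], [growthCurves()], [simulateMCT()].
#' @export
setClass("MCTDataset",
  slots = c(
    volumes = "data.frame",
    modelCovariates = "data.frame",
    expression = "ANY"
  )
)

setValidity("MCTDataset", function(object) {
  msg <- character()
  vol <- object@volumes
  need <- c("model_id", "mouse_id", "arm", "day", "volume_mm3")
  if (!all(need %in% names(vol)))
    return(paste("volumes must have columns", paste(need, collapse = ", ")))
  cov <- object@modelCovariates
  if (!"model_id" %in% names(cov))
    return("modelCovariates must have a model_id column")
  if (nrow(vol)) {
    if (!all(vol$arm %in% .ARMS))
      msg <- c(msg, "arm must be 'vehicle' or 'treatment'")
    if (any(vol$volume_mm3 < 0)) msg <- c(msg, "volumes must be non-negative")
    if (any(vol$day < 0)) msg <- c(msg, "days must be non-negative")
    key <- paste(vol$model_id, vol$mouse_id, vol$day)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (model_id, mouse_id, day) measurement")
    ## a mouse must sit in exactly one arm of one model
    mk <- paste(vol$model_id, vol$mouse_id)
    if (anyDuplicated(unique(cbind(mk, vol$arm))[, 1L]))
      msg <- c(msg, "a mouse_id maps to more than one arm within a model")
    if (!all(unique(vol$model_id) %in% cov$model_id))
      msg <- c(msg, "every curve's model_id must appear in modelCovariates")
  }
  if (anyDuplicated(cov$model_id))
    msg <- c(msg, "duplicate model_id in modelCovariates")
  ex <- object@expression
  if (!is.null(ex)) {
    if (!is.matrix(ex) || !is.numeric(ex))
      msg <- c(msg, "expression must be NULL or a numeric matrix")
    else if (!all(unique(vol$model_id) %in% colnames(ex)))
      msg <- c(msg, "expression must have one column per model_id")
  }
  if (length(msg)) msg else TRUE
})

#' GrowthFit: log-linear exponential growth fit
#'
#' Result of fitting exponential kinetics \eqn{TV_d = TV_0 e^{kd}} to one
#' growth curve by ordinary least squares of \eqn{\ln TV} on day.
#'
#' @slot k growth rate per day (slope of log-volume on day).
#' @slot logTV0 fitted intercept, \eqn{\ln TV_0}.
#' @slot rSquared coefficient of determination of the log-linear fit
#'   (0 by convention when log-volume is constant).
#' @slot nPoints number of positive-volume points used.
#' @export
setClass("GrowthFit",
  slots = c(k = "numeric", logTV0 = "numeric", rSquared = "numeric",
            nPoints = "integer")
)

setValidity("GrowthFit", function(object) {
  msg <- character()
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MCTLmmFit: three-level linear mixed model fit
#'
#' REML fit of a three-level linear mixed model for log tumor volume
#' (observations within mice within models), with random intercept and
#' day-slope at the model level and at the mouse-within-model level, and
#' iid residuals.
#'
#' @slot fixedEffects \code{data.frame} with columns \code{term},
#'   \code{estimate}, \code{se}, \code{z}, \code{p} (Wald z-tests).
#' @slot modelRanefCov 2x2 covariance matrix of (intercept, day) random
#'   effects at the model level.
#' @slot mouseRanefCov 2x2 covariance matrix at the mouse-within-model level.
#' @slot residualSd residual standard deviation.
#' @slot logLik REML log-likelihood.
#' @slot nModels,nMice,nObs design counts.
#' @slot nDroppedZero number of zero-volume observations dropped before
#'   log-scale fitting.
#' @slot converged,singular fit status flags.
#' @slot fit the underlying \code{lme4::lmerMod} object.
#' @export
setClass("MCTLmmFit",
  slots = c(
    fixedEffects = "data.frame",
    modelRanefCov = "matrix",
    mouseRanefCov = "matrix",
    residualSd = "numeric",
    logLik = "numeric",
    nModels = "integer",
    nMice = "integer",
    nObs = "integer",
    nDroppedZero = "integer",
    converged = "logical",
    singular = "logical",
    fit = "ANY"
  )
)

setValidity("MCTLmmFit", function(object) {
  msg <- character()
  fe <- object@fixedEffects
  if (!all(c("term", "estimate", "se", "z", "p") %in% names(fe)))
    msg <- c(msg, "fixedEffects must have term/estimate/se/z/p columns")
  if (object@residualSd < 0) msg <- c(msg, "residualSd must be >= 0")
  ok <- function(m) all(eigen(m, symmetric = TRUE,
                              only.values = TRUE)$values > -1e-6)
  if (!ok(object@modelRanefCov) || !ok(object@mouseRanefCov))
    msg <- c(msg, "random-effect covariance must be positive semi-definite")
  if (length(msg)) msg else TRUE
})

#' MCTCoxFit: Cox proportional hazards fit of the treatment effect
#'
#' Partial-likelihood estimate (Breslow tie handling) of the treatment
#' log-hazard for survival records derived from tumor-volume threshold
#' crossings, ignoring the clustered structure.
#'
#' @slot logHR treatment log-hazard estimate.
#' @slot se its standard error.
#' @slot hazardRatio \code{exp(logHR)}.
#' @slot ci 95\% Wald confidence interval for the hazard ratio.
#' @slot nEvents,nRecords counts.
#' @slot fit the underlying \code{survival::coxph} object.
#' @export
setClass("MCTCoxFit",
  slots = c(logHR = "numeric", se = "numeric", hazardRatio = "numeric",
            ci = "numeric", nEvents = "integer", nRecords = "integer",
            fit = "ANY")
)

#' MCTFrailtyFit: additive frailty survival model fit
#'
#' Maximum marginal likelihood fit of the additive frailty model
#' \deqn{h_{ij}(t) = h_0(t)\exp(u_i + (w + v_i) T_{ij} + \beta^T X_i)}
#' with Weibull baseline hazard and bivariate normal model-level frailties
#' \eqn{(u_i, v_i)} with variances \eqn{\sigma^2, \tau^2} and correlation
#' \eqn{\rho}, integrated by Gauss-Hermite quadrature.
#'
#' @slot w treatment log-hazard effect and @slot wSe its standard error.
#' @slot beta,betaSe named fixed covariate effects and standard errors.
#' @slot sigma2 variance of the baseline frailty \eqn{u_i}.
#' @slot tau2 variance of the treatment frailty \eqn{v_i}.
#' @slot rho correlation of \eqn{(u_i, v_i)}.
#' @slot weibullShape,weibullScale baseline hazard parameters, with
#'   \eqn{h_0(t) = (shape/scale)(t/scale)^{shape-1}}.
#' @slot hazardRatio \code{exp(w)} and @slot hrCI its 95\% Wald interval.
#' @slot varTests Wald tests of \eqn{\sigma^2 > 0} and \eqn{\tau^2 > 0}.
#' @slot frailty per-model empirical Bayes frailty estimates (posterior
#'   means by quadrature), columns \code{model_id}, \code{u}, \code{v}.
#' @slot logLik marginal log-likelihood at the optimum.
#' @slot vcov variance-covariance of the transformed parameter vector.
#' @slot boundary names of variance components estimated at the 0 boundary.
#' @slot converged optimizer status.
#' @slot nClusters,nRecords,nEvents,nodes bookkeeping.
#' @export
setClass("MCTFrailtyFit",
  slots = c(
    w = "numeric", wSe = "numeric",
    beta = "numeric", betaSe = "numeric",
    sigma2 = "numeric", tau2 = "numeric", rho = "numeric",
    weibullShape = "numeric", weibullScale = "numeric",
    hazardRatio = "numeric", hrCI = "numeric",
    varTests = "data.frame",
    frailty = "data.frame",
    logLik = "numeric",
    vcov = "matrix",
    boundary = "character",
    converged = "logical",
    nClusters = "integer", nRecords = "integer", nEvents = "integer",
    nodes = "integer"
  )
)

setValidity("MCTFrailtyFit", function(object) {
  msg <- character()
  if (object@sigma2 < 0 || object@tau2 < 0)
    msg <- c(msg, "frailty variances must be >= 0")
  if (is.finite(object@rho) && abs(object@rho) > 1 + 1e-8)
    msg <- c(msg, "rho must lie in [-1, 1]")
  if (object@weibullShape <= 0 || object@weibullScale <= 0)
    msg <- c(msg, "Weibull parameters must be > 0")
  if (length(msg)) msg else TRUE
})
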