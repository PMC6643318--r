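#' Progression-free survival of one mouse
#'
#' PFS in mouse studies is defined as the tumor volume doubling time,
#' obtained by linear interpolation on the measured volumes (see
#' [timeToMultiple()] with \code{factor = 2}). Mice whose tumor never
#' doubles are censored at their last measured day.
#'
#' @param curve a [GrowthCurve-class] with positive initial volume.
#' @return A list with \code{time} (days) and \code{event} (FALSE =
#'   censored).
#' @export
pfs <- function(curve) timeToMultiple(curve, 2)

.checkCurves <- function(x, what) {
  if (!length(x) || !all(vapply(x, is, logical(1), "GrowthCurve")))
    stop(what, " must be a non-empty list of GrowthCurve objects")
}

.groupRTV <- function(curves, day, aggregate) {
  aggregate(vapply(curves, rtv, numeric(1), day = day))
}

#' RTV ratio between treatment and vehicle groups
#'
#' The ratio \eqn{RTV_t / RTV_c} at a specific day, where \eqn{RTV_t} and
#' \eqn{RTV_c} are the group-level relative tumor volumes, aggregated over
#' each group's mice (arithmetic mean by default, configurable to e.g.
#' median).
#'
#' @param treated,vehicle lists of [GrowthCurve-class] objects.
#' @param day evaluation day (within every curve's measured range).
#' @param aggregate function reducing per-mouse RTVs to a group RTV.
#' @return The ratio (dimensionless).
#' @export
rtvRatio <- function(treated, vehicle, day, aggregate = mean) {
  .checkCurves(treated, "treated"); .checkCurves(vehicle, "vehicle")
  rc <- .groupRTV(vehicle, day, aggregate)
  if (rc == 0) stop("RTV ratio undefined: vehicle group RTV is 0")
  .groupRTV(treated, day, aggregate) / rc
}

#' Tumor growth inhibition
#'
#' TGI at a specific day, in one of its two common definitions:
#' \code{variant = "rtv"} gives \eqn{1 - RTV_t/RTV_c};
#' \code{variant = "delta"} gives \eqn{1 - \Delta T/\Delta C} where
#' \eqn{\Delta T} and \eqn{\Delta C} are the mean volume changes from
#' baseline in the treatment and vehicle groups. TGI is a time-dependent
#' efficacy metric: under exponential growth both variants change with the
#' evaluation day (unlike the growth-rate and AUC ratios).
#'
#' @inheritParams rtvRatio
#' @param variant \code{"rtv"} or \code{"delta"}.
#' @return TGI as a fraction (1 = complete inhibition; > 1 means
#'   regression under the delta variant).
#' @export
tgi <- function(treated, vehicle, day, variant = c("rtv", "delta"),
                aggregate = mean) {
  variant <- match.arg(variant)
  if (variant == "rtv") return(1 - rtvRatio(treated, vehicle, day, aggregate))
  .checkCurves(treated, "treated"); .checkCurves(vehicle, "vehicle")
  delta <- function(curves) mean(vapply(curves, function(cu)
    volumeAt(cu, day) - cu@volumes[1L], numeric(1)))
  dc <- delta(vehicle)
  if (dc == 0) stop("TGI (delta) undefined: mean vehicle volume change is 0")
  1 - delta(treated) / dc
}

## common growth-rate slope for a group of mice: OLS of log-volume on day
## with one intercept per mouse (zero-volume points excluded)
.pooledSlope <- function(curves) {
  sxy <- 0; sxx <- 0
  for (cu in curves) {
    keep <- cu@volumes > 0
    if (sum(keep) < 2L) next
    d <- cu@days[keep]; y <- log(cu@volumes[keep])
    db <- d - mean(d)
    sxy <- sxy + sum(db * (y - mean(y)))
    sxx <- sxx + sum(db^2)
  }
  if (sxx == 0) stop("growth rate undefined: no mouse has 2+ positive volumes")
  sxy / sxx
}

#' Ratio of exponential growth rates between groups
#'
#' Fits exponential kinetics to each group (by default a common log-linear
#' slope with a separate intercept per mouse) and returns
#' \eqn{k_t / k_c}. With \code{perMouse = TRUE} the group rate is instead
#' the mean of per-mouse fitted slopes.
#'
#' @inheritParams rtvRatio
#' @param perMouse use the mean of per-mouse slopes instead of the pooled
#'   common-slope fit.
#' @return The ratio of growth rates (dimensionless).
#' @export
growthRateRatio <- function(treated, vehicle, perMouse = FALSE) {
  .checkCurves(treated, "treated"); .checkCurves(vehicle, "vehicle")
  rate <- if (perMouse) {
    function(curves) mean(vapply(curves, function(cu) fitExponential(cu)@k,
                                 numeric(1)))
  } else .pooledSlope
  kc <- rate(vehicle)
  if (kc == 0) stop("growth-rate ratio undefined: vehicle growth rate is 0")
  rate(treated) / kc
}

## mean log-RTV of a group evaluated on a day grid
.meanLogRTV <- function(curves, grid) {
  m <- vapply(curves, function(cu) {
    v0 <- cu@volumes[1L]
    if (v0 <= 0) stop("AUC ratio undefined: initial tumor volume is 0")
    vapply(grid, function(d) {
      v <- volumeAt(cu, d)
      if (v <= 0) stop("AUC ratio undefined: zero volume inside the window")
      log(v / v0)
    }, numeric(1))
  }, numeric(length(grid)))
  if (is.null(dim(m))) m else rowMeans(m)
}

#' AUC ratio between treatment and vehicle groups
#'
#' Trapezoid area under each group's mean log-RTV curve over a common
#' evaluation window \eqn{[0, T]}, returned as the treated/vehicle ratio.
#' The AUC is defined on the log-RTV scale so that under exact exponential
#' kinetics the areas are \eqn{k T^2/2} and the ratio reduces to the ratio
#' of growth rates, making it a day-independent efficacy metric.
#'
#' @inheritParams rtvRatio
#' @param window upper end \eqn{T} of the evaluation window; defaults to
#'   the largest day covered by every curve in both groups.
#' @return The AUC ratio (dimensionless).
#' @export
aucRatio <- function(treated, vehicle, window = NULL) {
  .checkCurves(treated, "treated"); .checkCurves(vehicle, "vehicle")
  all <- c(treated, vehicle)
  if (is.null(window))
    window <- min(vapply(all, .lastDay, numeric(1)))
  if (window <= 0) stop("no positive common evaluation window")
  grid <- sort(unique(c(0, window,
                        unlist(lapply(all, function(cu)
                          cu@days[cu@days <= window])))))
  trap <- function(y) sum(diff(grid) * (y[-1L] + y[-length(y)]) / 2)
  ac <- trap(.meanLogRTV(vehicle, grid))
  if (ac == 0) stop("AUC ratio undefined: vehicle area is 0")
  trap(.meanLogRTV(treated, grid)) / ac
}

#' All continuous endpoints for one model
#'
#' Convenience wrapper computing the five continuous efficacy endpoints for
#' one model's matched treatment and vehicle groups: group PFS (median of
#' per-mouse doubling times, censored times taken at face value), RTV
#' ratio, TGI (both variants), growth-rate ratio and AUC ratio.
#'
#' @param dataset an [MCTDataset-class].
#' @param model model id.
#' @param day evaluation day for the day-specific endpoints; defaults to
#'   the last day covered by every mouse of the model.
#' @return One-row \code{data.frame} of endpoint values.
#' @export
modelEndpoints <- function(dataset, model, day = NULL) {
  tr <- growthCurves(dataset, arm = "treatment", model = model)
  ve <- growthCurves(dataset, arm = "vehicle", model = model)
  .checkCurves(tr, "treated"); .checkCurves(ve, "vehicle")
  if (is.null(day))
    day <- min(vapply(c(tr, ve), .lastDay, numeric(1)))
  pfsTimes <- vapply(tr, function(cu) pfs(cu)$time, numeric(1))
  data.frame(
    model_id = model, eval_day = day,
    n_treated = length(tr), n_vehicle = length(ve),
    pfs_median = stats::median(pfsTimes),
    rtv_ratio = rtvRatio(tr, ve, day),
    tgi_rtv = tgi(tr, ve, day, "rtv"),
    tgi_delta = tgi(tr, ve, day, "delta"),
    growth_rate_ratio = growthRateRatio(tr, ve),
    auc_ratio = aucRatio(tr, ve, window = day),
    stringsAsFactors = FALSE)
}
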