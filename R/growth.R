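#' Fit exponential tumor-growth kinetics to one curve
#'
#' Tumor growth is modeled as \eqn{TV_d = TV_0 e^{kd}}; taking logs,
#' \eqn{\ln TV_d = \ln TV_0 + k d}, which is fitted by ordinary least
#' squares of log-volume on day. Zero-volume measurements (no measurable
#' tumor mass) are excluded from the fit, since complete responses are
#' handled by the categorical endpoint layer.
#'
#' @param curve a [GrowthCurve-class].
#' @return A [GrowthFit-class] with slots \code{k} (per day),
#'   \code{logTV0}, \code{rSquared} and \code{nPoints}. When log-volume is
#'   constant, \code{rSquared} is 0 by convention.
#' @examples
#' gc <- GrowthCurve("m", "p", "vehicle", c(0, 3, 7, 10),
#'                   100 * exp(0.06 * c(0, 3, 7, 10)))
#' fitExponential(gc)@k  # 0.06
#' @export
fitExponential <- function(curve) {
  stopifnot(is(curve, "GrowthCurve"))
  keep <- curve@volumes > 0
  if (sum(keep) < 2L)
    stop("fitExponential needs at least 2 positive-volume measurements")
  d <- curve@days[keep]
  y <- log(curve@volumes[keep])
  db <- d - mean(d); yb <- y - mean(y)
  sxx <- sum(db^2)
  k <- sum(db * yb) / sxx
  intercept <- mean(y) - k * mean(d)
  ssres <- sum((y - intercept - k * d)^2)
  sstot <- sum(yb^2)
  r2 <- if (sstot <= 0) 0 else max(0, min(1, 1 - ssres / sstot))
  new("GrowthFit", k = k, logTV0 = intercept, rSquared = r2,
      nPoints = as.integer(sum(keep)))
}

#' Interpolated tumor volume at an arbitrary day
#'
#' Returns the measured volume when \code{day} is a measurement day;
#' otherwise interpolates between the flanking measured days linearly on
#' the log-volume scale (matching exponential kinetics). When a flanking
#' volume is 0, the interpolation falls back to the volume scale, where it
#' is well defined.
#'
#' @param curve a [GrowthCurve-class].
#' @param day numeric day within the measured range.
#' @return Volume in mm^3.
#' @export
volumeAt <- function(curve, day) {
  stopifnot(is(curve, "GrowthCurve"), length(day) == 1L)
  d <- curve@days; v <- curve@volumes
  if (day < d[1L] || day > d[length(d)])
    stop(sprintf("day %g outside measured range [%g, %g]: refusing to extrapolate",
                 day, d[1L], d[length(d)]))
  hit <- which(d == day)
  if (length(hit)) return(v[hit[1L]])
  i <- findInterval(day, d)                  # d[i] < day < d[i+1]
  d1 <- d[i]; d2 <- d[i + 1L]; v1 <- v[i]; v2 <- v[i + 1L]
  f <- (day - d1) / (d2 - d1)
  if (v1 > 0 && v2 > 0) exp((1 - f) * log(v1) + f * log(v2))
  else (1 - f) * v1 + f * v2
}

#' First time the tumor reaches a multiple of its initial volume
#'
#' Computes the first crossing time of \code{factor * TV_0} by linear
#' interpolation on the volume scale between the flanking measured days:
#' for a crossing between days \eqn{d_1} and \eqn{d_2} with volumes
#' \eqn{TV_1, TV_2}, the time is
#' \eqn{d_1 + (d_2 - d_1)(f\,TV_0 - TV_1)/(TV_2 - TV_1)}. With
#' \code{factor = 2} this is the tumor volume doubling time used as
#' progression-free survival in mouse studies; \code{factor = 3} gives the
#' tripling time used as overall survival.
#'
#' @param curve a [GrowthCurve-class] with positive initial volume.
#' @param factor volume multiple (> 1), e.g. 2 for doubling.
#' @return A list with \code{time} (days), \code{event} (TRUE if the
#'   threshold was crossed; FALSE when the curve never reaches it, in which
#'   case \code{time} is the censoring time, the last measured day).
#' @examples
#' gc <- GrowthCurve("m", "p", "treatment", c(0, 7, 14), c(100, 100, 300))
#' timeToMultiple(gc, 2)  # crossed at 10.5 days
#' @export
timeToMultiple <- function(curve, factor) {
  stopifnot(is(curve, "GrowthCurve"), length(factor) == 1L, factor >= 1)
  v0 <- curve@volumes[1L]
  if (v0 <= 0) stop("timeToMultiple requires a positive initial volume")
  target <- factor * v0
  d <- curve@days; v <- curve@volumes
  hit <- which(v >= target)
  if (!length(hit)) return(list(time = d[length(d)], event = FALSE))
  j <- hit[1L]
  if (v[j] == target || j == 1L) return(list(time = d[j], event = TRUE))
  d1 <- d[j - 1L]; d2 <- d[j]; v1 <- v[j - 1L]; v2 <- v[j]
  list(time = d1 + (d2 - d1) * (target - v1) / (v2 - v1), event = TRUE)
}
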