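## Category sets and a progressiveness ranking (higher = more progressive)
## shared by the four classification methods.
.METHODS <- c("recist", "cat3", "mrecist", "cat5")

.CATEGORIES <- list(
  recist = c("CR", "PR", "SD", "PD"),
  cat3 = c("OR", "SD", "PD"),
  mrecist = c("CR", "PR", "SD", "PD"),
  cat5 = c("MCR", "CR", "PR", "SD", "PD")
)

.OBJECTIVE <- list(
  recist = c("CR", "PR"),
  cat3 = "OR",
  mrecist = c("CR", "PR"),
  cat5 = c("MCR", "CR", "PR")
)

.PROGRESSIVENESS <- c(PD = 5, SD = 4, PR = 3, OR = 3, CR = 2, MCR = 1)

#' Relative tumor volume
#'
#' RTV at day \eqn{d} is the tumor volume at \eqn{d} (interpolated between
#' measurements if necessary, see [volumeAt()]) divided by the volume at
#' treatment initiation (day 0). All four categorical response methods are
#' thresholds on RTV.
#'
#' @param curve a [GrowthCurve-class] with positive initial volume.
#' @param day day within the measured range.
#' @return RTV, a non-negative ratio (1 at day 0).
#' @export
rtv <- function(curve, day) {
  stopifnot(is(curve, "GrowthCurve"))
  v0 <- curve@volumes[1L]
  if (v0 <= 0) stop("RTV undefined: initial tumor volume is 0")
  volumeAt(curve, day) / v0
}

## RTV at every measured day (no interpolation), used by the
## whole-curve classifiers
.rtvSeries <- function(curve) {
  v0 <- curve@volumes[1L]
  if (v0 <= 0) stop("RTV undefined: initial tumor volume is 0")
  curve@volumes / v0
}

.lastDay <- function(curve) curve@days[length(curve@days)]

#' RECIST-based response classification
#'
#' Classifies a mouse's response from the RTV at the evaluation day:
#' CR if RTV = 0, PR if 0 < RTV <= 0.657, SD if 0.657 < RTV <= 1.728,
#' PD if RTV > 1.728.
#'
#' @param curve a [GrowthCurve-class].
#' @param evalDay evaluation day; defaults to the last measured day.
#' @return One of \code{"CR"}, \code{"PR"}, \code{"SD"}, \code{"PD"}.
#' @export
classifyRECIST <- function(curve, evalDay = NULL) {
  if (is.null(evalDay)) evalDay <- .lastDay(curve)
  r <- rtv(curve, evalDay)
  if (r == 0) "CR" else if (r <= 0.657) "PR" else if (r <= 1.728) "SD" else "PD"
}

#' Three-category response classification
#'
#' Objective response (OR) if RTV <= 0.65, PD if RTV >= 1.35, SD for
#' 0.65 < RTV < 1.35, evaluated at the evaluation day.
#'
#' @inheritParams classifyRECIST
#' @return One of \code{"OR"}, \code{"SD"}, \code{"PD"}.
#' @export
classify3cat <- function(curve, evalDay = NULL) {
  if (is.null(evalDay)) evalDay <- .lastDay(curve)
  r <- rtv(curve, evalDay)
  if (r <= 0.65) "OR" else if (r >= 1.35) "PD" else "SD"
}

#' mRECIST summary statistics
#'
#' The mRECIST criterion considers tumor growth kinetics from day 10 after
#' treatment initiation onward, through two RTV-based quantities evaluated
#' at measured days: the best response (minimum RTV over days >= 10) and
#' the best average response (minimum, over measured days t >= 10, of the
#' running mean of RTV from day 0 through t).
#'
#' @param curve a [GrowthCurve-class] with at least one measurement at
#'   day >= 10.
#' @return A list with \code{bestResponse} and \code{bestAvgResponse}.
#' @export
mrecistSummary <- function(curve) {
  r <- .rtvSeries(curve)
  d <- curve@days
  win <- d >= 10
  if (!any(win))
    stop("mRECIST needs at least one measurement at day >= 10")
  running <- cumsum(r) / seq_along(r)
  list(bestResponse = min(r[win]), bestAvgResponse = min(running[win]))
}

#' mRECIST classification thresholds
#'
#' Cutoffs on (best response, best average response), on the RTV scale,
#' evaluated in order CR, PR, SD (both conditions required), else PD.
#' The defaults are the Gao et al. criteria: CR if best < 0.05 and
#' average < 0.60; PR if best < 0.50 and average < 0.80; SD if best < 1.35
#' and average < 1.30.
#'
#' @return Named list of (best, avg) cutoff pairs.
#' @export
mrecistThresholds <- function() {
  list(CR = c(best = 0.05, avg = 0.60),
       PR = c(best = 0.50, avg = 0.80),
       SD = c(best = 1.35, avg = 1.30))
}

#' mRECIST response classification
#'
#' Thresholds the pair (best response, best average response) from
#' [mrecistSummary()]; see [mrecistThresholds()]. Because the best average
#' response runs from day 0, a tumor that grows substantially before
#' shrinking late can be classified PD even if it eventually disappears.
#'
#' @inheritParams mrecistSummary
#' @param thresholds cutoffs as returned by [mrecistThresholds()].
#' @return One of \code{"CR"}, \code{"PR"}, \code{"SD"}, \code{"PD"}.
#' @export
classifyMRECIST <- function(curve, thresholds = mrecistThresholds()) {
  s <- mrecistSummary(curve)
  for (cat in c("CR", "PR", "SD")) {
    th <- thresholds[[cat]]
    if (s$bestResponse < th[["best"]] && s$bestAvgResponse < th[["avg"]])
      return(cat)
  }
  "PD"
}

#' Five-category response classification
#'
#' Uses the minimum RTV during the study period (measured days after day 0)
#' and the RTV at end of study, tested in order: MCR if RTV = 0 at end of
#' study; CR if RTV = 0 at at least one time point; PR if RTV <= 0.50 at at
#' least one time point; SD if RTV <= 1.25 at end of study; PD otherwise.
#'
#' @param curve a [GrowthCurve-class].
#' @param endDay end-of-study day; defaults to the last measured day.
#' @return One of \code{"MCR"}, \code{"CR"}, \code{"PR"}, \code{"SD"},
#'   \code{"PD"}.
#' @export
classify5cat <- function(curve, endDay = NULL) {
  if (is.null(endDay)) endDay <- .lastDay(curve)
  r <- .rtvSeries(curve)
  keep <- curve@days > 0 & curve@days <= endDay
  rEnd <- rtv(curve, endDay)
  if (rEnd == 0) return("MCR")
  if (any(r[keep] == 0)) return("CR")
  if (any(r[keep] <= 0.50)) return("PR")
  if (rEnd <= 1.25) "SD" else "PD"
}

#' Majority response of a group of mice
#'
#' The response of a treatment model is the majority (modal) response of
#' its mice. Ties are broken toward the more progressive category
#' (PD > SD > PR/OR > CR > MCR), a conservative efficacy call.
#'
#' @param categories character vector of per-mouse categories, all from the
#'   same method.
#' @param method one of \code{"recist"}, \code{"cat3"}, \code{"mrecist"},
#'   \code{"cat5"}.
#' @return The majority category.
#' @export
majorityResponse <- function(categories, method = c("recist", "cat3",
                                                    "mrecist", "cat5")) {
  method <- match.arg(method)
  if (!length(categories)) stop("majorityResponse needs at least one call")
  bad <- setdiff(categories, .CATEGORIES[[method]])
  if (length(bad))
    stop(sprintf("categories %s are not valid for method '%s'",
                 paste(unique(bad), collapse = ", "), method))
  counts <- table(categories)
  modal <- names(counts)[counts == max(counts)]
  modal[which.max(.PROGRESSIVENESS[modal])]
}

#' Per-mouse response calls for a whole trial
#'
#' Applies one categorical method to every mouse in the chosen arm.
#' For the single-day methods (RECIST, 3-cat) the default evaluation day is
#' the last day measured on every mouse (the last common measured day),
#' with log-linear interpolation for mice not measured exactly on it.
#'
#' @param dataset an [MCTDataset-class].
#' @param method classification method.
#' @param evalDay evaluation day for recist/cat3 (end-of-study day for
#'   cat5); default last common measured day.
#' @param arm which arm to classify (default \code{"treatment"}).
#' @param checkInitial if TRUE, warn about mice whose initial volume is
#'   outside the admissible 50-300 mm^3 range.
#' @return \code{data.frame} with columns \code{model_id}, \code{mouse_id},
#'   \code{method}, \code{category}.
#' @export
responseCalls <- function(dataset, method = c("recist", "cat3", "mrecist",
                                              "cat5"),
                          evalDay = NULL, arm = "treatment",
                          checkInitial = FALSE) {
  method <- match.arg(method)
  curves <- growthCurves(dataset, arm = arm)
  if (!length(curves)) stop("no curves in arm '", arm, "'")
  if (is.null(evalDay) && method %in% c("recist", "cat3", "cat5")) {
    evalDay <- min(vapply(curves, .lastDay, numeric(1)))
  }
  if (checkInitial) {
    v0 <- vapply(curves, function(cu) cu@volumes[1L], numeric(1))
    out <- v0 < 50 | v0 > 300
    if (any(out))
      warning(sprintf("%d mice have initial volume outside 50-300 mm^3",
                      sum(out)))
  }
  category <- vapply(curves, function(cu) {
    switch(method,
           recist = classifyRECIST(cu, evalDay),
           cat3 = classify3cat(cu, evalDay),
           mrecist = classifyMRECIST(cu),
           cat5 = classify5cat(cu, evalDay))
  }, character(1))
  data.frame(
    model_id = vapply(curves, function(cu) cu@modelId, character(1)),
    mouse_id = vapply(curves, function(cu) cu@mouseId, character(1)),
    method = method, category = category,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Majority response per model
#'
#' @param calls per-mouse calls from [responseCalls()].
#' @return \code{data.frame} with columns \code{model_id}, \code{method},
#'   \code{category} (the majority response) and \code{n_mice}.
#' @export
majorityTable <- function(calls) {
  stopifnot(all(c("model_id", "method", "category") %in% names(calls)))
  method <- unique(calls$method)
  if (length(method) != 1L)
    stop("calls must all come from a single method")
  sp <- split(calls$category, calls$model_id)
  data.frame(
    model_id = names(sp),
    method = method,
    category = vapply(sp, majorityResponse, character(1), method = method),
    n_mice = lengths(sp),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Objective response rate
#'
#' Fraction of models whose majority response falls in the method's
#' objective-response set: OR for 3-cat, CR + PR for RECIST and mRECIST,
#' MCR + CR + PR for 5-cat.
#'
#' @param majorities character vector of per-model majority categories (or
#'   a [majorityTable()] result).
#' @param method classification method.
#' @return Fraction in [0, 1].
#' @export
objectiveResponseRate <- function(majorities, method = c("recist", "cat3",
                                                         "mrecist", "cat5")) {
  method <- match.arg(method)
  if (is.data.frame(majorities)) majorities <- majorities$category
  if (!length(majorities)) stop("objectiveResponseRate needs at least one model")
  bad <- setdiff(majorities, .CATEGORIES[[method]])
  if (length(bad))
    stop(sprintf("categories %s are not valid for method '%s'",
                 paste(unique(bad), collapse = ", "), method))
  mean(majorities %in% .OBJECTIVE[[method]])
}
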