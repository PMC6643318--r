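#' Subsampling accuracy of categorical response calls
#'
#' Quantifies how measurement accuracy of the majority response grows with
#' the number of mice: for each model, n mice are drawn (without
#' replacement by default) from the chosen arm, their majority response is
#' computed with the same tie-break as [majorityResponse()], and compared
#' with the majority response of all mice. Accuracy is the fraction of
#' replications that agree, summarized per actual-majority category
#' (mean and SD across models) together with the unweighted average across
#' the method's categories.
#'
#' @param dataset an [MCTDataset-class].
#' @param method classification method (see [responseCalls()]).
#' @param nValues subsample sizes (each must not exceed the smallest group
#'   when sampling without replacement).
#' @param replications random draws per model and n (the reference
#'   procedure uses 1000).
#' @param seed integer seed (required; results are reproducible
#'   bit-for-bit).
#' @param evalDay,arm passed to [responseCalls()].
#' @param replace sample with replacement instead.
#' @return A list of class \code{mct_accuracy_curve} with elements
#'   \code{perCategory} (data.frame: n, category, mean, sd, n_models),
#'   \code{unweighted} (data.frame: n, accuracy), \code{perModel},
#'   \code{nValues}, \code{replications}, \code{method}.
#' @export
categoricalAccuracy <- function(dataset, method = c("recist", "cat3",
                                                    "mrecist", "cat5"),
                                nValues = c(1, 3, 5, 7),
                                replications = 1000, seed,
                                evalDay = NULL, arm = "treatment",
                                replace = FALSE) {
  method <- match.arg(method)
  calls <- responseCalls(dataset, method, evalDay = evalDay, arm = arm)
  byModel <- split(calls$category, calls$model_id)
  sizes <- lengths(byModel)
  if (!replace && max(nValues) > min(sizes))
    stop(sprintf("subsample size %d exceeds the smallest group (%d mice)",
                 max(nValues), min(sizes)))
  fullMaj <- vapply(byModel, majorityResponse, character(1), method = method)
  .withSeed(seed, {
    perModel <- expand.grid(model_id = names(byModel), n = nValues,
                            stringsAsFactors = FALSE)
    perModel$majority <- fullMaj[perModel$model_id]
    perModel$accuracy <- NA_real_
    for (i in seq_len(nrow(perModel))) {
      cats <- byModel[[perModel$model_id[i]]]
      n <- perModel$n[i]
      agree <- vapply(seq_len(replications), function(r)
        majorityResponse(sample(cats, n, replace = replace),
                         method = method) == perModel$majority[i],
        logical(1))
      perModel$accuracy[i] <- mean(agree)
    }
    perCat <- do.call(rbind, lapply(nValues, function(n) {
      sub <- perModel[perModel$n == n, ]
      sp <- split(sub$accuracy, sub$majority)
      data.frame(n = n, category = names(sp),
                 mean = vapply(sp, mean, numeric(1)),
                 sd = vapply(sp, stats::sd, numeric(1)),
                 n_models = lengths(sp),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    unweighted <- do.call(rbind, lapply(nValues, function(n) {
      sub <- perCat[perCat$n == n, ]
      data.frame(n = n, accuracy = mean(sub$mean))
    }))
    structure(list(perCategory = perCat, unweighted = unweighted,
                   perModel = perModel, nValues = nValues,
                   replications = replications, method = method,
                   seed = seed),
              class = "mct_accuracy_curve")
  })
}

## Per-mouse primitives from which every continuous endpoint of a
## subsample can be recomputed by index arithmetic.
.mouseStats <- function(curves, day, grid) {
  n <- length(curves)
  out <- data.frame(pfs = rep(NA_real_, n), rtv = NA_real_,
                    delta = NA_real_, sxx = NA_real_, sxy = NA_real_,
                    area = NA_real_)
  for (i in seq_len(n)) {
    cu <- curves[[i]]
    v0 <- cu@volumes[1L]
    if (v0 > 0) {
      out$pfs[i] <- pfs(cu)$time
      out$rtv[i] <- rtv(cu, day)
      out$delta[i] <- volumeAt(cu, day) - v0
      if (all(cu@volumes > 0))
        out$area[i] <- {
          y <- vapply(grid, function(d) log(volumeAt(cu, d) / v0), numeric(1))
          sum(diff(grid) * (y[-1L] + y[-length(y)]) / 2)
        }
    }
    keep <- cu@volumes > 0
    if (sum(keep) >= 2L) {
      d <- cu@days[keep]; y <- log(cu@volumes[keep]); db <- d - mean(d)
      out$sxx[i] <- sum(db^2); out$sxy[i] <- sum(db * (y - mean(y)))
    }
  }
  out
}

.endpointFromStats <- function(endpoint, st, sc, it, iv) {
  ratio <- function(num, den) if (!is.finite(den) || den == 0) NA_real_
                              else num / den
  switch(endpoint,
    pfs = stats::median(st$pfs[it]),
    rtv_ratio = ratio(mean(st$rtv[it]), mean(sc$rtv[iv])),
    tgi_rtv = 1 - ratio(mean(st$rtv[it]), mean(sc$rtv[iv])),
    tgi_delta = 1 - ratio(mean(st$delta[it]), mean(sc$delta[iv])),
    growth_rate_ratio = ratio(
      sum(st$sxy[it]) / sum(st$sxx[it]),
      sum(sc$sxy[iv]) / sum(sc$sxx[iv])),
    auc_ratio = ratio(mean(st$area[it]), mean(sc$area[iv])))
}

#' Subsampling error of continuous endpoints
#'
#' For each eligible model (at least \code{minMice} mice in the relevant
#' arm(s)), the endpoint computed from n randomly subsampled mice is
#' compared with the all-mice value; the distribution of errors over
#' models and replications gives the accuracy/mouse-number relationship.
#' PFS is a one-arm endpoint (group value: median of per-mouse doubling
#' times, censored times at face value); the others subsample both arms.
#' Replications where the endpoint is undefined on the subsample are
#' recorded as missing and counted.
#'
#' @param dataset an [MCTDataset-class].
#' @param endpoint one of \code{"pfs"}, \code{"rtv_ratio"},
#'   \code{"tgi_rtv"}, \code{"tgi_delta"}, \code{"growth_rate_ratio"},
#'   \code{"auc_ratio"}.
#' @param nValues subsample sizes (mice per arm).
#' @param replications draws per model and n.
#' @param seed integer seed (required).
#' @param errorType \code{"percent"} (|sub - full| / |full| x 100) or
#'   \code{"absolute"} (|sub - full|).
#' @param day evaluation day for day-specific endpoints and AUC window;
#'   default last day covered by every mouse.
#' @param minMice inclusion threshold (the reference analyses use models
#'   with at least 10 mice).
#' @return A list of class \code{mct_error_ecdf}: \code{errors}
#'   (data.frame: model_id, n, rep, error; NA = undefined),
#'   \code{missingRate} (per n), \code{fullValues}, \code{errorType}.
#' @export
continuousError <- function(dataset,
                            endpoint = c("pfs", "rtv_ratio", "tgi_rtv",
                                         "tgi_delta", "growth_rate_ratio",
                                         "auc_ratio"),
                            nValues = 1:5, replications = 1000, seed,
                            errorType = c("percent", "absolute"),
                            day = NULL, minMice = 10) {
  endpoint <- match.arg(endpoint)
  errorType <- match.arg(errorType)
  onearm <- endpoint == "pfs"
  allCurves <- growthCurves(dataset)
  if (is.null(day))
    day <- min(vapply(allCurves, .lastDay, numeric(1)))
  grid <- sort(unique(c(0, day, unlist(lapply(allCurves, function(cu)
    cu@days[cu@days <= day])))))
  ids <- modelIds(dataset)
  keep <- vapply(ids, function(m) {
    nt <- length(growthCurves(dataset, arm = "treatment", model = m))
    nv <- length(growthCurves(dataset, arm = "vehicle", model = m))
    nt >= minMice && (onearm || nv >= minMice)
  }, logical(1))
  ids <- ids[keep]
  if (!length(ids))
    stop("no model meets the inclusion rule (>= ", minMice,
         " mice per relevant arm)")
  .withSeed(seed, {
    res <- vector("list", length(ids))
    full <- numeric(length(ids))
    for (m in seq_along(ids)) {
      st <- .mouseStats(growthCurves(dataset, arm = "treatment",
                                     model = ids[m]), day, grid)
      sc <- if (onearm) NULL
            else .mouseStats(growthCurves(dataset, arm = "vehicle",
                                          model = ids[m]), day, grid)
      nt <- nrow(st); nv <- if (onearm) Inf else nrow(sc)
      if (max(nValues) > min(nt, nv))
        stop("subsample size exceeds group size for model ", ids[m])
      full[m] <- .endpointFromStats(endpoint, st, sc, seq_len(nt),
                                    if (onearm) NULL else seq_len(nrow(sc)))
      rows <- expand.grid(rep = seq_len(replications), n = nValues)
      err <- numeric(nrow(rows))
      for (r in seq_len(nrow(rows))) {
        n <- rows$n[r]
        it <- sample.int(nt, n)
        iv <- if (onearm) NULL else sample.int(nrow(sc), n)
        sub <- .endpointFromStats(endpoint, st, sc, it, iv)
        err[r] <- if (!is.finite(sub) || !is.finite(full[m])) NA_real_
                  else if (errorType == "percent")
                    abs(sub - full[m]) / abs(full[m]) * 100
                  else abs(sub - full[m])
      }
      res[[m]] <- data.frame(model_id = ids[m], n = rows$n, rep = rows$rep,
                             error = err, stringsAsFactors = FALSE)
    }
    errors <- do.call(rbind, res)
    missingRate <- vapply(nValues, function(n)
      mean(is.na(errors$error[errors$n == n])), numeric(1))
    names(missingRate) <- nValues
    structure(list(errors = errors,
                   missingRate = missingRate,
                   fullValues = stats::setNames(full, ids),
                   endpoint = endpoint, errorType = errorType,
                   nValues = nValues, replications = replications,
                   seed = seed),
              class = "mct_error_ecdf")
  })
}
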