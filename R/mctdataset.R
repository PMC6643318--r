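#' Construct a GrowthCurve
#'
#' @param mouseId,modelId,arm curve identity; \code{arm} is
#'   \code{"vehicle"} or \code{"treatment"}.
#' @param days,volumes parallel numeric vectors; days must start at 0 and
#'   increase strictly, volumes are in mm^3 and non-negative. Rows are
#'   sorted by day if supplied unsorted.
#' @return A [GrowthCurve-class] object.
#' @examples
#' gc <- GrowthCurve("m1", "PDX1", "treatment", c(0, 7, 14), c(120, 180, 260))
#' fitExponential(gc)
#' @export
GrowthCurve <- function(mouseId, modelId, arm, days, volumes) {
  o <- order(days)
  new("GrowthCurve", mouseId = as.character(mouseId),
      modelId = as.character(modelId), arm = as.character(arm),
      days = as.numeric(days)[o], volumes = as.numeric(volumes)[o])
}

#' Construct an MCTDataset
#'
#' @param volumes long-format \code{data.frame} with columns
#'   \code{model_id}, \code{mouse_id}, \code{arm}, \code{day},
#'   \code{volume_mm3}. Rows may be unsorted; they are grouped into curves
#'   and sorted by day.
#' @param modelCovariates \code{data.frame} with columns \code{model_id},
#'   \code{cancer_type} and optionally further model-level covariates. If
#'   missing, a minimal table with \code{cancer_type = NA} is synthesized.
#' @param expression optional numeric matrix, genes x models (column names
#'   must cover all model ids present in \code{volumes}).
#' @return A validated [MCTDataset-class].
#' @seealso [readMCT()] to build one from CSV files, [simulateMCT()].
#' @export
MCTDataset <- function(volumes, modelCovariates = NULL, expression = NULL) {
  volumes <- as.data.frame(volumes)
  need <- c("model_id", "mouse_id", "arm", "day", "volume_mm3")
  miss <- setdiff(need, names(volumes))
  if (length(miss))
    stop("volumes is missing required column(s): ", paste(miss, collapse = ", "))
  volumes <- volumes[need]
  for (col in c("model_id", "mouse_id", "arm"))
    volumes[[col]] <- trimws(as.character(volumes[[col]]))
  volumes$day <- as.numeric(volumes$day)
  volumes$volume_mm3 <- as.numeric(volumes$volume_mm3)
  volumes <- volumes[order(volumes$model_id, volumes$mouse_id, volumes$day), ,
                     drop = FALSE]
  rownames(volumes) <- NULL
  if (is.null(modelCovariates)) {
    ids <- sort(unique(volumes$model_id))
    modelCovariates <- data.frame(
      model_id = ids, cancer_type = rep(NA_character_, length(ids)),
      stringsAsFactors = FALSE)
  } else {
    modelCovariates <- as.data.frame(modelCovariates)
    modelCovariates$model_id <- trimws(as.character(modelCovariates$model_id))
    if ("cancer_type" %in% names(modelCovariates))
      modelCovariates$cancer_type <-
        as.character(modelCovariates$cancer_type)
    modelCovariates <- modelCovariates[order(modelCovariates$model_id), ,
                                       drop = FALSE]
    rownames(modelCovariates) <- NULL
  }
  new("MCTDataset", volumes = volumes, modelCovariates = modelCovariates,
      expression = expression)
}

#' Accessors for MCTDataset
#'
#' \code{mctVolumes} returns the long-format measurement table;
#' \code{modelCovariates} the model-level covariate table;
#' \code{expressionMatrix} the gene-by-model expression matrix (or NULL);
#' \code{modelIds} the model identifiers; \code{growthCurves} the curves as
#' a list of [GrowthCurve-class] objects, optionally restricted to one arm
#' and/or one model.
#'
#' @param x an [MCTDataset-class].
#' @param arm optional arm filter, \code{"vehicle"} or \code{"treatment"}.
#' @param model optional model-id filter.
#' @name MCTDataset-accessors
NULL

#' @rdname MCTDataset-accessors
#' @export
setMethod("mctVolumes", "MCTDataset", function(x) x@volumes)

#' @rdname MCTDataset-accessors
#' @export
setMethod("modelCovariates", "MCTDataset", function(x) x@modelCovariates)

#' @rdname MCTDataset-accessors
#' @export
setMethod("expressionMatrix", "MCTDataset", function(x) x@expression)

#' @rdname MCTDataset-accessors
#' @export
setMethod("modelIds", "MCTDataset",
          function(x) unique(x@volumes$model_id))

#' @rdname MCTDataset-accessors
#' @export
setMethod("growthCurves", "MCTDataset", function(x, arm = NULL, model = NULL) {
  vol <- x@volumes
  if (!is.null(arm)) {
    arm <- match.arg(arm, .ARMS)
    vol <- vol[vol$arm == arm, , drop = FALSE]
  }
  if (!is.null(model)) vol <- vol[vol$model_id %in% model, , drop = FALSE]
  if (!nrow(vol)) return(list())
  key <- paste(vol$model_id, vol$mouse_id, sep = "\r")
  idx <- split(seq_len(nrow(vol)), factor(key, levels = unique(key)))
  curves <- lapply(idx, function(i) {
    v <- vol[i, , drop = FALSE]
    GrowthCurve(v$mouse_id[1L], v$model_id[1L], v$arm[1L], v$day, v$volume_mm3)
  })
  names(curves) <- vapply(curves, function(cu)
    paste(cu@modelId, cu@mouseId, sep = "."), character(1))
  curves
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve %s/%s [%s]: %d measurements, day %g-%g, %g-%g mm3\n",
              object@modelId, object@mouseId, object@arm,
              length(object@days), min(object@days), max(object@days),
              min(object@volumes), max(object@volumes)))
})

setMethod("show", "MCTDataset", function(object) {
  vol <- object@volumes
  nmice <- length(unique(paste(vol$model_id, vol$mouse_id)))
  cat("MCTDataset\n")
  cat(sprintf("  %d models, %d mice, %d measurements\n",
              length(unique(vol$model_id)), nmice, nrow(vol)))
  if (nrow(vol)) {
    tb <- table(unique(data.frame(paste(vol$model_id, vol$mouse_id),
                                  vol$arm))[[2L]])
    cat(sprintf("  arms: %s\n",
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
    cat(sprintf("  days %g-%g\n", min(vol$day), max(vol$day)))
  }
  if (!is.null(object@expression))
    cat(sprintf("  expression: %d genes x %d models\n",
                nrow(object@expression), ncol(object@expression)))
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit: k = %.4g /day, TV0 = %.4g mm3, R2 = %.3f (n = %d)\n",
              object@k, exp(object@logTV0), object@rSquared, object@nPoints))
})

## number of mice per model/arm, used by resampling and simulation checks
.mouseTable <- function(dataset) {
  vol <- dataset@volumes
  unique(vol[c("model_id", "mouse_id", "arm")])
}
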