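#' Read a mouse clinical trial from CSV files
#'
#' Reads the long-format tumor-volume table and, optionally, the model
#' covariate table and gene-by-model expression matrix, validating the
#' clustered structure (every curve's model must have covariates, days
#' non-negative, volumes non-negative, no duplicate measurements).
#'
#' File formats:
#' \itemize{
#'   \item \code{volumes.csv}: columns \code{model_id, mouse_id, arm, day,
#'     volume_mm3}; one row per mouse per measurement day; rows may be in
#'     any order.
#'   \item \code{covariates.csv}: columns \code{model_id, cancer_type}
#'     plus any additional model-level covariate columns.
#'   \item \code{expression.csv}: first column \code{gene_id}, remaining
#'     columns one per model id (log2-scale values by convention).
#' }
#'
#' @param volumePath path to volumes.csv.
#' @param covariatePath optional path to covariates.csv.
#' @param expressionPath optional path to expression.csv.
#' @return A validated [MCTDataset-class].
#' @export
readMCT <- function(volumePath, covariatePath = NULL, expressionPath = NULL) {
  vol <- utils::read.csv(volumePath, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  need <- c("model_id", "mouse_id", "arm", "day", "volume_mm3")
  miss <- setdiff(need, names(vol))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 volumePath, paste(miss, collapse = ", ")))
  cov <- NULL
  if (!is.null(covariatePath)) {
    cov <- utils::read.csv(covariatePath, stringsAsFactors = FALSE,
                           strip.white = TRUE)
    if (!all(c("model_id", "cancer_type") %in% names(cov)))
      stop(sprintf("%s must have columns model_id and cancer_type",
                   covariatePath))
  }
  ex <- NULL
  if (!is.null(expressionPath)) {
    exdf <- utils::read.csv(expressionPath, stringsAsFactors = FALSE,
                            check.names = FALSE, strip.white = TRUE)
    if (names(exdf)[1L] != "gene_id")
      stop(sprintf("%s must have gene_id as its first column", expressionPath))
    ex <- as.matrix(exdf[-1L])
    rownames(ex) <- exdf$gene_id
    storage.mode(ex) <- "double"
  }
  MCTDataset(vol, cov, ex)
}

#' Write a mouse clinical trial to CSV files
#'
#' Inverse of [readMCT()]: writes \code{volumes.csv}, \code{covariates.csv}
#' and (when expression data are present) \code{expression.csv} such that
#' reading them back reproduces the dataset.
#'
#' @param dataset an [MCTDataset-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
writeMCT <- function(dataset, dir) {
  stopifnot(is(dataset, "MCTDataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(volumes = file.path(dir, "volumes.csv"),
             covariates = file.path(dir, "covariates.csv"))
  utils::write.csv(dataset@volumes, paths[["volumes"]], row.names = FALSE)
  utils::write.csv(dataset@modelCovariates, paths[["covariates"]],
                   row.names = FALSE)
  ex <- dataset@expression
  if (!is.null(ex)) {
    paths <- c(paths, expression = file.path(dir, "expression.csv"))
    exdf <- data.frame(gene_id = rownames(ex), ex, check.names = FALSE,
                       stringsAsFactors = FALSE)
    utils::write.csv(exdf, paths[["expression"]], row.names = FALSE)
  }
  invisible(paths)
}
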