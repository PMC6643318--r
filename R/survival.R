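#' Derive survival records from tumor growth curves
#'
#' In mouse studies progression-free survival is the tumor volume doubling
#' time and overall survival the tripling time (see [timeToMultiple()]).
#' Each mouse contributes one record; mice whose tumor never reaches the
#' threshold are censored at their last measured day. Mice with zero
#' initial volume (threshold undefined) or no follow-up after day 0 are
#' skipped, with counts attached as attributes.
#'
#' @param dataset an [MCTDataset-class].
#' @param endpoint \code{"doubling"} (PFS) or \code{"tripling"} (OS).
#' @param covariates model-level covariate columns to carry into the
#'   records (for use as \eqn{X_i} in [fitFrailty()] / [fitCox()]).
#' @return \code{data.frame} with columns \code{model_id},
#'   \code{mouse_id}, \code{treatment} (0/1), \code{time} (days),
#'   \code{event} (1 = crossed) and any requested covariates; attribute
#'   \code{"nSkipped"} counts skipped mice.
#' @export
deriveSurvival <- function(dataset, endpoint = c("doubling", "tripling"),
                           covariates = character()) {
  endpoint <- match.arg(endpoint)
  factor <- if (endpoint == "doubling") 2 else 3
  curves <- growthCurves(dataset)
  recs <- lapply(curves, function(cu) {
    if (cu@volumes[1L] <= 0 || length(cu@days) < 2L) return(NULL)
    tm <- timeToMultiple(cu, factor)
    if (tm$time <= 0) return(NULL)
    data.frame(model_id = cu@modelId, mouse_id = cu@mouseId,
               treatment = as.numeric(cu@arm == "treatment"),
               time = tm$time, event = as.integer(tm$event),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(recs, is.null, logical(1)))
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  rownames(out) <- NULL
  if (length(covariates)) {
    cov <- dataset@modelCovariates
    miss <- setdiff(covariates, names(cov))
    if (length(miss))
      stop("covariate(s) not in modelCovariates: ",
           paste(miss, collapse = ", "))
    for (cn in covariates)
      out[[cn]] <- cov[[cn]][match(out$model_id, cov$model_id)]
  }
  attr(out, "nSkipped") <- skipped
  out
}

.checkRecords <- function(records) {
  need <- c("model_id", "treatment", "time", "event")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (any(records$time <= 0)) stop("times must be > 0")
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1")
  if (!all(records$treatment %in% c(0, 1)))
    stop("treatment must be 0 (vehicle) or 1")
}

#' Cox proportional hazards fit of the treatment effect
#'
#' Partial-likelihood fit (Breslow tie handling) of the treatment
#' log-hazard, ignoring the clustering of mice within models — the
#' standard clinical-trial analysis that the additive frailty model
#' extends. When frailty variation across models is real, this marginal
#' estimate is attenuated toward hazard ratio 1.
#'
#' @param records survival records as from [deriveSurvival()] or
#'   [simulateSurvival()].
#' @param covariates names of additional fixed-effect columns.
#' @return An [MCTCoxFit-class].
#' @export
fitCox <- function(records, covariates = character()) {
  .checkRecords(records)
  evByArm <- tapply(records$event, records$treatment, sum)
  if (length(evByArm) < 2L || any(evByArm == 0))
    stop("monotone likelihood: need at least one event in each arm")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ treatment",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""))
  fit <- survival::coxph(fml, data = records, ties = "breslow")
  b <- stats::coef(fit)[["treatment"]]
  se <- sqrt(diag(stats::vcov(fit)))[["treatment"]]
  if (!is.finite(b) || !is.finite(se) || abs(b) > 15)
    stop("monotone likelihood: treatment coefficient diverges")
  new("MCTCoxFit", logHR = b, se = se, hazardRatio = exp(b),
      ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
      nEvents = as.integer(sum(records$event)),
      nRecords = nrow(records), fit = fit)
}

setMethod("show", "MCTCoxFit", function(object) {
  cat(sprintf(
    "MCTCoxFit: HR = %.3f (95%% CI %.3f-%.3f), log-HR = %.3f (SE %.3f), %d events / %d records\n",
    object@hazardRatio, object@ci[1], object@ci[2], object@logHR,
    object@se, object@nEvents, object@nRecords))
})

#' @rdname fit-accessors
#' @export
setMethod("hazardRatio", "MCTCoxFit", function(x) x@hazardRatio)

## ---- Gauss-Hermite machinery -------------------------------------------

## Nodes/weights for E[f(Z)], Z ~ N(0,1): Golub-Welsch on the Hermite
## Jacobi matrix, then z = sqrt(2) x and normalized weights.
.ghNorm <- function(n) {
  if (n == 1L) return(list(z = 0, w = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = sqrt(2) * e$values[ord], w = e$vectors[1L, ord]^2)
}

## Per-cluster sufficient statistics that do not depend on (a, b, w, beta)
.frailtyData <- function(records, covariates) {
  cl <- factor(records$model_id, levels = unique(records$model_id))
  X <- if (length(covariates))
    as.matrix(records[, covariates, drop = FALSE])
  else matrix(0, nrow(records), 0L)
  list(cl = cl, G = nlevels(cl), t = records$time, d = records$event,
       trt = records$treatment, X = X, p = ncol(X))
}

## Marginal negative log-likelihood of the additive frailty model at the
## transformed parameter vector th = (w, beta, log a, log b, l11[, l21],
## l22]), integrating the bivariate normal frailty per cluster by adaptive
## Gauss-Hermite quadrature: nodes are centered at each cluster's
## posterior mode of (u_i, v_i) and scaled by the local curvature, with
## the mode found by a damped Newton iteration vectorized across
## clusters. With detail = TRUE also returns the node grid and weights
## for posterior-mean frailty estimates.
.frailtyNegLogLik <- function(th, fd, gh, rhoFixed, tau2Zero,
                              detail = FALSE) {
  p <- fd$p
  w <- th[1L]
  beta <- if (p) th[1L + seq_len(p)] else numeric(0)
  la <- th[p + 2L]; lb <- th[p + 3L]
  a <- exp(la); b <- exp(lb)
  L11 <- exp(th[p + 4L])
  if (tau2Zero) {
    L21 <- 0; L22 <- 0
  } else if (!is.null(rhoFixed) && rhoFixed == 0) {
    L21 <- 0; L22 <- exp(th[p + 5L])
  } else {
    L21 <- th[p + 5L]; L22 <- exp(th[p + 6L])
  }
  ## per-cluster sufficient statistics at the current (a, b, w, beta)
  logt <- log(fd$t)
  logh0 <- la - lb + (a - 1) * (logt - lb)
  H0 <- exp(a * (logt - lb))
  etaX <- if (p) drop(fd$X %*% beta) else 0
  Cc <- rowsum(fd$d * (logh0 + etaX + w * fd$trt), fd$cl)[, 1L]
  D <- rowsum(fd$d, fd$cl)[, 1L]
  D1 <- rowsum(fd$d * fd$trt, fd$cl)[, 1L]
  hx <- H0 * exp(etaX)
  S0 <- rowsum(hx * (1 - fd$trt), fd$cl)[, 1L]
  S1 <- rowsum(hx * fd$trt * exp(w), fd$cl)[, 1L]
  G <- fd$G
  if (tau2Zero) {
    ## one-dimensional frailty u_i ~ N(0, L11^2)
    P11 <- 1 / L11^2
    u <- rep(0, G)
    for (it in 1:12) {
      eu <- exp(u) * (S0 + S1)
      g1 <- D + D1 * 0 - eu - P11 * u
      h11 <- eu + P11
      u <- u + pmin(3, pmax(-3, g1 / h11))
    }
    eu <- exp(u) * (S0 + S1)
    h11 <- eu + P11
    ## f(u) = Cc + (D + 0) u - e^u (S0 + S1) + log phi(u; 0, L11^2)
    fAt <- function(U) Cc + D * U - exp(U) * (S0 + S1) -
      0.5 * log(2 * pi) - log(L11) - 0.5 * P11 * U^2
    U <- outer(rep(1, G), gh$z1) / sqrt(h11) + u  # m_i + sd_i * z
    Fm <- fAt(U)
    logc <- log(sqrt(2 * pi)) + log(gh$w) + gh$z1^2 / 2
    M <- Fm + rep(logc, each = G) - 0.5 * log(h11)
    V <- matrix(0, G, length(gh$z1))
  } else {
    ## bivariate frailty: Sigma = LL', precision P
    s2 <- L11^2; cv <- L11 * L21; t2 <- L21^2 + L22^2
    dt <- s2 * t2 - cv^2
    if (dt <= 0) return(if (detail) NULL else 1e10)
    P11 <- t2 / dt; P12 <- -cv / dt; P22 <- s2 / dt
    u <- rep(0, G); v <- rep(0, G)
    for (it in 1:12) {
      e0 <- exp(u) * S0; e1 <- exp(u + v) * S1
      g1 <- D - e0 - e1 - (P11 * u + P12 * v)
      g2 <- D1 - e1 - (P12 * u + P22 * v)
      h11 <- e0 + e1 + P11; h12 <- e1 + P12; h22 <- e1 + P22
      det <- h11 * h22 - h12^2
      du <- (g1 * h22 - g2 * h12) / det
      dv <- (g2 * h11 - g1 * h12) / det
      u <- u + pmin(3, pmax(-3, du))
      v <- v + pmin(3, pmax(-3, dv))
    }
    e0 <- exp(u) * S0; e1 <- exp(u + v) * S1
    h11 <- e0 + e1 + P11; h12 <- e1 + P12; h22 <- e1 + P22
    det <- h11 * h22 - h12^2
    ## Cholesky of H^{-1}: A = [h22, -h12; -h12, h11]/det
    a11 <- h22 / det; a12 <- -h12 / det; a22 <- h11 / det
    c11 <- sqrt(a11); c21 <- a12 / c11
    c22 <- sqrt(pmax(a22 - c21^2, 1e-300))
    ## nodes: (u, v)_ik = mode_i + C_i %*% z_k  (z standardized pairs)
    U <- u + outer(c11, gh$z1)
    V <- v + outer(c21, gh$z1) + outer(c22, gh$z2)
    Fm <- Cc + D * U + D1 * V - exp(U) * S0 - exp(U + V) * S1 -
      log(2 * pi) - 0.5 * log(dt) -
      0.5 * (P11 * U^2 + 2 * P12 * U * V + P22 * V^2)
    logc <- log(2 * pi) + log(gh$w) + (gh$z1^2 + gh$z2^2) / 2
    M <- Fm + rep(logc, each = G) + log(c11) + log(c22)
  }
  mx <- apply(M, 1L, max)
  lik <- rowSums(exp(M - mx))
  ll <- sum(mx + log(lik))
  if (!is.finite(ll)) return(if (detail) NULL else 1e10)
  if (!detail) return(-ll)
  list(negll = -ll, M = M, mx = mx, U = U, V = V,
       modeU = u, modeV = if (tau2Zero) rep(0, G) else v)
}

## (sigma2, tau2, rho) from the Cholesky-parameterized tail of th
.frailtyVarMap <- function(th, p, rhoFixed, tau2Zero) {
  L11 <- exp(th[p + 4L])
  if (tau2Zero) c(sigma2 = L11^2, tau2 = 0, rho = NA_real_)
  else if (!is.null(rhoFixed) && rhoFixed == 0) {
    L22 <- exp(th[p + 5L])
    c(sigma2 = L11^2, tau2 = L22^2, rho = 0)
  } else {
    L21 <- th[p + 5L]; L22 <- exp(th[p + 6L])
    tau2 <- L21^2 + L22^2
    c(sigma2 = L11^2, tau2 = tau2,
      rho = if (tau2 > 0) L21 / sqrt(tau2) else NA_real_)
  }
}

#' Fit the additive frailty survival model
#'
#' Maximum marginal likelihood estimation of
#' \deqn{h_{ij}(t) = h_0(t)\exp(u_i + (w + v_i) T_{ij} + \beta^T X_i)}
#' for mouse \eqn{j} of model \eqn{i}, with Weibull baseline hazard
#' \eqn{h_0(t) = (a/b)(t/b)^{a-1}} and bivariate normal frailties
#' \eqn{(u_i, v_i)} (variances \eqn{\sigma^2, \tau^2}, correlation
#' \eqn{\rho}). The baseline frailty \eqn{u_i} captures a model's
#' characteristic growth/hazard; the treatment frailty \eqn{v_i} its
#' drug-response heterogeneity. Removing both reduces the model to
#' (Weibull) proportional hazards, and the marginal Cox estimate is then
#' attenuated relative to \eqn{e^w} when the frailties are real.
#'
#' The frailty pair is integrated out per cluster by adaptive
#' Gauss-Hermite quadrature (\code{nodes} points per dimension, centered
#' at each cluster's posterior mode and scaled by the local curvature);
#' variance components are parameterized by the Cholesky
#' factor of the frailty covariance, so estimates are non-negative by
#' construction, with boundary estimates flagged. Wald tests for
#' \eqn{\sigma^2 > 0} and \eqn{\tau^2 > 0} use delta-method standard
#' errors (computed on the positivity-respecting log-Cholesky scale) and
#' one-sided p-values; at the boundary the test is reported as p = 1.
#' Per-cluster frailty estimates are the posterior modes of
#' \eqn{(u_i, v_i)} under the fitted model (empirical Bayes BLUPs).
#'
#' @param records survival records (see [deriveSurvival()],
#'   [simulateSurvival()]); needs at least 5 clusters with both arms
#'   represented overall.
#' @param covariates names of model-level fixed-effect columns
#'   (\eqn{X_i}).
#' @param nodes adaptive Gauss-Hermite nodes per dimension (default 9).
#' @param rhoFixed NULL to estimate the frailty correlation, or 0 to fix
#'   it (more stable on small cluster counts).
#' @param tau2Zero fix \eqn{\tau^2 = 0} (shared baseline frailty only).
#' @return An [MCTFrailtyFit-class].
#' @examples
#' sim <- simulateSurvival(survSimConfig(nClusters = 30), seed = 7)
#' fit <- fitFrailty(sim$records, rhoFixed = 0)
#' hazardRatio(fit)
#' @export
fitFrailty <- function(records, covariates = character(), nodes = 9L,
                       rhoFixed = NULL, tau2Zero = FALSE) {
  .checkRecords(records)
  if (length(covariates)) {
    miss <- setdiff(covariates, names(records))
    if (length(miss)) stop("missing covariate column(s): ",
                           paste(miss, collapse = ", "))
  }
  fd <- .frailtyData(records, covariates)
  if (fd$G < 5L) stop("fitFrailty needs at least 5 clusters")
  if (length(unique(records$treatment)) < 2L)
    stop("both arms must be represented")
  nodes <- as.integer(nodes)
  g1 <- .ghNorm(nodes)
  if (tau2Zero) {
    gh <- list(z1 = g1$z, z2 = rep(0, nodes), w = g1$w)
  } else {
    gh <- list(z1 = rep(g1$z, times = nodes),
               z2 = rep(g1$z, each = nodes),
               w = as.vector(outer(g1$w, g1$w)))
  }
  p <- fd$p
  ## starting values from a Weibull AFT fit ignoring clustering
  sv <- tryCatch({
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ treatment",
      if (p) paste("+", paste(covariates, collapse = "+")) else ""))
    sr <- survival::survreg(fml, data = records, dist = "weibull")
    shape0 <- 1 / sr$scale
    c(w = -stats::coef(sr)[["treatment"]] / sr$scale,
      beta = if (p) -stats::coef(sr)[covariates] / sr$scale else NULL,
      la = log(shape0), lb = stats::coef(sr)[["(Intercept)"]])
  }, error = function(e)
    c(w = 0, beta = rep(0, p), la = 0, lb = log(stats::median(records$time))))
  th0 <- c(sv[1L], if (p) sv[1L + seq_len(p)] else NULL,
           sv[[p + 2L]], sv[[p + 3L]], log(0.4),
           if (tau2Zero) NULL
           else if (!is.null(rhoFixed) && rhoFixed == 0) log(0.4)
           else c(0, log(0.4)))
  nTh <- length(th0)
  lower <- c(-20, rep(-20, p), -5, -10, -7,
             if (tau2Zero) NULL
             else if (!is.null(rhoFixed) && rhoFixed == 0) -7
             else c(-5, -7))
  upper <- c(20, rep(20, p), 5, 12, 3,
             if (tau2Zero) NULL
             else if (!is.null(rhoFixed) && rhoFixed == 0) 3
             else c(5, 3))
  obj <- function(th) .frailtyNegLogLik(th, fd, gh, rhoFixed, tau2Zero)
  opt <- stats::nlminb(th0, obj, lower = lower, upper = upper,
                       control = list(iter.max = 500, eval.max = 1000))
  if (!opt$convergence %in% c(0, 1) || !is.finite(opt$objective))
    stop("frailty fit did not converge: ", opt$message)
  th <- unname(opt$par)
  boundary <- character(0)
  if (th[p + 4L] <= lower[p + 4L] + 1e-6) boundary <- c(boundary, "sigma2")
  if (!tau2Zero) {
    l22AtBound <- th[nTh] <= lower[nTh] + 1e-6
    rho0 <- !is.null(rhoFixed) && rhoFixed == 0
    if (l22AtBound && (rho0 || abs(th[p + 5L]) < 1e-6))
      boundary <- c(boundary, "tau2")
  }
  H <- stats::optimHess(th, obj)
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, nTh, nTh))
  vm <- .frailtyVarMap(th, p, rhoFixed, tau2Zero)
  ## delta-method SEs for (sigma2, tau2) via numeric jacobian
  jac <- vapply(seq_len(nTh), function(k) {
    h <- 1e-5 * max(1, abs(th[k]))
    tp <- th; tm <- th; tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (.frailtyVarMap(tp, p, rhoFixed, tau2Zero)[1:2] -
       .frailtyVarMap(tm, p, rhoFixed, tau2Zero)[1:2]) / (2 * h)
  }, numeric(2))
  seVar <- sqrt(pmax(diag(jac %*% V %*% t(jac)), 0))
  varTests <- data.frame(
    component = c("sigma2", "tau2"),
    estimate = unname(vm[c("sigma2", "tau2")]),
    se = seVar,
    z = unname(vm[c("sigma2", "tau2")]) / seVar,
    p = stats::pnorm(-unname(vm[c("sigma2", "tau2")]) / seVar),
    boundary = c("sigma2", "tau2") %in% boundary,
    stringsAsFactors = FALSE)
  varTests$p[varTests$boundary | !is.finite(varTests$p)] <- 1
  if (tau2Zero) varTests <- varTests[varTests$component != "tau2", ]
  wSe <- sqrt(V[1L, 1L])
  det <- .frailtyNegLogLik(th, fd, gh, rhoFixed, tau2Zero, detail = TRUE)
  frailty <- data.frame(
    model_id = levels(fd$cl),
    u = det$modeU, v = det$modeV,
    stringsAsFactors = FALSE)
  beta <- if (p) th[1L + seq_len(p)] else numeric(0)
  betaSe <- if (p) sqrt(diag(V)[1L + seq_len(p)]) else numeric(0)
  names(beta) <- names(betaSe) <- covariates
  new("MCTFrailtyFit",
      w = th[1L], wSe = wSe, beta = beta, betaSe = betaSe,
      sigma2 = unname(vm["sigma2"]), tau2 = unname(vm["tau2"]),
      rho = unname(vm["rho"]),
      weibullShape = exp(th[p + 2L]), weibullScale = exp(th[p + 3L]),
      hazardRatio = exp(th[1L]),
      hrCI = exp(th[1L] + c(-1, 1) * stats::qnorm(0.975) * wSe),
      varTests = varTests, frailty = frailty,
      logLik = -opt$objective, vcov = V, boundary = boundary,
      converged = opt$convergence == 0,
      nClusters = fd$G, nRecords = nrow(records),
      nEvents = as.integer(sum(fd$d)), nodes = nodes)
}

setMethod("show", "MCTFrailtyFit", function(object) {
  cat(sprintf(
    "MCTFrailtyFit: %d clusters, %d records, %d events (GH %d nodes/dim)\n",
    object@nClusters, object@nRecords, object@nEvents, object@nodes))
  cat(sprintf("  w = %.3f (SE %.3f), HR = %.3f (95%% CI %.3f-%.3f)\n",
              object@w, object@wSe, object@hazardRatio, object@hrCI[1],
              object@hrCI[2]))
  cat(sprintf("  sigma2 = %.3f, tau2 = %.3f, rho = %s\n",
              object@sigma2, object@tau2,
              if (is.na(object@rho)) "-" else sprintf("%.3f", object@rho)))
  cat(sprintf("  Weibull baseline: shape %.3f, scale %.3f; logLik %.2f%s\n",
              object@weibullShape, object@weibullScale, object@logLik,
              if (length(object@boundary))
                paste0(" [boundary: ",
                       paste(object@boundary, collapse = ", "), "]")
              else ""))
})

#' @rdname fit-accessors
#' @export
setMethod("hazardRatio", "MCTFrailtyFit", function(x) x@hazardRatio)

#' @rdname fit-accessors
#' @export
setMethod("frailtyEstimates", "MCTFrailtyFit", function(x) x@frailty)

#' Per-model vehicle growth rates
#'
#' Pooled common-slope log-linear growth rate of each model's vehicle arm
#' (\eqn{k_c}), the comparator for the baseline frailty in
#' [frailtyGrowthCorrelation()].
#'
#' @param dataset an [MCTDataset-class].
#' @return Named numeric vector of growth rates per model (per day).
#' @export
vehicleGrowthRates <- function(dataset) {
  ids <- modelIds(dataset)
  vapply(ids, function(m)
    .pooledSlope(growthCurves(dataset, arm = "vehicle", model = m)),
    numeric(1))
}

#' Correlation of baseline frailty with vehicle growth rate
#'
#' The baseline frailty \eqn{u_i} raises a model's hazard without
#' treatment; faster-growing tumors reach the volume threshold sooner, so
#' \eqn{u_i} should track the vehicle growth rate \eqn{k_c}. Returns the
#' per-model scatter and the Pearson correlation/R-squared between the
#' fitted frailty estimates and the growth rates.
#'
#' @param fit an [MCTFrailtyFit-class].
#' @param vehicleGrowthRates named numeric vector (model id -> \eqn{k_c}),
#'   e.g. from [vehicleGrowthRates()].
#' @return A list with \code{data} (model_id, u, kc), \code{r},
#'   \code{rSquared}.
#' @export
frailtyGrowthCorrelation <- function(fit, vehicleGrowthRates) {
  stopifnot(is(fit, "MCTFrailtyFit"))
  fr <- fit@frailty
  common <- intersect(fr$model_id, names(vehicleGrowthRates))
  if (length(common) < 3L)
    stop("need at least 3 clusters with growth rates")
  u <- fr$u[match(common, fr$model_id)]
  kc <- vehicleGrowthRates[common]
  r <- stats::cor(u, kc)
  list(data = data.frame(model_id = common, u = u, kc = unname(kc),
                         stringsAsFactors = FALSE),
       r = r, rSquared = r^2)
}

#' Per-model TGI
#'
#' Convenience for biomarker comparators: TGI (RTV variant by default) for
#' every model at a common evaluation day.
#'
#' @param dataset an [MCTDataset-class] with both arms.
#' @param day evaluation day; default the last day covered by every mouse.
#' @param variant passed to [tgi()].
#' @return Named numeric vector of TGI per model.
#' @export
modelTGI <- function(dataset, day = NULL, variant = "rtv") {
  ids <- modelIds(dataset)
  if (is.null(day)) {
    allc <- growthCurves(dataset)
    day <- min(vapply(allc, .lastDay, numeric(1)))
  }
  vapply(ids, function(m)
    tgi(growthCurves(dataset, arm = "treatment", model = m),
        growthCurves(dataset, arm = "vehicle", model = m),
        day = day, variant = variant),
    numeric(1))
}
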