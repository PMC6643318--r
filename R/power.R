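.binomCI <- function(p, n) {
  hw <- stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
  c(max(0, p - hw), min(1, p + hw))
}

#' Simulation-based power for the longitudinal LMM analysis
#'
#' Estimates the power of a balanced n:n MCT design analyzed by the
#' three-level LMM ([fitLMM()]): for each cell of the design grid
#' (number of models G, mice per model per arm n, treatment effect ratio
#' beta2/beta1), trials are simulated from the configured generator, the
#' Day x Treatment effect is tested by a two-sided Wald z-test at level
#' \code{alpha}, and power is the rejection fraction with a binomial
#' Monte-Carlo confidence interval. Replicates whose fit fails are counted
#' as non-rejections (conservative) and reported; a cell is flagged when
#' more than 5\% of its fits fail.
#'
#' @param nModels vector of model counts G.
#' @param micePerArm vector of per-arm group sizes n.
#' @param effectRatios vector of effect ratios beta2/beta1 (0 = null; the
#'   reference sweep is -0.1 to -0.9, i.e. the drug cuts the growth rate
#'   by 10-90\%).
#' @param replications simulated trials per cell.
#' @param alpha significance level.
#' @param config baseline generator parameters ([mctSimConfig()]); its
#'   \code{nModels}, \code{micePerArm} and \code{beta2} are overridden by
#'   the grid.
#' @param seed integer seed (required).
#' @return \code{data.frame} with one row per cell: \code{n_models},
#'   \code{mice_per_arm}, \code{effect_ratio}, \code{power},
#'   \code{ci_lo}, \code{ci_hi}, \code{failures}, \code{flagged},
#'   \code{replications}.
#' @export
powerLMM <- function(nModels, micePerArm, effectRatios,
                     replications = 500, alpha = 0.05,
                     config = mctSimConfig(), seed) {
  grid <- expand.grid(n_models = nModels, mice_per_arm = micePerArm,
                      effect_ratio = effectRatios)
  .withSeed(seed, {
    cellSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   nrow(grid) * replications),
                        nrow(grid), replications)
    out <- grid
    out$power <- NA_real_; out$ci_lo <- NA_real_; out$ci_hi <- NA_real_
    out$failures <- 0L
    for (i in seq_len(nrow(grid))) {
      cfg <- config
      cfg$nModels <- as.integer(grid$n_models[i])
      cfg$micePerArm <- as.integer(grid$mice_per_arm[i])
      cfg$beta2 <- grid$effect_ratio[i] * cfg$beta1
      rej <- logical(replications); fail <- logical(replications)
      for (r in seq_len(replications)) {
        res <- tryCatch({
          sim <- simulateMCT(cfg, seed = cellSeeds[i, r])
          fit <- fitLMM(sim$dataset, fast = TRUE)
          fe <- fit@fixedEffects
          fe$p[fe$term == "Day:Treatment"] < alpha
        }, error = function(e) NA)
        if (is.na(res)) fail[r] <- TRUE else rej[r] <- res
      }
      out$power[i] <- mean(rej)
      ci <- .binomCI(out$power[i], replications)
      out$ci_lo[i] <- ci[1]; out$ci_hi[i] <- ci[2]
      out$failures[i] <- sum(fail)
    }
    out$flagged <- out$failures / replications > 0.05
    out$replications <- replications
    out
  })
}

#' Simulation-based power for the additive frailty survival analysis
#'
#' As [powerLMM()], but trials are clustered survival datasets drawn from
#' the additive frailty generator ([simulateSurvival()]) at each hazard
#' ratio, fitted with [fitFrailty()], and the treatment log-hazard w is
#' tested by a two-sided Wald z-test.
#'
#' @param nClusters vector of model counts G.
#' @param micePerArm vector of per-arm group sizes n.
#' @param hazardRatios vector of hazard ratios exp(w) (1 = null; the
#'   reference sweep is 0.9 to 0.1).
#' @param replications simulated trials per cell.
#' @param alpha significance level.
#' @param config baseline generator parameters ([survSimConfig()]); its
#'   \code{nClusters}, \code{micePerArm} and \code{w} are overridden.
#' @param rhoFixed passed to [fitFrailty()] (default 0 for stability on
#'   simulated designs with uncorrelated frailties).
#' @param nodes quadrature nodes per dimension for the fits.
#' @param seed integer seed (required).
#' @return \code{data.frame} as in [powerLMM()], with \code{hazard_ratio}
#'   in place of \code{effect_ratio}.
#' @export
powerFrailty <- function(nClusters, micePerArm, hazardRatios,
                         replications = 500, alpha = 0.05,
                         config = survSimConfig(), rhoFixed = 0,
                         nodes = 9L, seed) {
  grid <- expand.grid(n_models = nClusters, mice_per_arm = micePerArm,
                      hazard_ratio = hazardRatios)
  .withSeed(seed, {
    cellSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   nrow(grid) * replications),
                        nrow(grid), replications)
    out <- grid
    out$power <- NA_real_; out$ci_lo <- NA_real_; out$ci_hi <- NA_real_
    out$failures <- 0L
    for (i in seq_len(nrow(grid))) {
      cfg <- config
      cfg$nClusters <- as.integer(grid$n_models[i])
      cfg$micePerArm <- as.integer(grid$mice_per_arm[i])
      cfg$w <- log(grid$hazard_ratio[i])
      rej <- logical(replications); fail <- logical(replications)
      for (r in seq_len(replications)) {
        res <- tryCatch({
          sim <- simulateSurvival(cfg, seed = cellSeeds[i, r])
          fit <- fitFrailty(sim$records, nodes = nodes,
                            rhoFixed = rhoFixed)
          2 * stats::pnorm(-abs(fit@w / fit@wSe)) < alpha
        }, error = function(e) NA)
        if (is.na(res)) fail[r] <- TRUE else rej[r] <- res
      }
      out$power[i] <- mean(rej)
      ci <- .binomCI(out$power[i], replications)
      out$ci_lo[i] <- ci[1]; out$ci_hi[i] <- ci[2]
      out$failures[i] <- sum(fail)
    }
    out$flagged <- out$failures / replications > 0.05
    out$replications <- replications
    out
  })
}
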