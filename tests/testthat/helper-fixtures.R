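# In-code fixtures shared across the suite.

# single curve with given days/volumes
curve <- function(volumes, days = seq(0, by = 7, length.out = length(volumes)),
                  arm = "treatment", mouse = "m1", model = "P1") {
  GrowthCurve(mouse, model, arm, days, volumes)
}

# exact exponential curve TV0 * exp(k * day)
expCurve <- function(k, tv0 = 100, days = seq(0, 21, by = 3), ...) {
  curve(tv0 * exp(k * days), days = days, ...)
}

# a toy two-arm dataset from per-mouse (arm, volumes) specs on shared days
toyDataset <- function(mice, days = c(0, 7, 14, 21), model = "P1",
                       cancer = "GA") {
  rows <- do.call(rbind, lapply(seq_along(mice), function(i) {
    m <- mice[[i]]
    data.frame(model_id = model, mouse_id = paste0("m", i), arm = m$arm,
               day = days[seq_along(m$volumes)], volume_mm3 = m$volumes,
               stringsAsFactors = FALSE)
  }))
  MCTDataset(rows, data.frame(model_id = model, cancer_type = cancer,
                              stringsAsFactors = FALSE))
}

# dataset where every mouse of a model/arm shares an exact exponential rate
ratesDataset <- function(kTreated, kVehicle, nPerArm = 3, tv0 = 100,
                         days = c(0, 3, 7, 10, 14, 17, 21)) {
  rows <- list()
  for (m in seq_along(kTreated)) {
    for (arm in c("treatment", "vehicle")) {
      k <- if (arm == "treatment") kTreated[m] else kVehicle[m]
      for (i in seq_len(nPerArm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          model_id = paste0("P", m), mouse_id = paste0(arm, i), arm = arm,
          day = days, volume_mm3 = tv0 * exp(k * days),
          stringsAsFactors = FALSE)
      }
    }
  }
  MCTDataset(do.call(rbind, rows))
}

# curve with the prescribed RTV value at the evaluation day (two points);
# unit baseline keeps the RTV exactly equal to the given literal
rtvCurve <- function(rtvEnd, tv0 = 1, endDay = 14) {
  curve(c(tv0, tv0 * rtvEnd), days = c(0, endDay))
}
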