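test_that("RTV is a plain volume ratio anchored at day 0", {
  cu <- curve(c(100, 120, 150))
  expect_equal(rtv(cu, 0), 1)
  expect_equal(rtv(cu, 14), 1.5)
  expect_error(rtv(curve(c(0, 50)), 7), "initial tumor volume is 0")
})

test_that("RECIST and 3-cat partitions match the printed thresholds", {
  recist <- vapply(c(0, 0.3, 0.657, 0.658, 1, 1.728, 1.729, 3),
                   function(r) classifyRECIST(rtvCurve(r)), character(1))
  expect_equal(recist, c("CR", "PR", "PR", "SD", "SD", "SD", "PD", "PD"))
  cat3 <- vapply(c(0, 0.65, 0.651, 1, 1.349, 1.35, 2),
                 function(r) classify3cat(rtvCurve(r)), character(1))
  expect_equal(cat3, c("OR", "OR", "SD", "SD", "SD", "PD", "PD"))
})

test_that("every classifier assigns exactly one category on an RTV sweep", {
  for (r in seq(0, 3, by = 0.01)) {
    cu <- rtvCurve(r)
    expect_length(classifyRECIST(cu), 1L)
    expect_true(classifyRECIST(cu) %in% c("CR", "PR", "SD", "PD"))
    expect_true(classify3cat(cu) %in% c("OR", "SD", "PD"))
    cu5 <- curve(c(100, 100 * r, 100 * r), days = c(0, 10, 21))
    expect_true(classify5cat(cu5) %in% c("MCR", "CR", "PR", "SD", "PD"))
  }
})

test_that("mRECIST summaries take both minima over the day >= 10 window", {
  # RTV series 1, 0.8, 0.4, 0.6 at days 0, 7, 14, 21:
  # best response = 0.4; running means at d14, d21 = 0.7333, 0.70
  cu <- curve(c(100, 80, 40, 60))
  s <- mrecistSummary(cu)
  expect_equal(s$bestResponse, 0.4)
  expect_equal(s$bestAvgResponse, 0.7)
  # monotone growth: best response is the first RTV at day >= 10
  cu2 <- curve(c(100, 150, 225, 340))
  expect_equal(mrecistSummary(cu2)$bestResponse, 2.25)
  expect_error(mrecistSummary(curve(c(100, 120), days = c(0, 7))),
               "day >= 10")
})

test_that("mRECIST classification applies both cutoffs in CR/PR/SD order", {
  expect_equal(classifyMRECIST(curve(c(100, 10, 0, 0))), "CR")
  expect_equal(classifyMRECIST(curve(c(100, 60, 40, 45))), "PR")
  expect_equal(classifyMRECIST(curve(c(100, 110, 100, 105))), "SD")
  expect_equal(classifyMRECIST(curve(c(100, 200, 200, 200))), "PD")
  # late complete disappearance after early growth can still be PD:
  # the running mean from day 0 dominates the day >= 10 window
  late <- curve(c(100, 250, 400, 300, 0), days = c(0, 7, 14, 21, 28))
  expect_equal(classifyMRECIST(late), "PD")
})

test_that("5-cat rules fire in MCR/CR/PR/SD/PD order", {
  expect_equal(classify5cat(curve(c(100, 0, 0))), "MCR")
  expect_equal(classify5cat(curve(c(100, 0, 80))), "CR")
  expect_equal(classify5cat(curve(c(100, 40, 150))), "PR")
  expect_equal(classify5cat(curve(c(100, 50, 150))), "PR")   # boundary 0.50
  expect_equal(classify5cat(curve(c(100, 80, 120))), "SD")
  expect_equal(classify5cat(curve(c(100, 80, 125))), "SD")   # boundary 1.25
  expect_equal(classify5cat(curve(c(100, 80, 150))), "PD")
})

test_that("objective-response calls can disagree between methods", {
  # RTV 0.655 at end: PR under RECIST (<= 0.657) but SD under 3-cat (> 0.65)
  borderline <- rtvCurve(0.655)
  expect_equal(classifyRECIST(borderline), "PR")
  expect_equal(classify3cat(borderline), "SD")
  # transient deep response, progressive end: PR (objective) under 5-cat,
  # SD under RECIST at end of study
  transient <- curve(c(100, 40, 150))
  expect_equal(classify5cat(transient), "PR")
  expect_equal(classifyRECIST(transient), "SD")
  # growth followed by late disappearance: objective under RECIST/3-cat/
  # 5-cat at end of study, PD under mRECIST
  late <- curve(c(100, 250, 400, 300, 0), days = c(0, 7, 14, 21, 28))
  expect_equal(classifyRECIST(late), "CR")
  expect_equal(classify3cat(late), "OR")
  expect_equal(classify5cat(late), "MCR")
  expect_equal(classifyMRECIST(late), "PD")
})

test_that("majority response uses the modal category, ties to progression", {
  expect_equal(majorityResponse(c("PD", "PD", "SD"), "recist"), "PD")
  expect_equal(majorityResponse(c("CR", "PD"), "recist"), "PD")
  expect_equal(majorityResponse(c("PR", "PR", "SD", "SD"), "recist"), "SD")
  expect_equal(majorityResponse("PR", "recist"), "PR")
  expect_error(majorityResponse(c("OR", "PD"), "recist"), "not valid")
  expect_error(majorityResponse(character(), "recist"), "at least one")
})

test_that("objective response rate counts the method's objective set", {
  maj <- c(rep("PR", 3), rep("SD", 4), rep("PD", 3))
  expect_equal(objectiveResponseRate(maj, "recist"), 0.3)
  expect_equal(objectiveResponseRate(rep("PD", 5), "recist"), 0)
  expect_equal(objectiveResponseRate(c("MCR", "CR", "PR", "SD", "PD", "PD"),
                                     "cat5"), 0.5)
  expect_error(objectiveResponseRate(character(), "recist"), "at least one")
})

test_that("trial-level calls classify each mouse and summarize per model", {
  ds <- toyDataset(list(
    list(arm = "treatment", volumes = c(100, 150, 250, 400)),
    list(arm = "treatment", volumes = c(100, 90, 70, 60)),
    list(arm = "treatment", volumes = c(100, 200, 350, 700)),
    list(arm = "vehicle", volumes = c(100, 250, 600, 1400))))
  calls <- responseCalls(ds, "recist")
  expect_equal(nrow(calls), 3L)  # treatment arm only
  maj <- majorityTable(calls)
  expect_equal(maj$category, "PD")
  expect_warning(responseCalls(ds, "recist", checkInitial = TRUE), NA)
  ds2 <- toyDataset(list(list(arm = "treatment", volumes = c(40, 60, 80, 90))))
  expect_warning(responseCalls(ds2, "recist", checkInitial = TRUE),
                 "initial volume")
})
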