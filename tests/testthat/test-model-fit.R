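# Least-squares objective, simulated-annealing search and model predictions.

test_that("the loss vanishes at the generating truth on noiseless data", {
  p <- rateParameters()
  sch <- stimulationSchedule(0)
  d <- genKineticDataset(p, sch, noiseCVPercent = 0, seed = 1)
  expect_lt(lossFunction(p, d, sch), 1e-8)
})

test_that("the loss is invariant under permutation of observation rows", {
  p <- rateParameters()
  sch <- stimulationSchedule(0)
  d <- genKineticDataset(p, sch, noiseCVPercent = 5, seed = 8)
  obs <- observations(d)
  shuffled <- timeCourseDataset(obs[sample(nrow(obs)), ],
                                truth = groundTruth(d))
  expect_identical(lossFunction(p, d, sch),
                   lossFunction(p, shuffled, sch))
})

test_that("the observable scale is identifiable: doubling s_Z raises the loss", {
  p <- rateParameters()
  sch <- stimulationSchedule(0)
  d <- genKineticDataset(p, sch, noiseCVPercent = 0, seed = 2)
  doubled <- rateParameters(s_Z = 2)
  expect_gt(lossFunction(doubled, d, sch), lossFunction(p, d, sch))
})

test_that("unsupported observables and empty annealing configs are rejected", {
  obs <- data.frame(time_min = c(0, 5), observable = "bound_pY493",
                    replicate = 1L, value = c(0.1, 0.2))
  d <- timeCourseDataset(obs)
  expect_error(lossFunction(rateParameters(), d, stimulationSchedule(0)),
               "unsupported observables")
  d2 <- genKineticDataset(rateParameters(), noiseCVPercent = 0, seed = 1)
  expect_error(annealFit(d2, stimulationSchedule(0),
                         control = list(nTemps = 0)), "at least one")
  expect_error(annealFit(d2, stimulationSchedule(0), fitNames = "nope"),
               "subset")
})

test_that("annealing is reproducible for a fixed seed and tracks its best", {
  sch <- stimulationSchedule(0)
  d <- genKineticDataset(rateParameters(), sch, noiseCVPercent = 5, seed = 3)
  ctl <- list(nTemps = 4, proposalsPerTemp = 10, polish = FALSE,
              initialTemp = 0.5, coolingFactor = 0.7)
  f1 <- annealFit(d, sch, seed = 42, control = ctl)
  f2 <- annealFit(d, sch, seed = 42, control = ctl)
  expect_identical(rateValues(f1), rateValues(f2))
  expect_identical(fitTrace(f1), fitTrace(f2))
  tr <- fitTrace(f1)
  expect_true(all(diff(tr$best) <= 0))           # best-so-far never worsens
  expect_true(all(tr$best <= tr$accepted + 1e-12))
  expect_lte(f1@rss, tr$best[nrow(tr)] + 1e-12)
  f3 <- annealFit(d, sch, seed = 43, control = ctl)
  expect_false(identical(fitTrace(f1), fitTrace(f3)))
})

test_that("a two-parameter fit on noiseless data recovers the truth within 5%", {
  truth <- rateParameters()
  sch <- stimulationSchedule(0)
  d <- genKineticDataset(truth, sch, noiseCVPercent = 0, seed = 5)
  fitNames <- c("k_itam_p", "k_y319")
  start <- rateParameters(k_itam_p = 0.8 * 10^0.3, k_y319 = 0.04 * 10^-0.3)
  fit <- annealFit(d, sch, init = start, fitNames = fitNames, seed = 11,
                   control = list(nTemps = 10, proposalsPerTemp = 25,
                                  initialTemp = 0.1, coolingFactor = 0.6))
  got <- rateValues(fit)[fitNames]
  want <- rateValues(truth)[fitNames]
  expect_true(all(abs(got / want - 1) < 0.05))
  expect_lt(fit@rss, 1e-4)
})

test_that("the fitted bounds are honoured", {
  sch <- stimulationSchedule(0)
  d <- genKineticDataset(rateParameters(), sch, noiseCVPercent = 5, seed = 6)
  fit <- annealFit(d, sch, fitNames = c("k_y319", "s_Z"),
                   bounds = list(lower = c(k_y319 = 0.01, s_Z = 0.5),
                                 upper = c(k_y319 = 0.1, s_Z = 2)),
                   seed = 1,
                   control = list(nTemps = 3, proposalsPerTemp = 10,
                                  polish = FALSE))
  v <- rateValues(fit)
  expect_gte(v[["k_y319"]], 0.01); expect_lte(v[["k_y319"]], 0.1)
  expect_gte(v[["s_Z"]], 0.5); expect_lte(v[["s_Z"]], 2)
  expect_error(annealFit(d, sch, bounds = list(lower = c(k_y319 = -1)),
                         fitNames = "k_y319", seed = 1), "bounds")
})

test_that("the model's three predictions hold at the default parameters", {
  pred <- predictUnfitted(rateParameters())
  expect_true(pred$y493Delay$pass)
  expect_gte(pred$y493Delay$timeToPeakPY493, pred$y493Delay$timeToPeakPY319)
  expect_true(pred$doubleDose$pass)
  expect_gt(pred$doubleDose$doubleDosePY319, pred$doubleDose$singleDosePY319)
  expect_true(pred$restingRatio$pass)
  expect_gt(pred$restingRatio$boundRatio, pred$restingRatio$totalRatio)
})
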