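# Generators must be reproducible, match their specified distributions, and
# deliver exact ground truth in their degenerate limits.

test_that("degenerate spread and zero background give the geometric mean exactly", {
  spec <- beadPopulationSpec(50, channelGeoMeans = c(PE = 500),
                             channelGeoCV = 0, backgroundGeoMean = 0,
                             seed = 1)
  tbl <- genBeadEvents(spec)
  expect_equal(nEvents(tbl), 50L)
  expect_true(all(eventData(tbl)$PE == 500))
  expect_equal(as.numeric(geometricMFI(tbl, "PE")), 500)
})

test_that("geometric MFI of a lognormal population converges at sigma/sqrt(n)", {
  sigma <- 0.4
  cv <- sqrt(exp(sigma^2) - 1)   # geometric CV equivalent to sdlog 0.4
  for (n in c(100, 1000, 5000)) {
    spec <- beadPopulationSpec(n, channelGeoMeans = c(PE = 500),
                               channelGeoCV = cv, backgroundGeoMean = 0,
                               seed = 42)
    mfi <- as.numeric(geometricMFI(genBeadEvents(spec), "PE"))
    expect_lt(abs(log(mfi) - log(500)), 3 * sigma / sqrt(n))
  }
})

test_that("fixed seed reproduces tables exactly; different seeds differ", {
  spec <- beadPopulationSpec(300, channelGeoMeans = c(PE = 200, APC = 80),
                             seed = 9)
  a <- genBeadEvents(spec)
  b <- genBeadEvents(spec)
  expect_identical(eventData(a), eventData(b))
  spec2 <- beadPopulationSpec(300, channelGeoMeans = c(PE = 200, APC = 80),
                              seed = 10)
  c <- genBeadEvents(spec2)
  expect_false(any(eventData(a)$PE == eventData(c)$PE))
  # same distributional summary within sampling error
  sdlog <- sqrt(log(1 + 0.35^2))  # generator's geo-CV -> sdlog convention
  expect_lt(abs(log(geometricMFI(a, "PE")) - log(geometricMFI(c, "PE"))),
            6 * sdlog / sqrt(300))
})

test_that("generator rejects invalid specifications", {
  expect_error(beadPopulationSpec(10, channelGeoMeans = c(PE = -5)),
               "geometric means")
  expect_error(beadPopulationSpec(10, channelGeoMeans = c(5)), "named")
  expect_error(genBeadEvents(beadPopulationSpec(0,
               channelGeoMeans = c(PE = 5))), "nEvents")
})

test_that("two-plex mixtures carry exact labels and gate out cleanly", {
  small <- beadPopulationSpec(1000, scatterCenter = c(120, 90),
                              scatterCV = 0.05,
                              channelGeoMeans = c(PE = 300), seed = 21)
  large <- beadPopulationSpec(1000, scatterCenter = c(400, 300),
                              scatterCV = 0.05,
                              channelGeoMeans = c(APC = 500), seed = 21)
  mix <- genTwoPlexEvents(small, large)
  expect_equal(unname(table(beadLabels(mix))["small"]), 1000)
  expect_equal(unname(table(beadLabels(mix))["large"]), 1000)
  expect_null(sampleMeta(mix)$separationWarning)
  # rectangular gate at the scatter midpoint recovers >= 99% of true labels
  mid <- (120 + 400) / 2
  gated <- gateEvents(mix, gateSpec(fscRange = c(0, mid), minEvents = 1))
  expect_gte(mean(beadLabels(gated) == "small"), 0.99)
  expect_gte(nEvents(gated) / 1000, 0.99)
})

test_that("empty small component yields a pure large-bead table", {
  small <- beadPopulationSpec(0, scatterCenter = c(120, 90),
                              channelGeoMeans = c(PE = 300), seed = 3)
  large <- beadPopulationSpec(500, scatterCenter = c(400, 300),
                              channelGeoMeans = c(PE = 500), seed = 3)
  mix <- genTwoPlexEvents(small, large)
  expect_equal(nEvents(mix), 500L)
  expect_true(all(beadLabels(mix) == "large"))
})

test_that("overlapping scatter populations record a separation warning", {
  a <- beadPopulationSpec(100, scatterCenter = c(200, 150), scatterCV = 0.2,
                         channelGeoMeans = c(PE = 10), seed = 5)
  b <- beadPopulationSpec(100, scatterCenter = c(240, 180), scatterCV = 0.2,
                         channelGeoMeans = c(PE = 10), seed = 5)
  mix <- genTwoPlexEvents(a, b)
  expect_match(sampleMeta(mix)$separationWarning, "overlap")
})

test_that("calibration ladder populations are ordered and exact when noise-free", {
  ladder <- genQuantibriteSet(seed = 11)
  mfis <- vapply(c("515", "5956", "26653", "69045"), function(lab) {
    sub <- eventData(ladder)$PE[beadLabels(ladder) == lab]
    exp(mean(log(sub)))
  }, numeric(1))
  expect_true(all(diff(mfis) > 0))
  exact <- genQuantibriteSet(gain = 1, sigma = 0, nPerPopulation = 50,
                             seed = 2)
  for (lab in c("515", "5956", "26653", "69045"))
    expect_equal(unique(eventData(exact)$PE[beadLabels(exact) == lab]),
                 as.numeric(lab))
  expect_error(genQuantibriteSet(moleculesPerBead = numeric(0)), "rung")
})

test_that("fitted log-log curve on a simulated ladder recovers gain within 3 s.e.", {
  gain <- 0.37
  ladder <- genQuantibriteSet(gain = gain, sigma = 0.3,
                              nPerPopulation = 2000, seed = 33)
  rungs <- c(515, 5956, 26653, 69045)
  mfis <- vapply(as.character(rungs), function(lab)
    exp(mean(log(eventData(ladder)$PE[beadLabels(ladder) == lab]))),
    numeric(1))
  curve <- fitStandardCurve(mfis, rungs)
  # independent OLS oracle for the standard errors
  ols <- summary(lm(log10(rungs) ~ log10(mfis)))$coefficients
  expect_lt(abs(curve@slope - 1), 3 * ols[2, 2] + 1e-12)
  expect_lt(abs(curve@intercept - (-log10(gain))), 3 * ols[1, 2] + 1e-12)
})

test_that("noise-free kinetic datasets equal the model output exactly", {
  p <- rateParameters()
  sch <- stimulationSchedule(0)
  times <- c(0, 2, 5, 10, 20, 60)
  ds <- genKineticDataset(p, sch, times, noiseCVPercent = 0, seed = 1)
  obs <- observations(ds)
  model <- computeObservables(simulateTimecourse(p, sch, times))
  for (o in c("bound_Z", "bound_pY319")) {
    for (r in 1:3) {
      got <- obs$value[obs$observable == o & obs$replicate == r]
      expect_equal(got, pmax(model[[o]], 0), tolerance = 1e-12)
    }
  }
  expect_equal(groundTruth(ds)$replicateCount, 3)
  expect_error(genKineticDataset(p, sch, times = c(-1, 5)), "non-negative")
})
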