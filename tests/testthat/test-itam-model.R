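# State enumeration, phosphatase recovery, mass-action field, steady state,
# simulation and observables of the opposing-ITAM-pair model.

test_that("state enumeration yields 7 single, 49 ordered and 28 unordered states", {
  expect_length(itamStates(), 7L)
  ps <- enumeratePairStates()
  expect_equal(nrow(ps$pairs), 28L)
  expect_equal(28L, 7L + choose(7L, 2L))
  expect_equal(length(ps$orderedIndex), 49L)
  expect_false(any(is.na(ps$orderedIndex)))
  # bijection: the index matrix is symmetric and every unordered state is
  # the image of one diagonal or two off-diagonal ordered pairs
  expect_identical(ps$orderedIndex, t(ps$orderedIndex))
  hits <- table(as.vector(ps$orderedIndex))
  expect_equal(sort(unique(as.integer(hits))), c(1L, 2L))
  expect_equal(sum(hits == 1), 7L)
  expect_equal(sum(hits == 2), 21L)
})

test_that("phosphatase activity drops to f_min at each dose and recovers exponentially", {
  sch <- stimulationSchedule(c(0, 20), horizon = 60)
  f <- 0.05; tau <- 10
  expect_equal(phosphataseActivity(-3, sch, f, tau), 1)
  expect_equal(phosphataseActivity(0, sch, f, tau), f)
  expect_equal(phosphataseActivity(tau, sch, f, tau),
               f + (1 - f) * (1 - exp(-1)))
  expect_equal(phosphataseActivity(20, sch, f, tau), f)  # reset at 2nd dose
  expect_equal(phosphataseActivity(20 + tau, sch, f, tau),
               f + (1 - f) * (1 - exp(-1)))
  g <- phosphataseActivity(seq(0, 60, by = 1), sch, f, tau)
  expect_true(all(g >= f & g <= 1))
})

test_that("the vector field conserves mass and vanishes for zero rates", {
  sch <- stimulationSchedule(0)
  zero <- rateParameters(0, 0, 0, 0, 0, 0, 0, 0, f_min = 0.5, tau_rec = 10)
  x <- rep(1 / 28, 28)
  expect_equal(derivativeField(5, x, zero, sch), rep(0, 28))
  set.seed(11)
  for (i in 1:10) {
    p <- randomRateParameters()
    w <- rexp(28); w <- w / sum(w)
    expect_lt(abs(sum(derivativeField(3, w, p, sch))), 1e-12)
  }
  expect_error(derivativeField(0, rep(1, 28), rateParameters(), sch), "sum")
})

test_that("the reduced field equals the aggregated 49-state brute-force field", {
  # g = 1 (pre-dose) and g = f_min (at the dose) probe both matrix parts
  set.seed(23)
  for (i in 1:6) {
    p <- randomRateParameters()
    w <- rexp(28); w <- w / sum(w)
    o <- oracleMatrices(p)
    x49 <- orderedFromUnordered(w)
    for (case in list(list(t = -1, sch = stimulationSchedule(5)),
                      list(t = 5, sch = stimulationSchedule(5)))) {
      g <- phosphataseActivity(case$t, case$sch,
                               rateValues(p)[["f_min"]],
                               rateValues(p)[["tau_rec"]])
      field49 <- as.numeric((o$A0 + g * o$A1) %*% x49)
      field28 <- derivativeField(case$t, w, p, case$sch)
      expect_equal(unorderedFromOrdered(field49), field28,
                   tolerance = 1e-10)
    }
  }
})

test_that("the resting steady state is stationary and matches the binomial law at k_on = 0", {
  p <- rateParameters()
  x <- restingSteadyState(p)
  expect_equal(sum(x), 1, tolerance = 1e-12)
  expect_lt(max(abs(derivativeField(0, x, p,
                                    stimulationSchedule(numeric(0))))),
            1e-10)
  # with no ZAP70 binding the four sites phosphorylate independently
  p0 <- rateParameters(k_itam_p = 0.3, k_itam_dp = 0.7, k_on = 0)
  x0 <- restingSteadyState(p0)
  prob <- 0.3 / (0.3 + 0.7)
  q <- c(U = (1 - prob)^2, P1 = 2 * prob * (1 - prob), P2 = prob^2)
  ps <- enumeratePairStates()$pairs
  expected <- vapply(seq_len(28), function(u) {
    s1 <- ps$site1[u]; s2 <- ps$site2[u]
    if (!s1 %in% names(q) || !s2 %in% names(q)) return(0)
    if (s1 == s2) q[[s1]]^2 else 2 * q[[s1]] * q[[s2]]
  }, numeric(1))
  expect_equal(unname(x0), expected, tolerance = 1e-9)
})

test_that("with irreversible forward steps all mass ends doubly trans-phosphorylated", {
  p <- rateParameters(k_itam_p = 1, k_itam_dp = 0, k_on = 1, k_off = 0,
                      k_y319 = 1, k_y319_dp = 0, k_y493 = 1, k_y493_dp = 0)
  x <- restingSteadyState(p)
  expect_equal(unname(x["Z319_493|Z319_493"]), 1, tolerance = 1e-9)
})

test_that("without a dose the trajectory stays at the resting state", {
  p <- rateParameters()
  tr <- simulateTimecourse(p, stimulationSchedule(numeric(0)),
                           times = c(0, 10, 30, 60))
  x0 <- restingSteadyState(p)
  for (i in 1:4)
    expect_equal(unname(stateOccupancies(tr)[i, ]), unname(x0),
                 tolerance = 1e-8)
})

test_that("halving integrator tolerances leaves observables unchanged to 1e-6", {
  p <- rateParameters()
  sch <- stimulationSchedule(0)
  times <- c(0, 2, 5, 10, 20, 60)
  a <- computeObservables(simulateTimecourse(p, sch, times))
  b <- computeObservables(simulateTimecourse(p, sch, times,
                                             rtol = 5e-10, atol = 5e-12))
  for (o in c("bound_Z", "bound_pY319", "bound_pY493"))
    expect_lt(max(abs(a[[o]] - b[[o]]) / pmax(abs(a[[o]]), 1e-12)), 1e-6)
})

test_that("observables count bound ITAMs per pair with the configured scales", {
  p <- rateParameters(s_Z = 2.5, s_pY = 0.5)
  ps <- enumeratePairStates()
  mkTraj <- function(label) {
    m <- matrix(0, 1, 28, dimnames = list(NULL, ps$pairs$label))
    m[1, label] <- 1
    new("PairStateTrajectory", times = 0, states = m, parameters = p,
        schedule = stimulationSchedule(0))
  }
  full <- computeObservables(mkTraj("Z319_493|Z319_493"))
  expect_equal(full$bound_Z, 2 * 2.5)
  expect_equal(full$bound_pY319, 2 * 0.5)
  expect_equal(full$bound_pY493, 2)
  expect_equal(full$ratio, 0.5 / 2.5 * 1)  # scale ratio times true ratio 1
  empty <- computeObservables(mkTraj("U|U"))
  expect_equal(empty$bound_Z, 0)
  expect_true(is.na(empty$ratio))
  mixed <- computeObservables(mkTraj("U|Z319"))
  expect_equal(mixed$bound_Z, 2.5)
  expect_equal(mixed$bound_pY319, 0.5)
  expect_equal(mixed$bound_pY493, 0)
})

test_that("the bound pY319/ZAP70 ratio dips after the dose and later exceeds rest", {
  obs <- computeObservables(simulateTimecourse(
    rateParameters(), stimulationSchedule(0), c(0, 2, 5, 10, 20, 60)))
  expect_lt(obs$ratio[obs$time_min == 2], obs$ratio[obs$time_min == 0])
  expect_gt(obs$ratio[obs$time_min == 60], obs$ratio[obs$time_min == 0])
})

test_that("Y493 phosphorylation peaks no earlier than Y319 around the fitted regime", {
  # The delay is a property of the slow-trans-autophosphorylation regime the
  # data select, not of arbitrary rate combinations (fast Y493 turnover can
  # move the pY493 peak slightly ahead); sample around the defaults.
  grid <- seq(0, 60, by = 0.5)
  set.seed(31)
  cases <- c(list(rateParameters()), lapply(1:6, function(i) {
    j <- rnorm(10, 0, 0.15)
    r <- rateValues(rateParameters())
    rateParameters(r[["k_itam_p"]] * 10^j[1], r[["k_itam_dp"]] * 10^j[2],
                   r[["k_on"]] * 10^j[3], r[["k_off"]] * 10^j[4],
                   r[["k_y319"]] * 10^j[5], r[["k_y319_dp"]] * 10^j[6],
                   r[["k_y493"]] * 10^j[7], r[["k_y493_dp"]] * 10^j[8],
                   f_min = min(r[["f_min"]] * 10^j[9], 1),
                   tau_rec = r[["tau_rec"]] * 10^j[10])
  }))
  for (p in cases) {
    obs <- computeObservables(simulateTimecourse(p, stimulationSchedule(0),
                                                 grid))
    expect_gte(grid[which.max(obs$bound_pY493)],
               grid[which.max(obs$bound_pY319)])
  }
})

test_that("stronger phosphatase inhibition weakly increases the bound observables", {
  times <- c(0, 2, 5, 10, 20, 60)
  sch <- stimulationSchedule(0)
  strong <- computeObservables(simulateTimecourse(
    rateParameters(f_min = 0.01), sch, times))
  weak <- computeObservables(simulateTimecourse(
    rateParameters(f_min = 0.3), sch, times))
  expect_true(all(strong$bound_Z >= weak$bound_Z - 1e-8))
  expect_true(all(strong$bound_pY319 >= weak$bound_pY319 - 1e-8))
})

test_that("a second dose raises bound pY319 at 60 min above the single-dose level", {
  p <- rateParameters()
  single <- computeObservables(simulateTimecourse(
    p, stimulationSchedule(0), c(0, 60)))
  double <- computeObservables(simulateTimecourse(
    p, stimulationSchedule(c(0, 20)), c(0, 60)))
  expect_gt(double$bound_pY319[double$time_min == 60],
            single$bound_pY319[single$time_min == 60])
})

test_that("the resting bound fraction is more phosphorylated than bound plus free pool", {
  r <- restingBoundVsTotal(rateParameters(), freePool = 10)
  expect_gt(r$boundRatio, r$totalRatio)
  expect_error(restingBoundVsTotal(rateParameters(), freePool = 0), "> 0")
})
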