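# Least-squares fitting of the pair model to time-course data by simulated
# annealing, plus the model's out-of-sample predictions.

.OBSERVABLE_COLS <- c("bound_Z", "bound_pY319")

#' Least-squares loss of the model against a time-course dataset
#'
#' Sum over all observation rows (both observables, every replicate
#' individually) of squared residuals between the measured values and the
#' scaled model observables at the observation times.  A failed simulation
#' returns a large but finite penalty (with attribute
#' \code{"simulationFailed"}) so a stochastic search can continue past bad
#' parameter regions.
#'
#' @param params a [RateParameters-class].
#' @param data a [TimeCourseDataset-class] with observables among
#'   \code{bound_Z}, \code{bound_pY319}.
#' @param schedule a [StimulationSchedule-class].
#' @param rtol,atol integrator tolerances used inside the objective
#'   (slightly looser than the simulation defaults; the residual scale is
#'   far above the integration error either way).
#' @return Scalar residual sum of squares.
#' @examples
#' p <- rateParameters()
#' d <- genKineticDataset(p, noiseCVPercent = 0, seed = 1)
#' lossFunction(p, d, stimulationSchedule(0))  # ~0 at the generating truth
#' @export
lossFunction <- function(params, data, schedule, rtol = 1e-7, atol = 1e-9) {
  stopifnot(is(data, "TimeCourseDataset"))
  obs <- observations(data)
  bad <- setdiff(unique(obs$observable), .OBSERVABLE_COLS)
  if (length(bad))
    stop("unsupported observables in data: ", paste(bad, collapse = ", "))
  times <- sort(unique(obs$time_min))
  pred <- tryCatch(
    computeObservables(simulateTimecourse(params, schedule, times,
                                          rtol = rtol, atol = atol)),
    error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(as.matrix(pred[.OBSERVABLE_COLS]))))
    return(structure(1e12, simulationFailed = TRUE))
  fitted <- mapply(function(tm, ob) pred[[ob]][match(tm, pred$time_min)],
                   obs$time_min, obs$observable)
  sum((obs$value - fitted)^2)
}

# default log10-space search box: rate constants span [1e-4, 1e3] /min;
# f_min is a fraction in (0, 1]; tau_rec in minutes; scales arbitrary.
.defaultBounds <- function() {
  lower <- c(k_itam_p = 1e-4, k_itam_dp = 1e-4, k_on = 1e-4, k_off = 1e-4,
             k_y319 = 1e-4, k_y319_dp = 1e-4, k_y493 = 1e-4,
             k_y493_dp = 1e-4, f_min = 1e-4, tau_rec = 0.1,
             s_Z = 1e-3, s_pY = 1e-3)
  upper <- c(k_itam_p = 1e3, k_itam_dp = 1e3, k_on = 1e3, k_off = 1e3,
             k_y319 = 1e3, k_y319_dp = 1e3, k_y493 = 1e3,
             k_y493_dp = 1e3, f_min = 1, tau_rec = 1e3,
             s_Z = 1e3, s_pY = 1e3)
  list(lower = lower, upper = upper)
}

.setRates <- function(params, values) {
  r <- rateValues(params)
  r[names(values)] <- values
  new("RateParameters", rates = r)
}

# reflect a proposal back into [lo, hi] (log10 space)
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Fit the pair model by simulated annealing
#'
#' Stochastic least-squares search over a chosen subset of the model
#' parameters in log10 space: Gaussian proposals, Metropolis acceptance, and
#' geometric cooling from an initial temperature set by the starting
#' objective.  The best-ever parameter set is returned; an optional
#' Nelder-Mead polish (on by default) refines it within the bounds.  The
#' whole search is reproducible for a fixed seed.
#'
#' @param data a [TimeCourseDataset-class].
#' @param schedule a [StimulationSchedule-class].
#' @param init starting [RateParameters-class] (also supplies the values of
#'   parameters that are not searched).
#' @param fitNames names of the parameters to search (subset of the twelve);
#'   default searches the kinetic rates that shape the stimulated response
#'   plus both observable scales.
#' @param bounds list with named \code{lower}/\code{upper} vectors (linear
#'   scale) for the searched parameters; defaults to \code{[1e-4, 1e3]} per
#'   minute for rate constants.
#' @param seed integer seed for the stochastic search.
#' @param control list of annealing settings: \code{nTemps} temperature
#'   levels (default 40), \code{proposalsPerTemp} (default 200),
#'   \code{coolingFactor} geometric cooling (default 0.95),
#'   \code{proposalSD} Gaussian proposal s.d. in log10 units (default 0.15),
#'   \code{initialTemp} (default: the starting objective, floored at 1e-8),
#'   \code{polish} logical Nelder-Mead refinement (default TRUE).
#' @return A [FitResult-class].
#' @examples
#' \donttest{
#' truth <- rateParameters()
#' d <- genKineticDataset(truth, noiseCVPercent = 5, seed = 2)
#' fit <- annealFit(d, stimulationSchedule(0), seed = 7,
#'                  control = list(nTemps = 10, proposalsPerTemp = 40))
#' bestParameters(fit)
#' }
#' @export
annealFit <- function(data, schedule, init = rateParameters(),
                      fitNames = c("k_itam_p", "k_itam_dp", "k_on",
                                   "k_y319", "f_min", "tau_rec",
                                   "s_Z", "s_pY"),
                      bounds = NULL, seed = 1L, control = list()) {
  stopifnot(is(data, "TimeCourseDataset"), is(init, "RateParameters"))
  if (!length(fitNames) || !all(fitNames %in% .RATE_NAMES))
    stop("'fitNames' must be a non-empty subset of the model parameters")
  ctl <- utils::modifyList(list(nTemps = 40L, proposalsPerTemp = 200L,
                                coolingFactor = 0.95, proposalSD = 0.15,
                                initialTemp = NULL, polish = TRUE), control)
  if (ctl$nTemps < 1L || ctl$proposalsPerTemp < 1L)
    stop("annealing config must allow at least one proposal")
  db <- .defaultBounds()
  lower <- db$lower[fitNames]; upper <- db$upper[fitNames]
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(lower >= upper))
    stop("bounds must be finite, positive, and lower < upper")
  lo <- log10(lower); hi <- log10(upper)
  objective <- function(theta) {
    vals <- 10^theta
    names(vals) <- fitNames
    lossFunction(.setRates(init, vals), data, schedule)
  }
  start <- pmin(pmax(log10(rateValues(init)[fitNames]), lo), hi)
  res <- withSeed(seed, {
    theta <- start
    f <- objective(theta)
    best <- list(theta = theta, f = f)
    temp <- if (is.null(ctl$initialTemp)) max(f, 1e-8) else ctl$initialTemp
    trace <- vector("list", ctl$nTemps)
    iter <- 0L
    for (lev in seq_len(ctl$nTemps)) {
      for (j in seq_len(ctl$proposalsPerTemp)) {
        iter <- iter + 1L
        prop <- .reflect(theta + stats::rnorm(length(theta), 0,
                                              ctl$proposalSD), lo, hi)
        fp <- objective(prop)
        if (fp <= f || stats::runif(1) < exp((f - fp) / temp)) {
          theta <- prop; f <- fp
          if (f < best$f) best <- list(theta = theta, f = f)
        }
      }
      trace[[lev]] <- data.frame(iteration = iter, temperature = temp,
                                 accepted = f, best = best$f)
      temp <- temp * ctl$coolingFactor
    }
    list(best = best, trace = do.call(rbind, trace))
  })
  best <- res$best
  if (isTRUE(ctl$polish)) {
    pen <- function(theta) {
      if (any(theta < lo) || any(theta > hi)) return(1e14)
      objective(theta)
    }
    # restarted Nelder-Mead: a fresh simplex at the previous optimum escapes
    # the degenerate collapse NM is prone to in >4 dimensions
    for (rep in 1:2) {
      opt <- stats::optim(best$theta, pen, method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-12))
      if (opt$value < best$f)
        best <- list(theta = opt$par, f = opt$value)
    }
  }
  vals <- 10^best$theta
  names(vals) <- fitNames
  new("FitResult", parameters = .setRates(init, vals), rss = best$f,
      trace = res$trace, seed = as.integer(seed),
      bounds = list(lower = lower, upper = upper), fitted = fitNames)
}

#' Out-of-sample predictions of a fitted model
#'
#' From a fit obtained on bound-ZAP70 and bound-pY319 data alone, emits the
#' model's three testable predictions, each with the predicted quantities
#' and a pass/fail flag on the qualitative direction:
#' \enumerate{
#'   \item Y493 delay: the bound-pY493 time course (never used in fitting)
#'     peaks no earlier than bound-pY319 after a single dose;
#'   \item a second inhibitor dose at 20 min raises bound-pY319 at 60 min
#'     above the single-dose value;
#'   \item at rest, the pY319/ZAP70 ratio of the TCR-bound fraction exceeds
#'     the ratio over bound plus free ZAP70 (the free pool being
#'     unphosphorylated in the model).
#' }
#'
#' @param fit a [FitResult-class] (or a [RateParameters-class]).
#' @param horizon prediction horizon in minutes (default 60).
#' @param freePool free ZAP70 per ITAM pair for the resting-ratio
#'   comparison.
#' @param dt time step of the dense prediction grid (minutes).
#' @return List with components \code{y493Delay}, \code{doubleDose} and
#'   \code{restingRatio}, each a list of values plus a \code{pass} flag.
#' @export
predictUnfitted <- function(fit, horizon = 60, freePool = 10, dt = 0.25) {
  params <- if (is(fit, "FitResult")) bestParameters(fit) else fit
  stopifnot(is(params, "RateParameters"))
  grid <- seq(0, horizon, by = dt)
  single <- stimulationSchedule(0, horizon = horizon)
  obs1 <- computeObservables(simulateTimecourse(params, single, grid))
  tPeak <- function(v) grid[which.max(v)]
  t319 <- tPeak(obs1$bound_pY319)
  t493 <- tPeak(obs1$bound_pY493)
  double <- stimulationSchedule(c(0, 20), horizon = horizon)
  obs2 <- computeObservables(simulateTimecourse(params, double,
                                                c(0, horizon)))
  pyEndSingle <- obs1$bound_pY319[length(grid)]
  pyEndDouble <- obs2$bound_pY319[obs2$time_min == horizon]
  rest <- restingBoundVsTotal(params, freePool = freePool)
  list(
    y493Delay = list(timeToPeakPY319 = t319, timeToPeakPY493 = t493,
                     pass = t493 >= t319),
    doubleDose = list(singleDosePY319 = pyEndSingle,
                      doubleDosePY319 = pyEndDouble,
                      pass = pyEndDouble > pyEndSingle),
    restingRatio = list(boundRatio = rest$boundRatio,
                        totalRatio = rest$totalRatio,
                        pass = rest$boundRatio > rest$totalRatio)
  )
}
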