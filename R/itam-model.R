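# Mass-action dynamics of the opposing-ITAM pair: phosphatase-inhibitor
# stimulation, steady-state initialisation, stiff integration, observables.

#' Phosphatase activity under inhibitor dosing
#'
#' Tyrosine-phosphatase inhibition by pervanadate is modelled as an
#' instantaneous drop of the phosphatase activity to a residual fraction
#' \code{fMin} at each dose, followed by slow exponential recovery (ongoing
#' phosphatase synthesis) with time constant \code{tauRec}:
#' \deqn{g(t) = f_{min} + (1 - f_{min})\,(1 - e^{-(t - t_{dose})/\tau})}
#' between doses, and \eqn{g(t) = 1} before the first dose.  The multiplier
#' applies to every dephosphorylation rate constant of the model (not to
#' ZAP70 unbinding, which is not a phosphatase-catalysed step).
#'
#' @param t time(s) in minutes (vectorised).
#' @param schedule a [StimulationSchedule-class].
#' @param fMin residual activity fraction in (0, 1] right after a dose.
#' @param tauRec recovery time constant in minutes.
#' @return Numeric vector of multipliers in (0, 1].
#' @examples
#' sch <- stimulationSchedule(0, horizon = 60)
#' phosphataseActivity(c(-1, 0, 35), sch, fMin = 0.02, tauRec = 35)
#' @export
phosphataseActivity <- function(t, schedule, fMin, tauRec) {
  stopifnot(is(schedule, "StimulationSchedule"))
  if (fMin <= 0 || fMin > 1) stop("'fMin' must lie in (0, 1]")
  if (tauRec <= 0) stop("'tauRec' must be > 0")
  doses <- schedule@doseTimes
  g <- rep(1, length(t))
  if (!length(doses)) return(g)
  idx <- findInterval(t, doses)  # 0 before first dose
  active <- idx > 0L
  dt <- t[active] - doses[idx[active]]
  g[active] <- fMin + (1 - fMin) * (1 - exp(-dt / tauRec))
  g
}

#' Time derivative of the 28 pair-state occupancies
#'
#' Evaluates the first-order mass-action vector field of the symmetry-reduced
#' pair model at time \code{t}: within each pair state both ITAM sites
#' undergo their single-ITAM transitions independently (with a combinatorial
#' factor 2 out of symmetric states), except Y493 trans-autophosphorylation,
#' which proceeds only when the opposing ITAM carries an opened (pY319)
#' ZAP70.  Dephosphorylation rate constants are multiplied by the
#' phosphatase activity \code{g(t)} from [phosphataseActivity()].
#'
#' @param t time in minutes.
#' @param x occupancy vector of the 28 pair states (sums to 1 within
#'   tolerance).
#' @param params a [RateParameters-class].
#' @param schedule a [StimulationSchedule-class].
#' @param matrices optional precomputed result of the internal generator
#'   assembly (used by the integrator to avoid rebuilding).
#' @return Numeric vector dx/dt of length 28 (sums to 0).
#' @examples
#' p <- rateParameters()
#' x0 <- restingSteadyState(p)
#' d <- derivativeField(0, x0, p, stimulationSchedule(numeric(0)))
#' max(abs(d))  # ~0 at the resting steady state
#' @export
derivativeField <- function(t, x, params, schedule, matrices = NULL) {
  if (length(x) != 28L) stop("'x' must have 28 entries")
  if (any(x < -1e-6)) stop("negative occupancies beyond tolerance")
  if (abs(sum(x) - 1) > 1e-3)
    stop("'x' must sum to 1 within tolerance")
  if (is.null(matrices)) matrices <- pairRateMatrices(params)
  r <- rateValues(params)
  g <- phosphataseActivity(t, schedule, r[["f_min"]], r[["tau_rec"]])
  as.numeric((matrices$A0 + g * matrices$A1) %*% x)
}

#' Resting steady state of the pair model
#'
#' The state of the system before any inhibitor dose: the stationary
#' distribution of the generator with uninhibited phosphatase activity
#' (g = 1), computed as the null vector of the rate matrix (normalised to
#' sum 1), with a long-time integration fallback if the algebraic solution
#' is not clean.
#'
#' @param params a [RateParameters-class].
#' @param tol maximum allowed residual \code{max(abs(dx/dt))} at the
#'   returned state.
#' @return Named occupancy vector of length 28 summing to 1.
#' @examples
#' x0 <- restingSteadyState(rateParameters())
#' sum(x0)
#' @export
restingSteadyState <- function(params, tol = 1e-10) {
  stopifnot(is(params, "RateParameters"))
  mats <- pairRateMatrices(params)
  A <- mats$A0 + mats$A1
  # Null vector via SVD; the generator has a one-dimensional kernel for any
  # irreducible parameter set.
  sv <- svd(A)
  x <- sv$v[, 28]
  x <- x / sum(x)
  if (any(x < -1e-9) || max(abs(A %*% x)) > tol) {
    # fallback: relax from the uniform distribution for a long horizon
    sch0 <- stimulationSchedule(numeric(0), horizon = 1)
    f <- function(t, y, p) list(as.numeric(A %*% y))
    horizon <- 1e4 / max(sum(abs(diag(A))), 1)
    out <- deSolve::lsoda(rep(1 / 28, 28), c(0, horizon), f, parms = NULL,
                          rtol = 1e-12, atol = 1e-14)
    x <- as.numeric(out[nrow(out), -1])
    x <- pmax(x, 0); x <- x / sum(x)
  }
  res <- max(abs(A %*% x))
  if (res > tol)
    stop(sprintf("steady state did not converge: residual %.3e > %.1e",
                 res, tol))
  x <- pmax(x, 0); x <- x / sum(x)
  names(x) <- enumeratePairStates()$pairs$label
  x
}

#' Simulate the pair model over a stimulation schedule
#'
#' Integrates the 28-state system from the resting steady state with a
#' stiff-capable solver (\code{deSolve::lsoda}), restarting at each inhibitor
#' dose so the discontinuity in \code{g(t)} is handled exactly.
#'
#' @param params a [RateParameters-class].
#' @param schedule a [StimulationSchedule-class].
#' @param times output time points in minutes (non-negative).
#' @param rtol,atol integrator tolerances.
#' @return A [PairStateTrajectory-class] with one row per requested time.
#' @examples
#' tr <- simulateTimecourse(rateParameters(), stimulationSchedule(0),
#'                          times = c(0, 2, 5, 10, 20, 60))
#' computeObservables(tr)
#' @export
simulateTimecourse <- function(params, schedule, times,
                               rtol = 1e-9, atol = 1e-11) {
  stopifnot(is(params, "RateParameters"), is(schedule, "StimulationSchedule"))
  if (any(times < 0)) stop("'times' must be non-negative")
  times <- as.numeric(times)
  outTimes <- sort(unique(times))
  mats <- pairRateMatrices(params)
  r <- rateValues(params)
  x <- restingSteadyState(params)
  labels <- names(x)
  doses <- schedule@doseTimes
  tEnd <- max(outTimes, doses, 0)
  # Segment boundaries: 0, each dose, end of horizon.
  bounds <- sort(unique(c(0, doses[doses <= tEnd], tEnd)))
  sol <- matrix(NA_real_, length(outTimes), 28,
                dimnames = list(NULL, labels))
  if (0 %in% outTimes) sol[which(outTimes == 0), ] <- x
  deriv <- function(t, y, p) {
    g <- phosphataseActivity(t, schedule, r[["f_min"]], r[["tau_rec"]])
    list(as.numeric((mats$A0 + g * mats$A1) %*% y))
  }
  # the field is linear in x, so the Jacobian is the generator itself
  jac <- function(t, y, p) {
    g <- phosphataseActivity(t, schedule, r[["f_min"]], r[["tau_rec"]])
    mats$A0 + g * mats$A1
  }
  for (seg in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    if (t1 <= t0) next
    inner <- outTimes[outTimes > t0 & outTimes <= t1]
    segTimes <- sort(unique(c(t0, inner, t1)))
    out <- tryCatch(
      deSolve::lsoda(x, segTimes, deriv, parms = NULL,
                     jacfunc = jac, jactype = "fullusr",
                     rtol = rtol, atol = atol),
      warning = function(w) stop("integrator failure: ",
                                 conditionMessage(w), call. = FALSE)
    )
    if (nrow(out) < length(segTimes))
      stop("integrator failure: incomplete output on segment [",
           t0, ", ", t1, "]")
    m <- out[, -1, drop = FALSE]
    if (length(inner))
      sol[match(inner, outTimes), ] <- m[match(inner, segTimes), ]
    x <- as.numeric(m[nrow(m), ])
  }
  drift <- abs(rowSums(sol) - 1)
  if (any(drift > 1e-6))
    stop("integrator failure: occupancy drift ", max(drift))
  # raw solver output is kept (no renormalisation) so conservation along the
  # trajectory remains a measurable property of the integration
  # return rows in the order the caller asked for
  sol <- sol[match(times, outTimes), , drop = FALSE]
  new("PairStateTrajectory", times = times, states = sol,
      parameters = params, schedule = schedule)
}

#' Model observables of a trajectory
#'
#' Maps pair-state occupancies to the assay's observables.  Per ITAM pair:
#' \describe{
#'   \item{bound_Z}{expected number of ITAMs carrying a bound ZAP70 (states
#'     Z, Z319, Z319_493, Z493), scaled by \code{s_Z};}
#'   \item{bound_pY319}{ITAMs whose ZAP70 is phosphorylated at Y319 (Z319,
#'     Z319_493), scaled by \code{s_pY};}
#'   \item{bound_pY493}{ITAMs whose ZAP70 is phosphorylated at Y493
#'     (Z319_493, Z493), unscaled prediction channel;}
#'   \item{ratio}{bound_pY319 / bound_Z (NA when bound_Z is zero).}
#' }
#'
#' @param trajectory a [PairStateTrajectory-class].
#' @return data.frame with columns \code{time_min}, \code{bound_Z},
#'   \code{bound_pY319}, \code{bound_pY493}, \code{ratio}.
#' @export
computeObservables <- function(trajectory) {
  stopifnot(is(trajectory, "PairStateTrajectory"))
  ps <- enumeratePairStates()$pairs
  countIn <- function(set) (ps$site1 %in% set) + (ps$site2 %in% set)
  x <- trajectory@states
  r <- rateValues(trajectory@parameters)
  bz  <- as.numeric(x %*% countIn(.ZAP_BOUND)) * r[["s_Z"]]
  py  <- as.numeric(x %*% countIn(.PY319)) * r[["s_pY"]]
  py4 <- as.numeric(x %*% countIn(.PY493))
  ratio <- ifelse(bz > 0, py / bz, NA_real_)
  data.frame(time_min = trajectory@times, bound_Z = bz,
             bound_pY319 = py, bound_pY493 = py4, ratio = ratio)
}

#' Bound versus total pY319/ZAP70 ratio at rest
#'
#' The model keeps the cytosolic ZAP70 pool constant and unphosphorylated,
#' so at the resting steady state the pY319/ZAP70 ratio of the TCR-bound
#' fraction always exceeds the ratio computed over bound plus free ZAP70.
#' This helper computes both ratios for a given free-pool size (free ZAP70
#' molecules per ITAM pair, in the same per-pair units as the observables).
#'
#' @param params a [RateParameters-class].
#' @param freePool constant free (unphosphorylated) ZAP70 per ITAM pair;
#'   must be > 0.
#' @return List with \code{boundRatio}, \code{totalRatio} and the resting
#'   per-pair \code{boundZ}, \code{boundPY319}.
#' @export
restingBoundVsTotal <- function(params, freePool = 10) {
  if (freePool <= 0) stop("'freePool' must be > 0")
  x <- restingSteadyState(params)
  ps <- enumeratePairStates()$pairs
  countIn <- function(set) (ps$site1 %in% set) + (ps$site2 %in% set)
  bz <- sum(x * countIn(.ZAP_BOUND))
  py <- sum(x * countIn(.PY319))
  list(boundRatio = py / bz, totalRatio = py / (bz + freePool),
       boundZ = bz, boundPY319 = py)
}
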