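#' @import methods
NULL

#' BeadEventTable: per-event scatter and fluorescence intensities
#'
#' Container for one acquired bead sample: one row per flow-cytometry event
#' with forward scatter (\code{fsc}), side scatter (\code{ssc}) and one column
#' per fluorescence channel.  Sample-level metadata (condition label, time
#' point in minutes, replicate id, gating provenance) live in \code{meta};
#' synthetic mixtures may carry hidden ground-truth population labels in
#' \code{labels} for gate-accuracy tests.
#'
#' @slot events data.frame with columns \code{fsc}, \code{ssc} and the
#'   fluorescence channels; all intensities are non-negative.
#' @slot channels character vector naming the fluorescence channel columns.
#' @slot labels character vector of hidden per-event population labels
#'   (length 0 when absent).
#' @slot meta named list of sample metadata.
#'
#' @seealso [beadEventTable()], [gateEvents()], [geometricMFI()]
#' @exportClass BeadEventTable
setClass("BeadEventTable",
  representation(
    events   = "data.frame",
    channels = "character",
    labels   = "character",
    meta     = "list"
  ),
  prototype(
    events   = data.frame(fsc = numeric(0), ssc = numeric(0)),
    channels = character(0),
    labels   = character(0),
    meta     = list()
  )
)

setValidity("BeadEventTable", function(object) {
  ev <- object@events
  msgs <- character(0)
  if (!all(c("fsc", "ssc") %in% names(ev)))
    msgs <- c(msgs, "'events' must contain 'fsc' and 'ssc' columns")
  if (length(object@channels) < 1L)
    msgs <- c(msgs, "at least one fluorescence channel is required")
  if (!all(object@channels %in% names(ev)))
    msgs <- c(msgs, "all 'channels' must be columns of 'events'")
  else {
    vals <- as.matrix(ev[, object@channels, drop = FALSE])
    if (nrow(ev) && any(!is.finite(vals) | vals < 0))
      msgs <- c(msgs, "channel intensities must be finite and >= 0")
  }
  if (length(object@labels) && length(object@labels) != nrow(ev))
    msgs <- c(msgs, "'labels' must be empty or one per event")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BeadEventTable
#'
#' @param events data.frame with \code{fsc}, \code{ssc} and channel columns.
#' @param channels character vector of fluorescence channel column names;
#'   defaults to every column of \code{events} other than \code{fsc}/\code{ssc}.
#' @param labels optional per-event ground-truth population labels.
#' @param meta named list of sample metadata (condition, time_min, replicate, ...).
#' @return A [BeadEventTable-class] object.
#' @examples
#' ev <- data.frame(fsc = c(100, 110), ssc = c(50, 55), PE = c(200, 220))
#' beadEventTable(ev)
#' @export
beadEventTable <- function(events, channels = NULL, labels = character(0),
                           meta = list()) {
  if (is.null(channels))
    channels <- setdiff(names(events), c("fsc", "ssc"))
  new("BeadEventTable", events = as.data.frame(events),
      channels = as.character(channels),
      labels = as.character(labels), meta = meta)
}

#' GateSpec: rectangular scatter gate
#'
#' A rectangular gate in (FSC, SSC) space plus the minimum number of events
#' the gated population must retain.  The acquisition default of 5000 events
#' per sample is configurable for small test samples.
#'
#' @slot fscRange,sscRange closed intervals \code{c(lower, upper)}.
#' @slot minEvents minimum retained events below which gating errors out.
#' @exportClass GateSpec
setClass("GateSpec",
  representation(fscRange = "numeric", sscRange = "numeric",
                 minEvents = "numeric"),
  prototype(fscRange = c(0, Inf), sscRange = c(0, Inf), minEvents = 5000)
)

setValidity("GateSpec", function(object) {
  msgs <- character(0)
  if (length(object@fscRange) != 2L || object@fscRange[1] >= object@fscRange[2])
    msgs <- c(msgs, "'fscRange' must be c(lower, upper) with lower < upper")
  if (length(object@sscRange) != 2L || object@sscRange[1] >= object@sscRange[2])
    msgs <- c(msgs, "'sscRange' must be c(lower, upper) with lower < upper")
  if (length(object@minEvents) != 1L || object@minEvents < 0)
    msgs <- c(msgs, "'minEvents' must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GateSpec
#'
#' @param fscRange,sscRange closed intervals \code{c(lower, upper)}.
#' @param minEvents minimum number of events the gate must retain (default
#'   5000, the usual number of beads acquired per sample).
#' @return A [GateSpec-class] object.
#' @export
gateSpec <- function(fscRange = c(0, Inf), sscRange = c(0, Inf),
                     minEvents = 5000) {
  new("GateSpec", fscRange = as.numeric(fscRange),
      sscRange = as.numeric(sscRange), minEvents = as.numeric(minEvents))
}

#' MFIResult: geometric MFI of one channel with background subtraction
#'
#' @slot channel channel name.
#' @slot geometricMFI geometric mean fluorescence intensity of the gated events.
#' @slot nEvents number of events entering the geometric mean.
#' @slot droppedEvents number of non-positive events dropped before the log.
#' @slot backgroundMFI geometric MFI of the matched control population.
#' @slot netMFI \code{max(geometricMFI - backgroundMFI, 0)}.
#' @slot floored TRUE when the subtraction was floored at zero.
#' @exportClass MFIResult
setClass("MFIResult",
  representation(channel = "character", geometricMFI = "numeric",
                 nEvents = "integer", droppedEvents = "integer",
                 backgroundMFI = "numeric", netMFI = "numeric",
                 floored = "logical"),
  prototype(channel = NA_character_, geometricMFI = NA_real_,
            nEvents = 0L, droppedEvents = 0L, backgroundMFI = 0,
            netMFI = NA_real_, floored = FALSE)
)

setValidity("MFIResult", function(object) {
  msgs <- character(0)
  if (!is.na(object@netMFI) && object@netMFI < 0)
    msgs <- c(msgs, "'netMFI' must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' CalibrationCurve: log-log map between MFI and molecules per bead
#'
#' Ordinary least-squares line fitted in (log10 MFI, log10 molecules-per-bead)
#' space from a calibration bead ladder; used to convert net MFIs into
#' absolute fluorophore (and hence stained-protein) counts.
#'
#' @slot slope,intercept coefficients of
#'   \code{log10(molecules) = slope * log10(MFI) + intercept}.
#' @slot r Pearson correlation coefficient of the log-log fit.
#' @slot nPoints number of ladder points used.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(slope = "numeric", intercept = "numeric", r = "numeric",
                 nPoints = "integer")
)

setValidity("CalibrationCurve", function(object) {
  msgs <- character(0)
  if (object@nPoints < 2L) msgs <- c(msgs, "'nPoints' must be >= 2")
  if (!is.finite(object@slope)) msgs <- c(msgs, "'slope' must be finite")
  if (object@slope <= 0)
    msgs <- c(msgs, "'slope' must be > 0 (monotone calibration)")
  if (length(msgs)) msgs else TRUE
})

#' MoleculeCount: absolute molecules per bead with uncertainty
#'
#' @slot molecules molecules per bead (continuous).
#' @slot sem standard error of the mean (NA when unknown).
#' @exportClass MoleculeCount
setClass("MoleculeCount",
  representation(molecules = "numeric", sem = "numeric"),
  prototype(molecules = NA_real_, sem = NA_real_)
)

setValidity("MoleculeCount", function(object) {
  if (!is.na(object@molecules) && object@molecules < 0)
    "'molecules' must be non-negative" else TRUE
})

#' Construct a MoleculeCount
#'
#' @param molecules molecules per bead.
#' @param sem standard error of the mean (optional).
#' @return A [MoleculeCount-class] object.
#' @export
moleculeCount <- function(molecules, sem = NA_real_) {
  new("MoleculeCount", molecules = as.numeric(molecules),
      sem = as.numeric(sem))
}

#' RateParameters: rate constants of the paired-ITAM model
#'
#' All first-order mass-action rate constants of the opposing-ITAM-pair model
#' (per minute; the constant active-Lck and free-ZAP70 concentrations are
#' absorbed into the pseudo-first-order constants), plus the
#' phosphatase-inhibition parameters and observable scale factors:
#' \describe{
#'   \item{k_itam_p}{per-site ITAM tyrosine phosphorylation by Lck (1/min)}
#'   \item{k_itam_dp}{per-site ITAM tyrosine dephosphorylation (1/min)}
#'   \item{k_on}{pseudo-first-order ZAP70 binding to a doubly phosphorylated
#'     ITAM (1/min)}
#'   \item{k_off}{ZAP70 unbinding (1/min)}
#'   \item{k_y319}{ZAP70 Y319 phosphorylation by Lck (1/min)}
#'   \item{k_y319_dp}{Y319 dephosphorylation (1/min)}
#'   \item{k_y493}{Y493 trans-autophosphorylation, active only when the
#'     opposing ITAM carries an opened (pY319) ZAP70 (1/min)}
#'   \item{k_y493_dp}{Y493 dephosphorylation (1/min)}
#'   \item{f_min}{residual phosphatase activity fraction right after an
#'     inhibitor dose, in (0, 1]}
#'   \item{tau_rec}{phosphatase-activity recovery time constant (min)}
#'   \item{s_Z, s_pY}{scale factors mapping the bound-ZAP70 and bound-pY319
#'     model observables to arbitrary fluorescence-ratio units}
#' }
#'
#' @slot rates named numeric vector holding the twelve parameters.
#' @seealso [rateParameters()], [simulateTimecourse()]
#' @exportClass RateParameters
setClass("RateParameters", representation(rates = "numeric"))

.RATE_NAMES <- c("k_itam_p", "k_itam_dp", "k_on", "k_off",
                 "k_y319", "k_y319_dp", "k_y493", "k_y493_dp",
                 "f_min", "tau_rec", "s_Z", "s_pY")

setValidity("RateParameters", function(object) {
  r <- object@rates
  msgs <- character(0)
  if (!identical(sort(names(r)), sort(.RATE_NAMES)))
    msgs <- c(msgs, paste("rates must be named exactly:",
                          paste(.RATE_NAMES, collapse = ", ")))
  else {
    if (any(!is.finite(r))) msgs <- c(msgs, "all rates must be finite")
    kin <- setdiff(.RATE_NAMES, c("f_min", "tau_rec", "s_Z", "s_pY"))
    if (any(r[kin] < 0)) msgs <- c(msgs, "rate constants must be >= 0")
    if (!is.na(r["f_min"]) && (r["f_min"] <= 0 || r["f_min"] > 1))
      msgs <- c(msgs, "'f_min' must lie in (0, 1]")
    if (!is.na(r["tau_rec"]) && r["tau_rec"] <= 0)
      msgs <- c(msgs, "'tau_rec' must be > 0")
    if (any(r[c("s_Z", "s_pY")] <= 0))
      msgs <- c(msgs, "observable scales must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RateParameters object
#'
#' Defaults reproduce the qualitative kinetics of phosphatase-inhibitor
#' stimulation of the TCR-CD3--ZAP70 module: a low resting phosphorylation
#' level, rapid recruitment of unphosphorylated ZAP70 after the dose (bound
#' ZAP70 peaking near 10 min), slower Y319 phosphorylation (peaking near
#' 20 min) producing an early dip of the bound pY319/ZAP70 ratio, and a
#' delayed Y493 phosphorylation wave.  See the package vignette for how the
#' defaults were chosen.
#'
#' @param k_itam_p,k_itam_dp,k_on,k_off,k_y319,k_y319_dp,k_y493,k_y493_dp
#'   first-order rate constants (1/min); see [RateParameters-class].
#' @param f_min residual phosphatase activity immediately after a dose.
#' @param tau_rec phosphatase recovery time constant (min).
#' @param s_Z,s_pY observable scale factors (arbitrary units).
#' @return A [RateParameters-class] object.
#' @examples
#' p <- rateParameters()
#' rateValues(p)[c("k_on", "f_min")]
#' @export
rateParameters <- function(k_itam_p = 0.8, k_itam_dp = 60,
                           k_on = 6, k_off = 0.1,
                           k_y319 = 0.04, k_y319_dp = 0.4,
                           k_y493 = 0.02, k_y493_dp = 0.3,
                           f_min = 0.02, tau_rec = 200,
                           s_Z = 1, s_pY = 1) {
  rates <- c(k_itam_p = k_itam_p, k_itam_dp = k_itam_dp, k_on = k_on,
             k_off = k_off, k_y319 = k_y319, k_y319_dp = k_y319_dp,
             k_y493 = k_y493, k_y493_dp = k_y493_dp, f_min = f_min,
             tau_rec = tau_rec, s_Z = s_Z, s_pY = s_pY)
  new("RateParameters", rates = rates)
}

#' StimulationSchedule: phosphatase-inhibitor dosing schedule
#'
#' @slot doseTimes minutes at which the inhibitor is applied (strictly
#'   increasing, non-negative; empty for an unstimulated run).
#' @slot horizon simulation horizon in minutes.
#' @exportClass StimulationSchedule
setClass("StimulationSchedule",
  representation(doseTimes = "numeric", horizon = "numeric"),
  prototype(doseTimes = 0, horizon = 60)
)

setValidity("StimulationSchedule", function(object) {
  msgs <- character(0)
  d <- object@doseTimes
  if (length(d) && (any(d < 0) || is.unsorted(d, strictly = TRUE)))
    msgs <- c(msgs, "'doseTimes' must be non-negative and strictly increasing")
  if (length(object@horizon) != 1L || object@horizon <= 0)
    msgs <- c(msgs, "'horizon' must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a StimulationSchedule
#'
#' @param doseTimes minutes at which the phosphatase inhibitor is applied.
#' @param horizon simulation horizon in minutes.
#' @return A [StimulationSchedule-class] object.
#' @examples
#' stimulationSchedule(c(0, 20), horizon = 60)  # double-dose protocol
#' @export
stimulationSchedule <- function(doseTimes = 0, horizon = 60) {
  new("StimulationSchedule", doseTimes = as.numeric(doseTimes),
      horizon = as.numeric(horizon))
}

#' PairStateTrajectory: time course of the 28 pair-state occupancies
#'
#' @slot times time points in minutes.
#' @slot states matrix (time x 28) of occupancy fractions; each row sums to 1
#'   within solver tolerance and column names are the canonical pair-state
#'   labels from [enumeratePairStates()].
#' @slot parameters the [RateParameters-class] used for the simulation.
#' @slot schedule the [StimulationSchedule-class] used.
#' @exportClass PairStateTrajectory
setClass("PairStateTrajectory",
  representation(times = "numeric", states = "matrix",
                 parameters = "RateParameters",
                 schedule = "StimulationSchedule")
)

setValidity("PairStateTrajectory", function(object) {
  msgs <- character(0)
  if (nrow(object@states) != length(object@times))
    msgs <- c(msgs, "one state row per time point required")
  if (ncol(object@states) != 28L)
    msgs <- c(msgs, "state matrix must have 28 columns")
  if (nrow(object@states)) {
    if (any(object@states < -1e-6))
      msgs <- c(msgs, "occupancies must be non-negative (within tolerance)")
    if (any(abs(rowSums(object@states) - 1) > 1e-6))
      msgs <- c(msgs, "occupancies must sum to 1 (within tolerance)")
  }
  if (length(msgs)) msgs else TRUE
})

#' TimeCourseDataset: timed observations with replicate structure
#'
#' Long-format observations of model observables (or their experimental
#' counterparts) in arbitrary fluorescence-ratio units, optionally carrying
#' the ground-truth parameters that generated them.
#'
#' @slot observations data.frame with columns \code{time_min},
#'   \code{observable}, \code{replicate}, \code{value}.
#' @slot truth list with elements \code{parameters}
#'   ([RateParameters-class]) and \code{schedule} when the data are
#'   synthetic; empty otherwise.
#' @exportClass TimeCourseDataset
setClass("TimeCourseDataset",
  representation(observations = "data.frame", truth = "list"),
  prototype(observations = data.frame(time_min = numeric(0),
                                      observable = character(0),
                                      replicate = integer(0),
                                      value = numeric(0)),
            truth = list())
)

setValidity("TimeCourseDataset", function(object) {
  obs <- object@observations
  need <- c("time_min", "observable", "replicate", "value")
  msgs <- character(0)
  if (!all(need %in% names(obs)))
    msgs <- c(msgs, paste("observations need columns:",
                          paste(need, collapse = ", ")))
  else if (nrow(obs)) {
    if (any(obs$time_min < 0)) msgs <- c(msgs, "times must be non-negative")
    if (any(obs$value < 0)) msgs <- c(msgs, "values must be >= 0")
    if (length(unique(obs$time_min)) < 2L)
      msgs <- c(msgs, "at least two distinct time points are required")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TimeCourseDataset
#'
#' @param observations data.frame with columns \code{time_min},
#'   \code{observable}, \code{replicate}, \code{value}.
#' @param truth optional list of ground-truth \code{parameters} and
#'   \code{schedule} for synthetic data.
#' @return A [TimeCourseDataset-class] object.
#' @export
timeCourseDataset <- function(observations, truth = list()) {
  new("TimeCourseDataset", observations = as.data.frame(observations),
      truth = truth)
}

#' FitResult: outcome of a simulated-annealing least-squares fit
#'
#' @slot parameters best-ever [RateParameters-class] found.
#' @slot rss residual sum of squares at the best parameters.
#' @slot trace data.frame of the annealing trace (iteration, temperature,
#'   accepted objective, best objective).
#' @slot seed RNG seed used for the stochastic search.
#' @slot bounds list with \code{lower}/\code{upper} named bounds (linear
#'   scale) for the fitted parameters.
#' @slot fitted names of the parameters that were searched.
#' @exportClass FitResult
setClass("FitResult",
  representation(parameters = "RateParameters", rss = "numeric",
                 trace = "data.frame", seed = "integer", bounds = "list",
                 fitted = "character")
)
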