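#' Number of events in a bead event table
#' @param object a [BeadEventTable-class].
#' @return integer event count.
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname nEvents
#' @export
setMethod("nEvents", "BeadEventTable", function(object) nrow(object@events))

#' Fluorescence channel names
#' @param object a [BeadEventTable-class].
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "BeadEventTable", function(object) object@channels)

#' Per-event data as a data.frame
#' @param object a [BeadEventTable-class].
#' @return data.frame with fsc, ssc and channel columns.
#' @export
setGeneric("eventData", function(object) standardGeneric("eventData"))

#' @rdname eventData
#' @export
setMethod("eventData", "BeadEventTable", function(object) object@events)

#' Hidden ground-truth population labels (synthetic mixtures)
#' @param object a [BeadEventTable-class].
#' @return character vector, empty when the table carries no labels.
#' @export
setGeneric("beadLabels", function(object) standardGeneric("beadLabels"))

#' @rdname beadLabels
#' @export
setMethod("beadLabels", "BeadEventTable", function(object) object@labels)

#' Sample metadata
#' @param object a [BeadEventTable-class].
#' @return named list.
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))

#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "BeadEventTable", function(object) object@meta)

#' Net background-subtracted geometric MFI
#' @param object an [MFIResult-class].
#' @return numeric net MFI (floored at zero).
#' @export
setGeneric("netMFI", function(object) standardGeneric("netMFI"))

#' @rdname netMFI
#' @export
setMethod("netMFI", "MFIResult", function(object) object@netMFI)

#' Molecules per bead
#' @param object a [MoleculeCount-class].
#' @return numeric molecule count.
#' @export
setGeneric("molecules", function(object) standardGeneric("molecules"))

#' @rdname molecules
#' @export
setMethod("molecules", "MoleculeCount", function(object) object@molecules)

#' Named rate-parameter vector
#' @param object a [RateParameters-class] or [FitResult-class].
#' @return named numeric vector of the twelve model parameters.
#' @export
setGeneric("rateValues", function(object) standardGeneric("rateValues"))

#' @rdname rateValues
#' @export
setMethod("rateValues", "RateParameters", function(object) object@rates)

#' @rdname rateValues
#' @export
setMethod("rateValues", "FitResult", function(object) object@parameters@rates)

#' State-occupancy matrix of a trajectory
#' @param object a [PairStateTrajectory-class].
#' @return matrix (time x 28) of occupancy fractions.
#' @export
setGeneric("stateOccupancies",
           function(object) standardGeneric("stateOccupancies"))

#' @rdname stateOccupancies
#' @export
setMethod("stateOccupancies", "PairStateTrajectory",
          function(object) object@states)

#' Observation table of a time-course dataset
#' @param object a [TimeCourseDataset-class].
#' @return data.frame (time_min, observable, replicate, value).
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))

#' @rdname observations
#' @export
setMethod("observations", "TimeCourseDataset",
          function(object) object@observations)

#' Ground truth of a synthetic time-course dataset
#' @param object a [TimeCourseDataset-class].
#' @return list with parameters and schedule, or empty list.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "TimeCourseDataset", function(object) object@truth)

#' Best parameters of a fit
#' @param object a [FitResult-class].
#' @return a [RateParameters-class] object.
#' @export
setGeneric("bestParameters",
           function(object) standardGeneric("bestParameters"))

#' @rdname bestParameters
#' @export
setMethod("bestParameters", "FitResult", function(object) object@parameters)

#' Annealing trace of a fit
#' @param object a [FitResult-class].
#' @return data.frame (iteration, temperature, accepted, best).
#' @export
setGeneric("fitTrace", function(object) standardGeneric("fitTrace"))

#' @rdname fitTrace
#' @export
setMethod("fitTrace", "FitResult", function(object) object@trace)

setMethod("show", "BeadEventTable", function(object) {
  cat("BeadEventTable with", nrow(object@events), "events and",
      length(object@channels), "channel(s):",
      paste(object@channels, collapse = ", "), "\n")
  if (length(object@labels))
    cat("  ground-truth labels:",
        paste(names(table(object@labels)), table(object@labels),
              sep = "=", collapse = ", "), "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "MFIResult", function(object) {
  cat(sprintf(
    "MFIResult [%s]: geoMFI %.4g (n=%d, dropped=%d), background %.4g, net %.4g%s\n",
    object@channel, object@geometricMFI, object@nEvents,
    object@droppedEvents, object@backgroundMFI, object@netMFI,
    if (object@floored) " (floored)" else ""))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: log10(molecules) = %.4f * log10(MFI) + %.4f  (r = %.5f, n = %d)\n",
    object@slope, object@intercept, object@r, object@nPoints))
})

setMethod("show", "MoleculeCount", function(object) {
  cat(sprintf("MoleculeCount: %.4g +/- %s\n", object@molecules,
              if (is.na(object@sem)) "NA" else sprintf("%.3g", object@sem)))
})

setMethod("show", "RateParameters", function(object) {
  cat("RateParameters (per minute unless noted):\n")
  print(signif(object@rates, 4))
})

setMethod("show", "StimulationSchedule", function(object) {
  cat("StimulationSchedule: doses at {",
      paste(object@doseTimes, collapse = ", "),
      "} min, horizon", object@horizon, "min\n")
})

setMethod("show", "PairStateTrajectory", function(object) {
  cat("PairStateTrajectory:", length(object@times), "time points over [",
      min(object@times), ",", max(object@times), "] min; 28 pair states\n")
})

setMethod("show", "TimeCourseDataset", function(object) {
  obs <- object@observations
  cat("TimeCourseDataset:", nrow(obs), "observations;",
      length(unique(obs$time_min)), "time points;",
      "observables:", paste(unique(obs$observable), collapse = ", "), "\n")
  if (length(object@truth)) cat("  carries synthetic ground truth\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: RSS %.6g after %d trace steps (seed %d)\n",
              object@rss, nrow(object@trace), object@seed))
  cat("  fitted:", paste(object@fitted, collapse = ", "), "\n")
})
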