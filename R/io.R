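# Plain-text input/output: CSV event tables, CSV time-course tables with a
# YAML ground-truth sidecar.

#' Write / read a bead event table as CSV
#'
#' One row per event, header = \code{fsc}, \code{ssc} and the channel names;
#' a \code{label} column is appended when the table carries ground-truth
#' population labels.
#'
#' @param events a [BeadEventTable-class].
#' @param path output CSV path.
#' @return \code{writeBeadEventsCSV} returns \code{path} invisibly;
#'   \code{readBeadEventsCSV} returns a [BeadEventTable-class].
#' @export
writeBeadEventsCSV <- function(events, path) {
  stopifnot(is(events, "BeadEventTable"))
  df <- events@events
  if (length(events@labels)) df$label <- events@labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBeadEventsCSV
#' @export
readBeadEventsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(df)) as.character(df$label)
            else character(0)
  df$label <- NULL
  beadEventTable(df, meta = list(source = path), labels = labels)
}

#' Write / read a time-course dataset as CSV with a YAML sidecar
#'
#' The observations go to \code{path} as
#' \code{time_min, observable, replicate, value}; when the dataset carries
#' synthetic ground truth, the generating parameters, schedule and noise
#' settings are written to \code{<path>.yaml}.
#'
#' @param dataset a [TimeCourseDataset-class].
#' @param path output CSV path.
#' @return \code{writeTimeCourseCSV} returns \code{path} invisibly;
#'   \code{readTimeCourseCSV} returns a [TimeCourseDataset-class]
#'   (re-attaching the sidecar ground truth when present).
#' @export
writeTimeCourseCSV <- function(dataset, path) {
  stopifnot(is(dataset, "TimeCourseDataset"))
  utils::write.csv(observations(dataset), path, row.names = FALSE)
  truth <- groundTruth(dataset)
  if (length(truth)) {
    side <- list(
      parameters = as.list(rateValues(truth$parameters)),
      dose_times_min = as.numeric(truth$schedule@doseTimes),
      horizon_min = truth$schedule@horizon,
      noise_cv_percent = truth$noiseCVPercent,
      replicate_count = truth$replicateCount,
      seed = truth$seed)
    yaml::write_yaml(side, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname writeTimeCourseCSV
#' @export
readTimeCourseCSV <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  truth <- list()
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    side <- yaml::read_yaml(sidecar)
    pars <- unlist(side$parameters)
    truth <- list(
      parameters = new("RateParameters", rates = pars[.RATE_NAMES]),
      schedule = stimulationSchedule(as.numeric(side$dose_times_min),
                                     horizon = side$horizon_min),
      noiseCVPercent = side$noise_cv_percent,
      replicateCount = side$replicate_count,
      seed = side$seed)
  }
  timeCourseDataset(obs, truth = truth)
}
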