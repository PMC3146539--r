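# Bead-level quantification: scatter gating, geometric MFI, background
# subtraction, channel ratios and replicate statistics.

#' Gate events by rectangular scatter intervals
#'
#' Retains events whose forward and side scatter fall inside the closed
#' intervals of the gate.  The fraction of events retained is recorded in
#' the output metadata; if fewer than \code{gate@minEvents} events survive,
#' gating fails with an explicit low-count error.
#'
#' @param events a non-empty [BeadEventTable-class].
#' @param gate a [GateSpec-class].
#' @return A gated [BeadEventTable-class].
#' @examples
#' tbl <- genBeadEvents(beadPopulationSpec(200, channelGeoMeans = c(PE = 100)))
#' g <- gateSpec(minEvents = 100)
#' nEvents(gateEvents(tbl, g))
#' @export
gateEvents <- function(events, gate) {
  stopifnot(is(events, "BeadEventTable"), is(gate, "GateSpec"))
  ev <- events@events
  if (!nrow(ev)) stop("'events' must be non-empty")
  keep <- ev$fsc >= gate@fscRange[1] & ev$fsc <= gate@fscRange[2] &
          ev$ssc >= gate@sscRange[1] & ev$ssc <= gate@sscRange[2]
  n <- sum(keep)
  if (n == 0L)
    stop("low event count after gating: 0 retained (gate excludes all events)")
  if (n < gate@minEvents)
    stop(sprintf("low event count after gating: %d retained < %d required",
                 n, as.integer(gate@minEvents)))
  meta <- events@meta
  meta$fractionRetained <- n / nrow(ev)
  labels <- if (length(events@labels)) events@labels[keep] else character(0)
  beadEventTable(ev[keep, , drop = FALSE], channels = events@channels,
                 labels = labels, meta = meta)
}

#' Geometric mean fluorescence intensity of one channel
#'
#' Computes \code{exp(mean(log(values)))} over the gated events of one
#' channel.  Non-positive intensities (acquisition floor artifacts) are
#' dropped before the log; the number dropped is attached as the
#' \code{"droppedEvents"} attribute.  An error is raised if no positive
#' events remain.
#'
#' @param events a [BeadEventTable-class].
#' @param channel channel name.
#' @return Geometric MFI (numeric) with attribute \code{droppedEvents}.
#' @examples
#' tbl <- beadEventTable(data.frame(fsc = 1:2, ssc = 1:2, PE = c(10, 1000)))
#' geometricMFI(tbl, "PE")  # sqrt(10 * 1000) = 100
#' @export
geometricMFI <- function(events, channel) {
  stopifnot(is(events, "BeadEventTable"))
  if (!channel %in% events@channels)
    stop(sprintf("channel '%s' not present", channel))
  v <- events@events[[channel]]
  if (!length(v)) stop("empty input: no events")
  pos <- v > 0
  dropped <- sum(!pos)
  v <- v[pos]
  if (!length(v))
    stop(sprintf("no positive events on channel '%s' after zero handling",
                 channel))
  structure(exp(mean(log(v))), droppedEvents = dropped)
}

#' Subtract a background MFI from a sample MFI
#'
#' Net signal is \code{max(sample - control, 0)}; whether the result was
#' floored at zero is recorded in the \code{"floored"} attribute rather than
#' raised as an error (a control brighter than the sample is a legitimate
#' below-detection observation).
#'
#' @param sampleMFI,controlMFI geometric MFIs (>= 0).
#' @return Net MFI with attribute \code{floored}.
#' @examples
#' subtractBackground(120, 20)  # 100
#' subtractBackground(15, 20)   # 0, floored
#' @export
subtractBackground <- function(sampleMFI, controlMFI) {
  if (sampleMFI < 0 || controlMFI < 0)
    stop("MFIs must be non-negative")
  net <- sampleMFI - controlMFI
  structure(max(net, 0), floored = net < 0)
}

#' Summarise one channel of a gated sample as an MFIResult
#'
#' Convenience constructor combining [geometricMFI()] on the sample with
#' background subtraction against a matched control population (uncoupled
#' beads stained identically).
#'
#' @param events gated sample [BeadEventTable-class].
#' @param channel channel name.
#' @param control either a control [BeadEventTable-class] measured on the
#'   same channel or a precomputed background MFI (numeric); 0 for no
#'   background.
#' @return An [MFIResult-class].
#' @export
mfiResult <- function(events, channel, control = 0) {
  g <- geometricMFI(events, channel)
  bg <- if (is(control, "BeadEventTable"))
    as.numeric(geometricMFI(control, channel)) else as.numeric(control)
  net <- subtractBackground(as.numeric(g), bg)
  new("MFIResult", channel = channel, geometricMFI = as.numeric(g),
      nEvents = nEvents(events) - attr(g, "droppedEvents"),
      droppedEvents = attr(g, "droppedEvents"),
      backgroundMFI = bg, netMFI = as.numeric(net),
      floored = attr(net, "floored"))
}

#' Ratio of two background-subtracted channel MFIs
#'
#' The assay's normalised readout: the ratio of two net geometric MFIs
#' (e.g. bound ZAP70 normalised by captured CD3e), dimensionless arbitrary
#' units.
#'
#' @param numerator,denominator [MFIResult-class] objects (or plain net MFI
#'   values).
#' @return Numeric ratio.
#' @examples
#' channelRatio(50, 200)  # 0.25
#' @export
channelRatio <- function(numerator, denominator) {
  num <- if (is(numerator, "MFIResult")) numerator@netMFI
         else as.numeric(numerator)
  den <- if (is(denominator, "MFIResult")) denominator@netMFI
         else as.numeric(denominator)
  if (is.na(den) || den <= 0) {
    who <- if (is(denominator, "MFIResult")) denominator@channel else "value"
    stop(sprintf("undefined ratio: denominator net MFI (%s) is not > 0", who))
  }
  num / den
}

#' Replicate statistics: mean, s.e.m. and percent coefficient of variation
#'
#' Uses the n-1 sample standard deviation; \code{sem = sd / sqrt(n)} and
#' \code{percent_cv = 100 * sd / mean}.
#'
#' @param values numeric replicate values (n >= 2).
#' @return List with \code{mean}, \code{sd}, \code{sem}, \code{percent_cv}
#'   and \code{n}.
#' @examples
#' replicateStats(c(90, 100, 110))  # mean 100, %cv 10
#' @export
replicateStats <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("at least two replicates are required")
  m <- mean(values)
  if (m == 0) stop("percent cv undefined: replicate mean is zero")
  s <- stats::sd(values)
  list(mean = m, sd = s, sem = s / sqrt(n), percent_cv = 100 * s / m, n = n)
}
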