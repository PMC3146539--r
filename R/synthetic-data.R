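# Synthetic-data generators: every input the quantification and modelling
# pipeline consumes, with known ground truth.  All randomness routes through
# explicit seeds; for a fixed seed the output tables are identical across
# runs.

#' Specification of one synthetic bead population
#'
#' Bead fluorescence is modelled as an additive superposition, on the linear
#' scale, of an autofluorescent background draw and a stain signal draw, both
#' lognormal.  Scatter is bivariate normal around \code{scatterCenter}.
#'
#' @param nEvents number of events (>= 1, or 0 for an empty component of a
#'   mixture).
#' @param scatterCenter length-2 vector \code{c(fsc, ssc)} in arbitrary
#'   units.
#' @param scatterCV coefficient of variation of the scatter (fraction).
#' @param channelGeoMeans named numeric vector: signal geometric mean per
#'   fluorescence channel (> 0).
#' @param channelGeoCV geometric coefficient of variation of the signal
#'   (fraction, > 0).
#' @param backgroundGeoMean autofluorescence geometric mean per channel
#'   (> 0); use a very small value to emulate negligible background.
#' @param seed integer seed.
#' @return A validated list of class \code{"BeadPopulationSpec"}.
#' @examples
#' beadPopulationSpec(1000, channelGeoMeans = c(PE = 500))
#' @export
beadPopulationSpec <- function(nEvents, scatterCenter = c(200, 150),
                               scatterCV = 0.05,
                               channelGeoMeans, channelGeoCV = 0.35,
                               backgroundGeoMean = 5, seed = 1L) {
  if (nEvents < 0) stop("'nEvents' must be >= 0")
  if (is.null(names(channelGeoMeans)) || any(!nzchar(names(channelGeoMeans))))
    stop("'channelGeoMeans' must be a named vector")
  if (any(channelGeoMeans <= 0))
    stop("all channel geometric means must be > 0")
  if (channelGeoCV < 0) stop("'channelGeoCV' must be >= 0")
  if (any(backgroundGeoMean < 0))
    stop("'backgroundGeoMean' must be >= 0 (0 = no autofluorescence)")
  if (length(scatterCenter) != 2L || any(scatterCenter <= 0))
    stop("'scatterCenter' must be c(fsc, ssc) with positive entries")
  structure(list(nEvents = as.integer(nEvents),
                 scatterCenter = as.numeric(scatterCenter),
                 scatterCV = scatterCV,
                 channelGeoMeans = channelGeoMeans,
                 channelGeoCV = channelGeoCV,
                 backgroundGeoMean = backgroundGeoMean,
                 seed = as.integer(seed)),
            class = "BeadPopulationSpec")
}

.drawPopulation <- function(spec) {
  n <- spec$nEvents
  channels <- names(spec$channelGeoMeans)
  sSig <- sdlogFromCV(spec$channelGeoCV)
  ev <- data.frame(
    fsc = stats::rnorm(n, spec$scatterCenter[1],
                       spec$scatterCV * spec$scatterCenter[1]),
    ssc = stats::rnorm(n, spec$scatterCenter[2],
                       spec$scatterCV * spec$scatterCenter[2])
  )
  bg <- spec$backgroundGeoMean
  if (length(bg) == 1L) bg <- stats::setNames(rep(bg, length(channels)),
                                              channels)
  for (ch in channels) {
    signal <- rlnormGeo(n, spec$channelGeoMeans[[ch]], sSig)
    background <- if (bg[[ch]] > 0) rlnormGeo(n, bg[[ch]], sSig) else 0
    ev[[ch]] <- background + signal
  }
  ev
}

#' Generate a single synthetic bead population
#'
#' Draws \code{nEvents} events whose per-channel fluorescence is the sum of a
#' lognormal autofluorescent background and a lognormal stain signal with the
#' specified geometric mean and geometric CV.  In the degenerate limit
#' \code{channelGeoCV -> 0} every event equals its geometric mean.
#'
#' @param spec a [beadPopulationSpec()].
#' @return A [BeadEventTable-class].
#' @examples
#' tbl <- genBeadEvents(beadPopulationSpec(500, channelGeoMeans = c(PE = 500),
#'                                         backgroundGeoMean = 0, seed = 7))
#' geometricMFI(tbl, "PE")
#' @export
genBeadEvents <- function(spec) {
  stopifnot(inherits(spec, "BeadPopulationSpec"))
  if (spec$nEvents < 1L) stop("'nEvents' must be >= 1")
  ev <- withSeed(spec$seed, .drawPopulation(spec))
  beadEventTable(ev, channels = names(spec$channelGeoMeans),
                 meta = list(spec = spec))
}

#' Generate a two-plex bead-size mixture with ground-truth labels
#'
#' Emulates a two-plex assay in which two bead sizes (e.g. 3 um and 10 um)
#' are mixed before capture and separated afterwards by scatter gating.  The
#' output carries hidden per-event population labels (\code{"small"},
#' \code{"large"}) for gate-accuracy tests.  If the two scatter centres are
#' closer than four combined scatter standard deviations along FSC, a
#' separation warning is recorded in the output metadata.
#'
#' @param specSmall,specLarge [beadPopulationSpec()]s for the two bead sizes
#'   (their seeds are taken from \code{specSmall}).
#' @return A [BeadEventTable-class] with labels.
#' @export
genTwoPlexEvents <- function(specSmall, specLarge) {
  stopifnot(inherits(specSmall, "BeadPopulationSpec"),
            inherits(specLarge, "BeadPopulationSpec"))
  meta <- list()
  sdS <- specSmall$scatterCV * specSmall$scatterCenter[1]
  sdL <- specLarge$scatterCV * specLarge$scatterCenter[1]
  sep <- abs(specLarge$scatterCenter[1] - specSmall$scatterCenter[1])
  if (sep <= 4 * (sdS + sdL))
    meta$separationWarning <- sprintf(
      "scatter populations overlap: separation %.3g <= 4 * combined sd %.3g",
      sep, sdS + sdL)
  parts <- withSeed(specSmall$seed, {
    small <- if (specSmall$nEvents > 0) .drawPopulation(specSmall) else NULL
    large <- if (specLarge$nEvents > 0) .drawPopulation(specLarge) else NULL
    list(small = small, large = large)
  })
  chans <- union(names(specSmall$channelGeoMeans),
                 names(specLarge$channelGeoMeans))
  fill <- function(df) {
    for (ch in setdiff(chans, names(df))) df[[ch]] <- 0
    df[, c("fsc", "ssc", chans), drop = FALSE]
  }
  evs <- list(); labels <- character(0)
  if (!is.null(parts$small)) {
    evs <- c(evs, list(fill(parts$small)))
    labels <- c(labels, rep("small", nrow(parts$small)))
  }
  if (!is.null(parts$large)) {
    evs <- c(evs, list(fill(parts$large)))
    labels <- c(labels, rep("large", nrow(parts$large)))
  }
  if (!length(evs)) stop("both populations are empty")
  beadEventTable(do.call(rbind, evs), channels = chans,
                 labels = labels, meta = meta)
}

#' Generate a synthetic PE calibration-bead ladder
#'
#' Emulates a calibration bead set carrying known numbers of PE fluorophores
#' per bead (default ladder 515, 5956, 26653 and 69045 molecules).  Each rung
#' is a lognormal fluorescence population with geometric mean \code{gain *
#' molecules}; population labels name the nominal molecule count.
#'
#' @param moleculesPerBead nominal PE molecules per bead for each rung.
#' @param gain MFI units per molecule (> 0).
#' @param nPerPopulation events per rung.
#' @param sigma lognormal spread (sdlog) of each rung; 0 gives exact
#'   populations.
#' @param seed integer seed.
#' @return A [BeadEventTable-class] with one \code{"PE"} channel and rung
#'   labels.
#' @examples
#' ladder <- genQuantibriteSet(seed = 11)
#' table(beadLabels(ladder))
#' @export
genQuantibriteSet <- function(moleculesPerBead = c(515, 5956, 26653, 69045),
                              gain = 1, nPerPopulation = 2000,
                              sigma = 0.3, seed = 1L) {
  if (!length(moleculesPerBead)) stop("ladder must contain at least one rung")
  if (any(moleculesPerBead <= 0)) stop("all molecule counts must be > 0")
  if (gain <= 0) stop("'gain' must be > 0")
  if (nPerPopulation < 1) stop("'nPerPopulation' must be >= 1")
  ev <- withSeed(seed, {
    do.call(rbind, lapply(moleculesPerBead, function(m) {
      data.frame(
        fsc = stats::rnorm(nPerPopulation, 200, 10),
        ssc = stats::rnorm(nPerPopulation, 150, 8),
        PE = rlnormGeo(nPerPopulation, gain * m, sigma),
        label = as.character(m)
      )
    }))
  })
  beadEventTable(ev[, c("fsc", "ssc", "PE")], channels = "PE",
                 labels = ev$label,
                 meta = list(moleculesPerBead = moleculesPerBead,
                             gain = gain, sigma = sigma))
}

#' Generate a noisy synthetic kinetic dataset from the pair model
#'
#' Simulates the ITAM-pair model at the requested times, maps the trajectory
#' to the scaled \code{bound_Z} and \code{bound_pY319} observables, and
#' applies independent multiplicative lognormal replicate noise of the stated
#' percent coefficient of variation.  The default noise level of 5\% and the
#' triplicate design match the replicate precision of the bead immunoassay
#' the generator emulates (replicate \%cv in the 4--7 range).  Ground-truth
#' parameters are stored alongside the observations.
#'
#' @param trueParams a [RateParameters-class] used as ground truth.
#' @param schedule a [StimulationSchedule-class].
#' @param times observation times in minutes (default the assay's
#'   0/2/5/10/20/60 grid).
#' @param replicateCount replicates per time point (default 3).
#' @param noiseCVPercent multiplicative noise \%cv per observation
#'   (default 5).
#' @param seed integer seed.
#' @return A [TimeCourseDataset-class] carrying the ground truth.
#' @examples
#' ds <- genKineticDataset(rateParameters(), stimulationSchedule(0), seed = 3)
#' head(observations(ds))
#' @export
genKineticDataset <- function(trueParams,
                              schedule = stimulationSchedule(0),
                              times = c(0, 2, 5, 10, 20, 60),
                              replicateCount = 3,
                              noiseCVPercent = 5,
                              seed = 1L) {
  stopifnot(is(trueParams, "RateParameters"))
  if (any(times < 0)) stop("'times' must be non-negative")
  if (replicateCount < 1) stop("'replicateCount' must be >= 1")
  if (noiseCVPercent < 0) stop("'noiseCVPercent' must be >= 0")
  traj <- simulateTimecourse(trueParams, schedule, sort(unique(times)))
  obs <- computeObservables(traj)
  long <- do.call(rbind, lapply(c("bound_Z", "bound_pY319"), function(o) {
    do.call(rbind, lapply(seq_len(replicateCount), function(r) {
      data.frame(time_min = obs$time_min, observable = o, replicate = r,
                 value = obs[[o]], stringsAsFactors = FALSE)
    }))
  }))
  long$value <- pmax(long$value, 0) * withSeed(seed,
    lnormNoiseFactors(nrow(long), noiseCVPercent))
  rownames(long) <- NULL
  timeCourseDataset(long,
    truth = list(parameters = trueParams, schedule = schedule,
                 noiseCVPercent = noiseCVPercent,
                 replicateCount = replicateCount, seed = seed))
}
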