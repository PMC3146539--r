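# Absolute quantification: calibration against a PE bead ladder of known
# fluorophore content, conversion of net MFIs to molecules per bead, and
# per-receptor stoichiometries.

#' Fit a log-log standard curve from a calibration ladder
#'
#' Ordinary least squares of log10(molecules per bead) on log10(MFI),
#' matching the orientation in which the curve is used (predicting molecule
#' counts from measured MFIs).  On an exact power-law ladder the correlation
#' coefficient is 1 to machine precision.
#'
#' @param ladderMFIs geometric MFIs of the ladder rungs (> 0).
#' @param ladderMolecules nominal molecules per bead per rung (> 0), same
#'   length.
#' @return A [CalibrationCurve-class].
#' @examples
#' ladder <- c(515, 5956, 26653, 69045)
#' fitStandardCurve(0.1 * ladder, ladder)  # slope 1, intercept 1, r = 1
#' @export
fitStandardCurve <- function(ladderMFIs, ladderMolecules) {
  if (length(ladderMFIs) != length(ladderMolecules))
    stop("ladder MFIs and molecule counts must have equal length")
  if (length(ladderMFIs) < 2L)
    stop("at least two ladder points are required")
  if (any(ladderMFIs <= 0) || any(ladderMolecules <= 0))
    stop("all ladder values must be > 0")
  x <- log10(ladderMFIs); y <- log10(ladderMolecules)
  if (stats::sd(x) == 0)
    stop("degenerate fit: identical MFI values across rungs")
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  new("CalibrationCurve",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = r, nPoints = length(x))
}

#' Convert a net MFI to absolute molecules per bead
#'
#' Applies the calibration curve,
#' \code{molecules = 10^(slope * log10(netMFI) + intercept)}, then divides by
#' the antibody labelling efficiency (fluorophores per antibody; 1 for the
#' one-PE-per-antibody conjugates the assay assumes).
#'
#' @param curve a [CalibrationCurve-class].
#' @param netMFI background-subtracted geometric MFI (> 0); vectorised.
#' @param labellingEfficiency fluorophores per antibody (> 0, default 1).
#' @return Numeric molecules per bead (same length as \code{netMFI}).
#' @examples
#' curve <- fitStandardCurve(c(515, 5956, 26653, 69045),
#'                           c(515, 5956, 26653, 69045))
#' mfiToMolecules(curve, 515)  # identity curve: 515 molecules
#' @export
mfiToMolecules <- function(curve, netMFI, labellingEfficiency = 1) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(netMFI <= 0))
    stop("cannot calibrate a non-positive net MFI")
  if (labellingEfficiency <= 0)
    stop("'labellingEfficiency' must be > 0")
  10^(curve@slope * log10(netMFI) + curve@intercept) / labellingEfficiency
}

.asCount <- function(x) {
  if (is(x, "MoleculeCount")) x else moleculeCount(as.numeric(x))
}

#' Molecules of a target protein per receptor complex
#'
#' Converts per-bead molecule counts into a per-complex stoichiometry using
#' a reference subunit of known copy number: with two CD3e subunits per
#' TCR-CD3 complex, \code{complexes = CD3e / 2} and the stoichiometry is
#' \code{target / complexes}.  Standard errors, when present on both counts,
#' are propagated by the first-order delta method.
#'
#' @param target [MoleculeCount-class] (or numeric) of the target protein.
#' @param referenceSubunit [MoleculeCount-class] (or numeric) of the
#'   reference subunit (> 0).
#' @param copiesPerComplex integer copies of the reference subunit per
#'   complex (>= 1, default 2).
#' @return A [MoleculeCount-class] whose \code{molecules} slot holds the
#'   dimensionless per-complex stoichiometry.
#' @examples
#' molecules(moleculesPerComplex(5300, 16000))   # 0.6625 ZAP70 per TCR-CD3
#' molecules(moleculesPerComplex(220, 16000))    # 0.0275 pY319 per TCR-CD3
#' @export
moleculesPerComplex <- function(target, referenceSubunit,
                                copiesPerComplex = 2) {
  t <- .asCount(target); ref <- .asCount(referenceSubunit)
  if (copiesPerComplex < 1) stop("'copiesPerComplex' must be >= 1")
  if (ref@molecules <= 0) stop("reference subunit count must be > 0")
  val <- t@molecules / (ref@molecules / copiesPerComplex)
  sem <- if (!is.na(t@sem) && !is.na(ref@sem) && t@molecules > 0)
    val * sqrt((t@sem / t@molecules)^2 + (ref@sem / ref@molecules)^2)
  else NA_real_
  moleculeCount(val, sem)
}

#' Percent of a protein phosphorylated
#'
#' \code{100 * phospho / total}.  A phospho count exceeding the total is
#' flagged with a warning (different staining antibodies can have different
#' effective efficiencies) rather than treated as fatal.
#'
#' @param phospho [MoleculeCount-class] (or numeric) of the phosphorylated
#'   form.
#' @param total [MoleculeCount-class] (or numeric) of the total protein
#'   (> 0).
#' @return A [MoleculeCount-class] whose \code{molecules} slot holds the
#'   percentage (delta-method sem when available).
#' @examples
#' molecules(phosphoFraction(220, 5300))  # 4.1509...% pY319 of ZAP70
#' @export
phosphoFraction <- function(phospho, total) {
  p <- .asCount(phospho); t <- .asCount(total)
  if (t@molecules <= 0) stop("total molecule count must be > 0")
  if (p@molecules > t@molecules)
    warning("phospho count exceeds total; check antibody efficiencies")
  val <- 100 * p@molecules / t@molecules
  sem <- if (!is.na(p@sem) && !is.na(t@sem) && p@molecules > 0)
    val * sqrt((p@sem / p@molecules)^2 + (t@sem / t@molecules)^2)
  else NA_real_
  moleculeCount(val, sem)
}
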