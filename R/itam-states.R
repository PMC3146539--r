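# State-space enumeration for the opposing-ITAM-pair model.
#
# A single ITAM (two tyrosines, treated as identical sites) together with its
# recruited ZAP70 occupies one of seven states; a pair of opposing ITAMs is
# then an unordered pair of single-ITAM states, 28 in total after symmetry
# reduction of the 49 ordered configurations.

.ITAM_STATES <- c("U", "P1", "P2", "Z", "Z319", "Z319_493", "Z493")

# States in which a ZAP70 molecule is bound (requires the doubly
# phosphorylated ITAM) and in which its Y319 is phosphorylated ("opened").
.ZAP_BOUND <- c("Z", "Z319", "Z319_493", "Z493")
.PY319     <- c("Z319", "Z319_493")
.PY493     <- c("Z319_493", "Z493")

#' Single-ITAM state labels
#'
#' The seven states a single ITAM can occupy with respect to its two-tyrosine
#' phosphorylation, ZAP70 recruitment and ZAP70 phosphorylation:
#' \code{U} (no tyrosine phosphorylated), \code{P1} (one of the two),
#' \code{P2} (both, ZAP70-free), \code{Z} (ZAP70 bound, unmodified),
#' \code{Z319} (bound ZAP70 phosphorylated at Y319), \code{Z319_493}
#' (pY319 and pY493) and \code{Z493} (pY493 only, after Y319 has been
#' dephosphorylated).  ZAP70-bearing states presuppose the doubly
#' phosphorylated ITAM.
#'
#' @return Character vector of length 7.
#' @examples
#' itamStates()
#' @export
itamStates <- function() .ITAM_STATES

#' Enumerate the symmetry-reduced pair state space
#'
#' The basic modelling unit is a pair of opposing ITAMs.  With 7 single-ITAM
#' states there are 7 x 7 = 49 ordered joint configurations; because the two
#' ITAMs are indistinguishable, the dynamics close on the 28 unordered pairs
#' \{(s, t): s <= t\} (7 symmetric + choose(7, 2) mixed).  This function
#' returns the canonical ordering of those 28 states and the bijection from
#' each ordered pair onto its unordered representative.
#'
#' @return A list with components:
#' \describe{
#'   \item{singleStates}{the 7 single-ITAM state labels.}
#'   \item{pairs}{data.frame of the 28 canonical unordered pairs with columns
#'     \code{index}, \code{label} (e.g. \code{"U|Z319"}), \code{site1},
#'     \code{site2} (state labels, site1 <= site2 in canonical order) and
#'     \code{symmetric}.}
#'   \item{orderedIndex}{7 x 7 integer matrix mapping the ordered pair
#'     (row state, column state) to the index of its unordered
#'     representative.}
#' }
#' @examples
#' ps <- enumeratePairStates()
#' nrow(ps$pairs)            # 28
#' length(ps$orderedIndex)   # 49 ordered configurations
#' @export
enumeratePairStates <- function() {
  s <- .ITAM_STATES
  n <- length(s)
  site1 <- character(0); site2 <- character(0)
  for (i in seq_len(n)) for (j in i:n) {
    site1 <- c(site1, s[i]); site2 <- c(site2, s[j])
  }
  pairs <- data.frame(
    index = seq_along(site1),
    label = paste(site1, site2, sep = "|"),
    site1 = site1, site2 = site2,
    symmetric = site1 == site2,
    stringsAsFactors = FALSE
  )
  ordered <- matrix(NA_integer_, n, n, dimnames = list(s, s))
  for (k in seq_len(nrow(pairs)))
    ordered[pairs$site1[k], pairs$site2[k]] <-
      ordered[pairs$site2[k], pairs$site1[k]] <- pairs$index[k]
  list(singleStates = s, pairs = pairs, orderedIndex = ordered)
}

# Single-site reaction list: each row is one first-order transition of one
# ITAM site.  `mult` carries the identical-site combinatorics (two ways to
# place the first phosphate on an unphosphorylated ITAM, two ways to remove
# one from a doubly phosphorylated ITAM).  `gscaled` marks dephosphorylation
# steps whose rate constant is multiplied by the phosphatase activity g(t).
# `needsOpenPartner` marks Y493 trans-autophosphorylation, which requires the
# opposing ITAM to carry an opened (pY319) ZAP70.
.siteTransitions <- function() {
  data.frame(
    from = c("U",  "P1", "P1", "P2",
             "P2", "Z", "Z319", "Z319_493", "Z493",
             "Z",  "Z319",
             "Z319", "Z319_493",
             "Z493", "Z319_493", "Z493"),
    to   = c("P1", "U",  "P2", "P1",
             "Z",  "P2", "P2",  "P2",       "P2",
             "Z319", "Z",
             "Z319_493", "Z319",
             "Z",    "Z493",     "Z319_493"),
    rate = c("k_itam_p", "k_itam_dp", "k_itam_p", "k_itam_dp",
             "k_on", "k_off", "k_off", "k_off", "k_off",
             "k_y319", "k_y319_dp",
             "k_y493", "k_y493_dp",
             "k_y493_dp", "k_y319_dp", "k_y319"),
    mult = c(2, 1, 1, 2,
             1, 1, 1, 1, 1,
             1, 1,
             1, 1,
             1, 1, 1),
    gscaled = c(FALSE, TRUE, FALSE, TRUE,
                FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, TRUE,
                FALSE, TRUE,
                TRUE, TRUE, FALSE),
    needsOpenPartner = c(FALSE, FALSE, FALSE, FALSE,
                         FALSE, FALSE, FALSE, FALSE, FALSE,
                         FALSE, FALSE,
                         TRUE, FALSE,
                         FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Structural transition table of the 28-state pair system, parameter-free:
# one row per (from pair, to pair, rate name, combinatorial coefficient,
# g-scaled flag).  Built once and cached; pairRateMatrices() fills in the
# numeric rates.
.pairTransitionCache <- new.env(parent = emptyenv())

.pairTransitionTable <- function() {
  if (!is.null(.pairTransitionCache$tbl)) return(.pairTransitionCache$tbl)
  ps <- enumeratePairStates()
  st <- .siteTransitions()
  rows <- list()
  for (u in seq_len(nrow(ps$pairs))) {
    a <- ps$pairs$site1[u]; b <- ps$pairs$site2[u]
    # transitions of the site in state `a` (partner `b`), and of the site in
    # state `b` (partner `a`); for symmetric pairs one pass with factor 2.
    combos <- if (a == b) list(c(a, b, 2)) else list(c(a, b, 1), c(b, a, 1))
    for (cmb in combos) {
      siteState <- cmb[1]; partner <- cmb[2]; factor <- as.numeric(cmb[3])
      tr <- st[st$from == siteState, , drop = FALSE]
      for (k in seq_len(nrow(tr))) {
        if (tr$needsOpenPartner[k] && !(partner %in% .PY319)) next
        target <- ps$orderedIndex[tr$to[k], partner]
        rows[[length(rows) + 1L]] <- data.frame(
          from = u, to = target, rate = tr$rate[k],
          coef = factor * tr$mult[k], gscaled = tr$gscaled[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  tbl <- do.call(rbind, rows)
  .pairTransitionCache$tbl <- tbl
  tbl
}

# Assemble the 28x28 generator split A(g) = A0 + g * A1 for given rates, so
# that dx/dt = (A0 + g(t) A1) %*% x.  Columns sum to zero by construction
# (mass conservation).
pairRateMatrices <- function(params) {
  stopifnot(is(params, "RateParameters"))
  tbl <- .pairTransitionTable()
  k <- rateValues(params)[tbl$rate]
  v <- tbl$coef * as.numeric(k)
  labels <- enumeratePairStates()$pairs$label
  build <- function(sel) {
    A <- matrix(0, 28, 28, dimnames = list(labels, labels))
    if (any(sel)) {
      gain <- rowsum(v[sel], (tbl$from[sel] - 1L) * 28L + tbl$to[sel])
      loss <- rowsum(v[sel], (tbl$from[sel] - 1L) * 28L + tbl$from[sel])
      A[as.integer(rownames(gain))] <- A[as.integer(rownames(gain))] + gain
      A[as.integer(rownames(loss))] <- A[as.integer(rownames(loss))] - loss
    }
    A
  }
  list(A0 = build(!tbl$gscaled), A1 = build(tbl$gscaled))
}
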