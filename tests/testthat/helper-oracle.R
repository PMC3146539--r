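# Brute-force oracle: the full 49-ordered-state pair model, built directly
# from the per-site reaction list with the two ITAM sites kept
# distinguishable.  Written independently of the package's 28-state
# generator assembly so that agreement between the two is a genuine
# dual-route check of the symmetry reduction.

oracleStateGrid <- function() {
  s <- itamStates()
  expand.grid(s1 = s, s2 = s, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

# per-site reactions: from, to, rate name, site multiplicity, g-scaled,
# partner must carry an opened (pY319) ZAP70
oracleReactions <- function() {
  list(
    list("U",        "P1",       "k_itam_p",  2, FALSE, FALSE),
    list("P1",       "U",        "k_itam_dp", 1, TRUE,  FALSE),
    list("P1",       "P2",       "k_itam_p",  1, FALSE, FALSE),
    list("P2",       "P1",       "k_itam_dp", 2, TRUE,  FALSE),
    list("P2",       "Z",        "k_on",      1, FALSE, FALSE),
    list("Z",        "P2",       "k_off",     1, FALSE, FALSE),
    list("Z319",     "P2",       "k_off",     1, FALSE, FALSE),
    list("Z319_493", "P2",       "k_off",     1, FALSE, FALSE),
    list("Z493",     "P2",       "k_off",     1, FALSE, FALSE),
    list("Z",        "Z319",     "k_y319",    1, FALSE, FALSE),
    list("Z319",     "Z",        "k_y319_dp", 1, TRUE,  FALSE),
    list("Z319",     "Z319_493", "k_y493",    1, FALSE, TRUE),
    list("Z319_493", "Z319",     "k_y493_dp", 1, TRUE,  FALSE),
    list("Z493",     "Z",        "k_y493_dp", 1, TRUE,  FALSE),
    list("Z319_493", "Z493",     "k_y319_dp", 1, TRUE,  FALSE),
    list("Z493",     "Z319_493", "k_y319",    1, FALSE, FALSE)
  )
}

# 49x49 generator split (A0 constant, A1 multiplied by phosphatase activity)
oracleMatrices <- function(params) {
  r <- rateValues(params)
  grid <- oracleStateGrid()
  key <- paste(grid$s1, grid$s2)
  idx <- function(a, b) match(paste(a, b), key)
  opened <- c("Z319", "Z319_493")
  A0 <- matrix(0, 49, 49)
  A1 <- matrix(0, 49, 49)
  for (i in seq_len(49)) {
    pair <- c(grid$s1[i], grid$s2[i])
    for (site in 1:2) {
      partner <- pair[3 - site]
      for (rx in oracleReactions()) {
        if (rx[[1]] != pair[site]) next
        if (rx[[6]] && !(partner %in% opened)) next
        after <- pair
        after[site] <- rx[[2]]
        j <- idx(after[1], after[2])
        rate <- rx[[4]] * r[[rx[[3]]]]
        if (rx[[5]]) {
          A1[j, i] <- A1[j, i] + rate
          A1[i, i] <- A1[i, i] - rate
        } else {
          A0[j, i] <- A0[j, i] + rate
          A0[i, i] <- A0[i, i] - rate
        }
      }
    }
  }
  list(A0 = A0, A1 = A1, grid = grid)
}

# integrate the 49-state system under a dosing schedule
oracleSimulate <- function(params, schedule, times, x0) {
  mats <- oracleMatrices(params)
  r <- rateValues(params)
  deriv <- function(t, y, p) {
    g <- phosphataseActivity(t, schedule, r[["f_min"]], r[["tau_rec"]])
    list(as.numeric((mats$A0 + g * mats$A1) %*% y))
  }
  doses <- schedule@doseTimes
  outTimes <- sort(unique(times))
  bounds <- sort(unique(c(0, doses[doses <= max(outTimes)], max(outTimes))))
  sol <- matrix(NA_real_, length(outTimes), 49)
  if (0 %in% outTimes) sol[which(outTimes == 0), ] <- x0
  x <- x0
  for (seg in seq_len(max(length(bounds) - 1L, 0))) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    if (t1 <= t0) next
    inner <- outTimes[outTimes > t0 & outTimes <= t1]
    segTimes <- sort(unique(c(t0, inner, t1)))
    out <- deSolve::lsoda(x, segTimes, deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    m <- out[, -1, drop = FALSE]
    if (length(inner))
      sol[match(inner, outTimes), ] <- m[match(inner, segTimes), ]
    x <- as.numeric(m[nrow(m), ])
  }
  list(times = outTimes, states = sol, grid = mats$grid)
}

# spread a 28-state symmetric occupancy vector over the 49 ordered states
orderedFromUnordered <- function(x28) {
  ps <- enumeratePairStates()
  grid <- oracleStateGrid()
  vapply(seq_len(49), function(i) {
    u <- ps$orderedIndex[grid$s1[i], grid$s2[i]]
    if (ps$pairs$symmetric[u]) x28[u] else x28[u] / 2
  }, numeric(1))
}

# collapse 49 ordered occupancies onto the 28 canonical unordered states
unorderedFromOrdered <- function(x49) {
  ps <- enumeratePairStates()
  grid <- oracleStateGrid()
  u <- ps$orderedIndex[cbind(grid$s1, grid$s2)]
  as.numeric(rowsum(x49, u))
}

# observables computed directly on the ordered representation
oracleObservables <- function(sim, params) {
  r <- rateValues(params)
  zset <- c("Z", "Z319", "Z319_493", "Z493")
  p319 <- c("Z319", "Z319_493")
  p493 <- c("Z319_493", "Z493")
  cnt <- function(set) (sim$grid$s1 %in% set) + (sim$grid$s2 %in% set)
  data.frame(
    time_min = sim$times,
    bound_Z = as.numeric(sim$states %*% cnt(zset)) * r[["s_Z"]],
    bound_pY319 = as.numeric(sim$states %*% cnt(p319)) * r[["s_pY"]],
    bound_pY493 = as.numeric(sim$states %*% cnt(p493))
  )
}

# random but well-behaved parameter sets for property sweeps
randomRateParameters <- function() {
  lp <- stats::runif(8, -1.3, 1)            # rates 10^-1.3 .. 10
  rateParameters(
    k_itam_p = 10^lp[1], k_itam_dp = 10^lp[2],
    k_on = 10^lp[3], k_off = 10^lp[4],
    k_y319 = 10^lp[5], k_y319_dp = 10^lp[6],
    k_y493 = 10^lp[7], k_y493_dp = 10^lp[8],
    f_min = stats::runif(1, 0.02, 0.9),
    tau_rec = stats::runif(1, 5, 120),
    s_Z = 10^stats::runif(1, -0.5, 0.5),
    s_pY = 10^stats::runif(1, -0.5, 0.5))
}
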