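# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
# Generators take explicit seeds (never global state), so every draw routes
# through here.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Lognormal sdlog corresponding to a geometric coefficient of variation
# expressed as a fraction: CV^2 = exp(sdlog^2) - 1.
sdlogFromCV <- function(cv) {
  if (any(cv < 0)) stop("coefficient of variation must be >= 0")
  sqrt(log(1 + cv^2))
}

# Mean-one multiplicative lognormal noise factors for a %cv.
lnormNoiseFactors <- function(n, cvPercent) {
  if (cvPercent < 0) stop("'cvPercent' must be >= 0")
  if (cvPercent == 0) return(rep(1, n))
  s <- sdlogFromCV(cvPercent / 100)
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

# Lognormal draws with a given geometric mean and sdlog.
rlnormGeo <- function(n, geoMean, sdlog) {
  if (any(geoMean <= 0)) stop("geometric mean must be > 0")
  if (sdlog == 0) return(rep(geoMean, n))
  stats::rlnorm(n, meanlog = log(geoMean), sdlog = sdlog)
}
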