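# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage seed derived from (master seed, stage name), so
# adding a stage never perturbs earlier stages' randomness. Kept < 2^31.
.stageSeed <- function(masterSeed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(masterSeed) * 1000003 + h) %% 2147483647L)
}

# Gaussian smoothing of a regularly sampled signal, kernel sd in grid units.
# Edge-renormalised so a constant signal stays constant.
.gaussianSmooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(3 * sd))
  w <- stats::dnorm(seq(-half, half), sd = sd)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  num <- stats::filter(xp, w, sides = 2)
  as.numeric(num[(half + 1):(half + n)]) / sum(w)
}

# Format numbers for CSV output: round-trip stable at 10 significant digits.
.fmtNum <- function(x) sprintf("%.10g", x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
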