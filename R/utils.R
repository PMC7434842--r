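# Internal utilities: seeded RNG scoping, causal biquad filtering,
# not-a-knot cubic B-spline interpolation helpers.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed == floor(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# -- causal second-order sections ------------------------------------------

# Design a causal low-pass Butterworth biquad; returns b (3), a (3, a[1]=1).
lowpass_biquad <- function(cutoff_hz, fs, order = 2L) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# Fresh direct-form-II transposed state for an n-th order filter.
biquad_state <- function(filt) numeric(length(filt$b) - 1L)

# Advance the filter by one sample; returns list(y, state).  Pure function of
# (x, state) so streaming use is causal by construction.
biquad_step <- function(filt, x, state) {
  b <- filt$b; a <- filt$a
  y <- b[1] * x + state[1]
  n <- length(state)
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      state[k] <- b[k + 1L] * x + state[k + 1L] - a[k + 1L] * y
    }
  }
  state[n] <- b[n + 1L] * x - a[n + 1L] * y
  list(y = y, state = state)
}

# Vectorized causal run over a whole signal (offline use; identical to
# repeated biquad_step).
biquad_run <- function(filt, x, state = biquad_state(filt)) {
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    st <- biquad_step(filt, x[i], state)
    y[i] <- st$y
    state <- st$state
  }
  list(y = y, state = state)
}

# -- not-a-knot cubic B-spline interpolation -------------------------------
# Reproduces polynomials up to degree 3 exactly; used for the MTU kinematics
# surrogate and the per-Gauss-point strain splines.

nak_knots <- function(x, ord = 4L) {
  n <- length(x)
  stopifnot(n >= ord)
  if (ord == 4L) {
    interior <- if (n > 4L) x[seq(3L, n - 2L)] else numeric(0)
  } else if (ord == 2L) {
    interior <- x[seq(2L, n - 1L)]
  } else stop("unsupported order")
  c(rep(x[1], ord), interior, rep(x[n], ord))
}

# Collocation: coefficients c with B(x) %*% c = y (y may be a matrix).
nak_spline_fit <- function(x, y, ord = 4L) {
  kn <- nak_knots(x, ord)
  A <- splines::splineDesign(kn, x, ord = ord)
  list(knots = kn, ord = ord, coef = solve(A, y), range = range(x))
}

nak_spline_eval <- function(fit, xout, deriv = 0L) {
  rng <- fit$range
  if (any(xout < rng[1] - 1e-12 | xout > rng[2] + 1e-12))
    stop("evaluation outside the fitted range (no extrapolation)")
  xout <- pmin(pmax(xout, rng[1]), rng[2])
  B <- splines::splineDesign(fit$knots, xout, ord = fit$ord,
                             derivs = rep(deriv, length(xout)))
  B %*% fit$coef
}
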