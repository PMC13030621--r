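# Internal utilities: classed conditions, seeded evaluation, logging,
# peak picking, zero-phase low-pass filtering, smooth periodic noise.

## ---- classed conditions ----------------------------------------------------

# Two top-level families drive the CLI exit-code policy:
#   gv_validation_error -> exit 2 (bad configuration / arguments / invariants)
#   gv_data_error       -> exit 3 (bad or inconsistent data, pairing, signals)
gv_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "gaitval_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_validation <- function(msg, subclass = NULL) {
  gv_abort(msg, c(subclass, "gv_validation_error"))
}

abort_data <- function(msg, subclass = NULL) {
  gv_abort(msg, c(subclass, "gv_data_error"))
}

abort_format    <- function(msg) abort_data(msg, "gv_format_error")
abort_parse     <- function(msg) abort_data(msg, "gv_parse_error")
abort_integrity <- function(msg) abort_data(msg, "gv_integrity_error")
abort_pairing   <- function(msg) abort_data(msg, "gv_pairing_error")
abort_signal    <- function(msg) abort_data(msg, "gv_signal_error")
abort_design    <- function(msg) abort_data(msg, "gv_design_error")
abort_io        <- function(msg) abort_data(msg, "gv_io_error")

## ---- seeded evaluation -----------------------------------------------------

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulate_* calls leave no global side effects.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort_validation("'seed' must be a single finite number")
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

## ---- logging ---------------------------------------------------------------

# Structured-ish logging to stderr; silent unless option gaitval.verbose is set
# (the CLI sets it). Tests stay quiet by default.
gv_log <- function(stage, msg) {
  if (isTRUE(getOption("gaitval.verbose", FALSE))) {
    message(sprintf("[gaitval %s] %s: %s",
                    format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  invisible(NULL)
}

# Run a stage, log its wall time, return list(value, seconds).
gv_timed <- function(stage, code) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(code)
  dt <- proc.time()[["elapsed"]] - t0
  gv_log(stage, sprintf("done in %.2f s", dt))
  list(value = value, seconds = dt)
}

## ---- peak picking ----------------------------------------------------------

# Indices of local maxima of x, optionally above min_height, with a greedy
# (highest-first) minimum index separation. Plateaus yield their left edge.
find_peaks <- function(x, min_height = -Inf, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
  cand <- cand[x[cand] >= min_height]
  if (length(cand) <= 1L || min_distance <= 1L) return(cand)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= min_distance)) kept <- c(kept, p)
  }
  sort(kept)
}

find_troughs <- function(x, max_height = Inf, min_distance = 1L) {
  find_peaks(-x, min_height = -max_height, min_distance = min_distance)
}

## ---- zero-phase Butterworth low-pass ---------------------------------------

# 2nd-order Butterworth low-pass biquad (bilinear transform, Q = 1/sqrt(2)).
butter2_lowpass <- function(cutoff_hz, rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    abort_validation("low-pass cutoff must lie in (0, rate/2)")
  }
  K <- tan(pi * cutoff_hz / rate_hz)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  list(b = c(K^2, 2 * K^2, K^2) * norm,
       a = c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm))
}

# Causal IIR filter y = filter(b, a, x), initialized at the DC steady state of
# x[1] so step-free signals start settled.
filt2 <- function(ba, x) {
  n <- length(x)
  b <- ba$b; a <- ba$a
  xp <- c(rep(x[1], 2L), x)
  v <- b[1] * xp[3:(n + 2L)] + b[2] * xp[2:(n + 1L)] + b[3] * xp[1:n]
  as.numeric(stats::filter(v, filter = -a[2:3], method = "recursive",
                           init = rep(x[1], 2L)))
}

# Forward-backward (zero-phase) application with reflective edge padding.
filtfilt2 <- function(ba, x) {
  n <- length(x)
  if (n < 7L) return(x)
  pad <- min(n - 1L, 30L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- filt2(ba, xp)
  y <- rev(filt2(ba, rev(y)))
  y[(pad + 1L):(pad + n)]
}

## ---- smooth periodic random curves ----------------------------------------

# n zero-mean smooth periodic curves over the 101-point gait-cycle grid, built
# from the first n_harm Fourier harmonics with 1/k amplitude decay, scaled so
# the expected pointwise RMS equals `rms`. Used for subject deviation fields,
# stride-to-stride waveform variability and correlated measurement noise.
smooth_random_curves <- function(n, rms, n_harm = 6L) {
  if (n == 0L || rms == 0) return(matrix(0, nrow = n, ncol = 101L))
  t <- seq(0, 1, length.out = 101L)
  w <- 1 / seq_len(n_harm)
  basis <- matrix(0, nrow = 2L * n_harm, ncol = 101L)
  for (k in seq_len(n_harm)) {
    basis[2L * k - 1L, ] <- sin(2 * pi * k * t)
    basis[2L * k, ]      <- cos(2 * pi * k * t)
  }
  coef <- matrix(rnorm(n * 2L * n_harm), nrow = n)
  coef <- sweep(coef, 2L, rep(w, each = 2L), `*`)
  scale <- rms / sqrt(sum(w^2))
  (coef %*% basis) * scale
}

## ---- misc ------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
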