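# Shared fixtures: small detectors and pre-simulated stacks reused across
# test files (built once per test run).

quiet_sim <- function(expr) suppressWarnings(expr)

# A small quiet detector: no nonlinearity, no brighter-fatter.
test_detector <- function(shape = c(128L, 128L), ...) {
  detector_model(shape = shape, ...)
}

# Flat stack at the reference acquisition conditions, cached.
ref_stack_cache <- new.env(parent = emptyenv())

ref_stack_128 <- function() {
  if (is.null(ref_stack_cache$stk)) {
    det <- test_detector()
    beam <- flat_beam(det, 7050, 0.85)
    ref_stack_cache$det <- det
    ref_stack_cache$beam <- beam
    ref_stack_cache$stk <- simulate_flat_stack(det, beam, 16L, 16L, 0.85,
                                               seed = 20260901L)
    ref_stack_cache$ref <- build_gain_reference(ref_stack_cache$stk$signal,
                                                ref_stack_cache$stk$dark)
  }
  ref_stack_cache
}

# Direct circular-lag autocovariance double sum (brute-force oracle).
brute_autocov <- function(img) {
  m <- nrow(img); n <- ncol(img)
  d <- img - mean(img)
  out <- matrix(0, 2 * m - 1, 2 * n - 1)
  for (mm in -(m - 1):(m - 1)) for (nn in -(n - 1):(n - 1)) {
    s <- 0
    for (i in 1:m) for (j in 1:n) {
      s <- s + d[i, j] * d[((i - 1 + mm) %% m) + 1, ((j - 1 + nn) %% n) + 1]
    }
    out[m + mm, n + nn] <- s / (m * n)
  }
  out
}
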