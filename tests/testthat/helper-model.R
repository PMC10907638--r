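## Shared fixtures. The package caches the expensive deterministic
## quantities (equilibrated limit-cycle states, the calcium target), so
## building them here once keeps the whole suite fast.
test_model <- function() cell_model()

test_cstar <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- as.numeric(compute_target_calcium(test_model()))
    val
  }
})

test_params <- function(...) {
  regulation_params(c_target_mM = test_cstar(), ...)
}

## an ideal square-pulse train: period 1000 ms, width 300 ms, 2 ms sampling
square_pulse_trace <- function(n_beats = 5, width = 300, period = 1000,
                               dt = 2) {
  t <- seq(0, n_beats * period, by = dt)
  v <- as.numeric((t %% period) >= 100 & (t %% period) < (100 + width))
  as_trace(tibble::tibble(time_ms = t, V_mV = v))
}

## feasible random synthetic-trace spec for property sweeps
random_synth_spec <- function(seed) {
  rate <- stats::runif(1, 30, 120)
  period <- 60000 / rate
  a50 <- stats::runif(1, 150, min(500, 0.55 * period))
  a80 <- a50 + stats::runif(1, 30, min(120, 0.35 * a50,
                                       0.35 * (period - a50)))
  synth_trace_spec(
    beat_rate_bpm = rate, apd50_ms = a50, apd80_ms = a80,
    noise_sd = stats::runif(1, 0, 0.05),
    drift_per_s = stats::runif(1, -0.02, 0.02), seed = seed
  )
}
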