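# shared fixtures, built in code and memoized for the duration of the run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

battery_freqs <- c(0.7, 1, 1.5, 2.1, 3.5, 5.3, 10.6)

noise_free_config <- function(mode = "body_free", ...) {
  sim_config(mode = mode, noise_std_head = 0, noise_std_body = 0, ...)
}

# direct-sum DFT oracle, deliberately naive and independent of czt_spectrum
dft_oracle <- function(x, sample_rate, freqs) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / sample_rate
  vapply(freqs, function(f) sum(x * exp(-2i * pi * f * tt)), complex(1)) *
    2i / n
}

# one noise-free body-free trial at 2.1 Hz, reused by several files
quick_trial <- function() {
  memo("quick_trial", simulate_trial(
    default_fly(), single_sine(2.1, duration = 12),
    noise_free_config(transient_discard = 2)))
}

# the full study-scale pipeline run, shared by the acceptance tests
acceptance_run <- function() {
  memo("acceptance_run", {
    dir <- file.path(tempdir(), "gazeloop-acceptance")
    suppressWarnings(run_pipeline(run_config(seed = 42L), out_dir = dir))
  })
}
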