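# Shared synthetic fixtures, built in code at test time.
#
# Tests run on a scaled-down instrument: sweep limited to the 1-100 Hz
# analysis band (the structural damping fit never uses higher frequencies)
# and 1 kHz sampling, which keeps a full curve near 10^4 samples.

test_instrument <- function(noise_sd_force = 0, b0 = 2e-6, ...) {
  instrument_config(sweep = sweep_schedule(f_max = 100),
                    sample_rate = 1000,
                    noise_sd_force = noise_sd_force, b0 = b0, ...)
}

# memoized noiseless healthy curve reused across test files
.fixture_env <- new.env(parent = emptyenv())

healthy_curve <- function() {
  if (is.null(.fixture_env$healthy)) {
    .fixture_env$healthy <- generate_force_curve(cohort_preset("healthy"),
                                                 test_instrument())
  }
  .fixture_env$healthy
}

# generator transfer (complex F_hat(d)/z_hat ratio building block) recorded
# as ground truth in curve metadata
truth_transfer <- function(curve) {
  tt <- curve$meta$truth$transfer
  complex(real = tt$re, imaginary = tt$im)
}
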