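test_that("pure sinusoids are demodulated to machine precision", {
  tip <- tip_geometry("sphere", radius = 75e-9)
  sched <- sweep_schedule(frequencies = c(2, 5, 10), cycles = 4,
                          amplitude = 1e-8)
  fs <- 500
  n <- ceiling(sched$total_time * fs)
  win <- afmrheo:::schedule_windows(sched, 1L, fs)
  win$end[nrow(win)] <- n
  z <- numeric(n)
  d <- numeric(n)
  for (j in seq_len(nrow(win))) {
    idx <- seq.int(win$start[j], win$end[j])
    tau <- (idx - 1) / fs - win$t_start[j]
    # cosine input -> complex amplitude a, phase 0; plus constant offset
    z[idx] <- 1e-8 * cos(2 * pi * win$f[j] * tau) + 5e-7
    d[idx] <- 2e-9 * sin(2 * pi * win$f[j] * tau) + 1e-9
  }
  cv <- force_curve((seq_len(n) - 1) / fs, z, d, 0.1, tip,
                    segments = data.frame(segment = "modulation", start = 1L,
                                          end = n),
                    schedule = sched)
  dm <- demodulate(cv)
  expect_true(all(dm$valid))
  # cos -> a + 0i (offset absorbed by C); sin -> -i a, i.e. F = k * d
  expect_equal(dm$z_hat, rep(complex(real = 1e-8, imaginary = 0), 3),
               tolerance = 1e-12)
  expect_equal(dm$F_hat, rep(complex(real = 0, imaginary = -0.1 * 2e-9), 3),
               tolerance = 1e-12)

  # adding a constant offset changes nothing
  cv2 <- cv
  cv2$deflection <- cv2$deflection + 3e-8
  expect_equal(demodulate(cv2)$F_hat, dm$F_hat, tolerance = 1e-10)
})

test_that("noiseless generator sweep reproduces the scheduled transfer", {
  cv <- healthy_curve()
  truth <- cv$meta$truth
  cp <- find_contact_point(cv)
  dm <- demodulate(cv, z0 = cp$z0, baseline = cp$baseline)
  expect_true(all(dm$valid))
  # measured deflection/piezo transfer equals the generator's per-frequency
  # transfer T = (H + i w b0)/(k + H)
  Td_meas <- (dm$F_hat / cv$spring_constant) / dm$z_hat
  expect_equal(Td_meas, truth_transfer(cv), tolerance = 1e-6)
  # operating indentation read back from the modulation carrier
  expect_equal(mean(dm$delta0), truth$delta0, tolerance = 1e-6)
})

test_that("windows shorter than two cycles are skipped with a warning", {
  cv <- healthy_curve()
  short <- cv
  # chop the modulation so the last scheduled frequency loses its window
  mod <- short$segments[short$segments$segment == "modulation", ]
  cut <- mod$end - 150L
  keep <- seq_len(cut)
  short <- force_curve(short$time[keep], short$z_piezo[keep],
                       short$deflection[keep], short$spring_constant,
                       short$tip,
                       segments = data.frame(segment = c("approach", "dwell",
                                                         "modulation"),
                                             start = short$segments$start[1:3],
                                             end = c(short$segments$end[1:2],
                                                     cut)),
                       schedule = short$schedule)
  expect_warning(dm <- demodulate(short), "cycles")
  expect_false(all(dm$valid))
  expect_true(any(dm$valid))
})
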