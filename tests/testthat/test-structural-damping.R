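test_that("modulus conversion handles real, imaginary and in-contact cases", {
  tip <- tip_geometry("paraboloid", radius = 75e-9, poisson = 0.5)
  f <- c(1, 10, 100)
  dm <- structure(data.frame(f = f, n = 100L,
                             F_hat = complex(real = c(1e-10, 0, 1e-10),
                                             imaginary = c(0, 1e-10, 1e-10)),
                             delta_hat = complex(real = rep(1e-8, 3)),
                             z_hat = complex(real = rep(2e-8, 3)),
                             delta0 = 5e-7, valid = TRUE),
                  class = c("sweep_demod", "data.frame"))
  attr(dm, "drag_corrected") <- TRUE
  sp <- complex_modulus(dm, tip)
  # real transfer -> E'' = 0, phase 0
  expect_equal(sp$E_loss[1], 0)
  expect_equal(sp$phase[1], 0)
  # purely imaginary transfer -> phase pi/2, E' = 0 -> flagged invalid
  expect_equal(sp$phase[2], pi / 2)
  expect_false(sp$valid[2])
  expect_true(sp$valid[1] && sp$valid[3])
  # conversion factor: E* = (1 - nu^2) / (2 sqrt(R delta0)) F_hat/delta_hat
  fac <- (1 - 0.25) / (2 * sqrt(75e-9 * 5e-7))
  expect_equal(sp$E_storage[1], fac * 1e-10 / 1e-8, tolerance = 1e-12)
})

test_that("noiseless healthy spectrum converts to the model storage
           modulus at 1 Hz", {
  cv <- healthy_curve()
  an <- analyze_sweep_curve(cv, drag = 2e-6)
  cell <- cohort_preset("healthy")
  E1 <- Re(structural_damping_modulus(1, cell$E0, cell$alpha, cell$mu))
  sp <- an$spectrum
  expect_equal(sp$E_storage[which.min(abs(sp$f - 1))], E1,
               tolerance = 1e-6)
})

test_that("alpha = 0 limit returns a Kelvin-Voigt fit exactly", {
  f <- 10^seq(0, 2, by = 0.1)
  E0 <- 2500
  mu <- 9
  sp <- model_spectrum(cell_params(1000, E0, 0, mu), frequencies = f)
  expect_equal(sp$E_storage, rep(E0, length(f)), tolerance = 1e-9)
  expect_equal(sp$E_loss, 2 * pi * f * mu, tolerance = 1e-9)
  expect_equal(sp$loss_tangent, 2 * pi * f * mu / E0, tolerance = 1e-9)
  fit <- fit_structural_damping(sp)
  expect_lte(fit$alpha, 1e-6)
  expect_equal(fit$E0, E0, tolerance = 1e-9)
  expect_equal(fit$mu, mu, tolerance = 1e-9)
})

test_that("eta is coupled to alpha as tan(pi alpha / 2)", {
  expect_equal(tan(0.055 * pi), 0.1745, tolerance = 5e-4)
  sp <- model_spectrum(cell_params(1000, 3000, 0.11, 5))
  fit <- fit_structural_damping(sp)
  expect_identical(fit$eta, tan(pi * fit$alpha / 2))
  # mu = 0: loss tangent is frequency independent and equals eta
  sp0 <- model_spectrum(cell_params(1000, 3000, 0.2, 0))
  fit0 <- fit_structural_damping(sp0)
  ev <- evaluate_model(fit0, c(1, 7, 50, 100))
  expect_equal(ev$loss_tangent, rep(tan(pi * 0.2 / 2), 4), tolerance = 1e-9)
})

test_that("model evaluation matches direct arithmetic and is monotone", {
  fit <- fit_structural_damping(model_spectrum(cell_params(1000, 3260,
                                                           0.11, 7)))
  ev1 <- evaluate_model(fit, 1)
  # direct arithmetic oracle at 1 Hz
  expect_equal(ev1$E_loss, tan(pi * 0.11 / 2) * 3260 + 2 * pi * 7,
               tolerance = 1e-6)
  expect_equal(ev1$E_storage, 3260, tolerance = 1e-6)
  # with mu > 0 the loss tangent strictly increases with frequency
  dense <- evaluate_model(fit, seq(1, 100, length.out = 400))
  expect_true(all(diff(dense$loss_tangent) > 0))
  expect_true(all(dense$E_storage > 0))
  expect_true(all(diff(dense$E_storage) > 0))
  expect_error(evaluate_model(fit, c(1, -2)), "f must be > 0")
})

test_that("fit recovers parameters across the physiological range", {
  # exact spectra over a 3x3x3 grid; recovery to 1e-4 relative
  for (E0 in c(100, 3000, 100e3)) {
    for (alpha in c(0.01, 0.17, 0.5)) {
      for (mu in c(0, 5, 50)) {
        sp <- model_spectrum(cell_params(1000, E0, alpha, mu))
        fit <- fit_structural_damping(sp)
        expect_equal(fit$E0, E0, tolerance = 1e-4)
        expect_equal(fit$alpha, alpha, tolerance = 1e-4)
        if (mu > 0) expect_equal(fit$mu, mu, tolerance = 1e-4 * mu)
        else expect_lt(fit$mu, 1e-6)
      }
    }
  }
})

test_that("free-eta variant matches the coupled fit on coupled data", {
  sp <- model_spectrum(cell_params(1000, 3308, 0.11, 7))
  fit <- fit_structural_damping(sp, free_eta = TRUE)
  expect_equal(fit$eta, tan(pi * 0.11 / 2), tolerance = 1e-4)
  expect_equal(fit$E0, 3308, tolerance = 1e-3)
})

test_that("unbiased parameter recovery under additive spectrum noise", {
  # spectrum-level Gaussian noise; median estimates over replicates stay
  # close to the generating parameters
  set.seed(11)
  cell <- cohort_preset("healthy")
  est <- replicate(60, {
    sp <- model_spectrum(cell)
    sp$E_storage <- sp$E_storage + rnorm(nrow(sp), 0, 30)
    sp$E_loss <- sp$E_loss + rnorm(nrow(sp), 0, 30)
    fit <- fit_structural_damping(sp)
    c(fit$E0, fit$alpha, fit$mu)
  })
  expect_equal(median(est[1, ]), cell$E0, tolerance = 0.02)
  expect_equal(median(est[2, ]), cell$alpha, tolerance = 0.1)
  expect_equal(median(est[3, ]), cell$mu, tolerance = 0.15 * cell$mu)
})
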