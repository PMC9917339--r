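#' Demodulate a stepped-frequency modulation segment
#'
#' For every scheduled frequency, least-squares fits each channel over that
#' frequency's window to `A*cos(2*pi*f*t) + B*sin(2*pi*f*t) + C` and reports
#' the complex amplitude `A - iB` (so a pure `cos` has phase 0 and a pure
#' `sin` has phase `-pi/2`; constant offsets are absorbed by `C`). Channels
#' are force (`k *` baseline-subtracted deflection), indentation
#' `(z - z0) - d` and piezo position `z`. Windows shorter than 2 cycles are
#' skipped with a warning and flagged invalid.
#'
#' @param curve a [force_curve()] with a `modulation` segment.
#' @param schedule a [sweep_schedule()]; defaults to the one carried by the
#'   curve.
#' @param z0 contact-point z position, m (from [find_contact_point()],
#'   possibly refined); 0 for out-of-contact drag curves.
#' @param baseline deflection-force baseline coefficients `c(intercept,
#'   slope_vs_z)` in N; defaults to no baseline.
#' @return a data.frame of class `sweep_demod` with columns `f`, `n`,
#'   `F_hat`, `delta_hat`, `z_hat` (complex), `delta0` (per-window mean
#'   indentation, m) and `valid`.
#' @export
demodulate <- function(curve, schedule = curve$schedule, z0 = 0,
                       baseline = c(0, 0)) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(schedule))
    stop("demodulate: no sweep schedule available", call. = FALSE)
  idx <- segment_range(curve, "modulation")
  fs <- 1 / stats::median(diff(curve$time))
  win <- schedule_windows(schedule, idx[1], fs)
  last <- idx[length(idx)]
  k <- curve$spring_constant
  z <- curve$z_piezo
  fN <- k * curve$deflection - (baseline[1] + baseline[2] * z)
  out <- data.frame(f = win$f, n = 0L, F_hat = complex(nrow(win)),
                    delta_hat = complex(nrow(win)),
                    z_hat = complex(nrow(win)), delta0 = NA_real_,
                    valid = FALSE)
  for (j in seq_len(nrow(win))) {
    hi <- min(win$end[j], last)
    if (hi < win$start[j]) next
    w <- seq.int(win$start[j], hi)
    # skip only genuinely truncated windows: full scheduled windows cover
    # their integer cycle count up to a fraction of one sample period
    n_cycles <- (length(w) + 1L) / fs * win$f[j]
    if (n_cycles < 2) {
      warning(sprintf("demodulate: window for %.3g Hz covers %.2f cycles;",
                      win$f[j], n_cycles), " skipped", call. = FALSE)
      next
    }
    tau <- (w - idx[1]) / fs - win$t_start[j]
    X <- cbind(cos(2 * pi * win$f[j] * tau), sin(2 * pi * win$f[j] * tau), 1)
    XtX <- crossprod(X)
    coefs <- solve(XtX, crossprod(X, cbind(force = fN[w],
                                           delta = (z[w] - z0) -
                                             fN[w] / k,
                                           z = z[w])))
    amp <- complex(real = coefs[1, ], imaginary = -coefs[2, ])
    out$F_hat[j] <- amp[1]
    out$delta_hat[j] <- amp[2]
    out$z_hat[j] <- amp[3]
    out$delta0[j] <- coefs[3, 2]
    out$n[j] <- length(w)
    out$valid[j] <- TRUE
  }
  attr(out, "drag_corrected") <- FALSE
  class(out) <- c("sweep_demod", class(out))
  out
}

#' Estimate the hydrodynamic drag coefficient from out-of-contact curves
#'
#' For each tip--surface height the drag coefficient is
#' `b(h) = median over f of Im(F_hat / z_hat) / (2*pi*f)`; the zero-gap
#' coefficient `b0` is the intercept of a straight-line fit of `b(h)` versus
#' `h` restricted to the smallest heights, where the height dependence is
#' close to linear.
#'
#' @param drag_curves list of `list(height =, curve =)` as produced by
#'   [generate_drag_curves()].
#' @param schedule optional [sweep_schedule()] override.
#' @param n_extrapolate number of smallest heights used for the linear
#'   extrapolation (default 3, or all available if fewer).
#' @return an object of class `drag_calibration` with `heights`, `b`, `b0`
#'   and `extrapolation_model`.
#' @export
estimate_drag <- function(drag_curves, schedule = NULL, n_extrapolate = 3L) {
  if (length(drag_curves) < 2L)
    stop("estimate_drag: need at least 2 heights", call. = FALSE)
  heights <- vapply(drag_curves, function(x) x$height, numeric(1))
  b <- vapply(drag_curves, function(x) {
    dm <- demodulate(x$curve,
                     schedule = if (is.null(schedule)) x$curve$schedule
                                else schedule)
    ok <- dm$valid
    stats::median(Im(dm$F_hat[ok] / dm$z_hat[ok]) / (2 * pi * dm$f[ok]))
  }, numeric(1))
  if (any(b < 0)) {
    warning("estimate_drag: negative b(h) estimates clipped at 0",
            call. = FALSE)
    b <- pmax(b, 0)
  }
  o <- order(heights)
  use <- o[seq_len(min(n_extrapolate, length(heights)))]
  if (length(use) >= 2L) {
    co <- stats::lm.fit(cbind(1, heights[use]), b[use])$coefficients
    b0 <- co[1]
  } else {
    b0 <- b[use]
  }
  if (b0 < 0) {
    warning("estimate_drag: negative b0 extrapolation clipped at 0",
            call. = FALSE)
    b0 <- 0
  }
  structure(list(heights = heights[o], b = b[o], b0 = unname(b0),
                 extrapolation_model = "linear"),
            class = "drag_calibration")
}

#' @export
print.drag_calibration <- function(x, ...) {
  cat(sprintf("<drag_calibration> b0 = %.4g N.s/m from %d heights (%s)\n",
              x$b0, length(x$heights), x$extrapolation_model))
  invisible(x)
}

#' Subtract the cantilever drag force from a demodulated sweep
#'
#' Removes the out-of-contact hydrodynamic contribution
#' `i * 2*pi*f * b0 * z_hat` from the complex force amplitudes.
#'
#' @param demod a [demodulate()] result.
#' @param b0 drag coefficient at zero separation, N s/m, or a
#'   [estimate_drag()] calibration.
#' @return the demod table with corrected `F_hat` and the `drag_corrected`
#'   attribute set.
#' @export
correct_drag <- function(demod, b0) {
  stopifnot(inherits(demod, "sweep_demod"))
  if (inherits(b0, "drag_calibration")) b0 <- b0$b0
  demod$F_hat <- demod$F_hat - 1i * 2 * pi * demod$f * b0 * demod$z_hat
  attr(demod, "drag_corrected") <- TRUE
  demod
}

#' Convert a demodulated sweep to a complex modulus spectrum
#'
#' Linearized-contact conversion about the operating indentation `delta0`:
#' for spheres/paraboloids
#' \eqn{E^*(f) = \frac{1-\nu^2}{2\sqrt{R\,\delta_0}} \hat F / \hat\delta},
#' for cones
#' \eqn{E^*(f) = \frac{\pi(1-\nu^2)}{4\tan\theta\,\delta_0} \hat F /
#' \hat\delta}. Frequencies whose indentation amplitude falls below
#' `delta_floor`, or where the storage modulus is non-positive, are flagged
#' invalid.
#'
#' @param demod a [demodulate()] result, normally drag-corrected.
#' @param tip a [tip_geometry()].
#' @param delta0 operating indentation, m; defaults to the mean of the
#'   per-window values measured by [demodulate()].
#' @param delta_floor minimum usable `|delta_hat|`, m.
#' @return a data.frame of class `complex_spectrum` with columns `f`,
#'   `E_storage`, `E_loss`, `loss_tangent`, `phase` and `valid`; `delta0`
#'   and `drag_corrected` are attributes.
#' @export
complex_modulus <- function(demod, tip, delta0 = NULL, delta_floor = 1e-12) {
  stopifnot(inherits(demod, "sweep_demod"), inherits(tip, "tip_geometry"))
  if (is.null(delta0)) delta0 <- mean(demod$delta0[demod$valid])
  if (!is.finite(delta0) || delta0 <= 0)
    stop("complex_modulus: operating indentation delta0 must be > 0",
         call. = FALSE)
  Estar <- modulus_from_transfer(demod$F_hat / demod$delta_hat, tip, delta0)
  out <- data.frame(f = demod$f,
                    E_storage = Re(Estar), E_loss = Im(Estar),
                    loss_tangent = Im(Estar) / Re(Estar),
                    phase = Arg(Estar),
                    valid = demod$valid & Mod(demod$delta_hat) >= delta_floor)
  out$valid <- out$valid & is.finite(out$E_storage) & out$E_storage > 0
  attr(out, "delta0") <- delta0
  attr(out, "drag_corrected") <- attr(demod, "drag_corrected")
  class(out) <- c("complex_spectrum", class(out))
  out
}

#' Build a complex-modulus spectrum directly from the structural damping
#' model
#'
#' Evaluates the model at given frequencies and packages the result as a
#' [complex_modulus()]-style spectrum. Used for desk-scale round trips and
#' model exploration without synthesizing full force curves.
#'
#' @param cell a [cell_params()] (only `E0`, `alpha`, `mu` are used).
#' @param frequencies Hz; default 10 per decade over 1--100 Hz.
#' @param f0 reference frequency, Hz.
#' @return a `complex_spectrum` data.frame.
#' @export
model_spectrum <- function(cell,
                           frequencies = 10^seq(0, 2, by = 0.1),
                           f0 = 1) {
  stopifnot(inherits(cell, "cell_params"))
  Estar <- structural_damping_modulus(frequencies, cell$E0, cell$alpha,
                                      cell$mu, f0 = f0)
  out <- data.frame(f = frequencies,
                    E_storage = Re(Estar), E_loss = Im(Estar),
                    loss_tangent = Im(Estar) / Re(Estar),
                    phase = Arg(Estar), valid = TRUE)
  attr(out, "delta0") <- NA_real_
  attr(out, "drag_corrected") <- TRUE
  class(out) <- c("complex_spectrum", class(out))
  out
}

# inner linear solve of the profile fit: given alpha (and its eta), find the
# least-squares (E0, mu >= 0) and residual sum of squares over real and
# imaginary parts jointly
sd_profile <- function(alpha, f, Es, El, f0, free_eta = FALSE,
                       weights = NULL) {
  x <- (f / f0)^alpha
  w <- 2 * pi * f
  if (is.null(weights)) weights <- rep(1, length(f))
  sw <- sqrt(weights)
  if (!free_eta) {
    eta <- tan(pi * alpha / 2)
    X <- rbind(cbind(x, 0), cbind(eta * x, w)) * c(sw, sw)
    y <- c(Es, El) * c(sw, sw)
    co <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA))
    if (anyNA(co) || co[2] < 0) {
      # mu pinned at 0: single-parameter solve
      xx <- c(x, eta * x) * c(sw, sw)
      co <- c(sum(xx * y) / sum(xx * xx), 0)
    }
    E0 <- unname(co[1]); mu <- unname(co[2])
  } else {
    xs <- x * sw
    E0 <- sum(xs * Es * sw) / sum(xs * xs)
    Xi <- cbind(x, w) * sw
    co <- tryCatch(qr.coef(qr(Xi), El * sw), error = function(e) c(NA, NA))
    if (anyNA(co) || co[2] < 0) {
      co <- c(sum(x * El * weights) / sum(x * x * weights), 0)
    }
    eta <- unname(co[1] / E0); mu <- unname(co[2])
  }
  rss <- sum(weights * (Es - E0 * x)^2) +
    sum(weights * (El - E0 * eta * x - w * mu)^2)
  list(E0 = E0, mu = mu, eta = eta, rss = rss)
}

#' Fit the power-law structural damping model to a spectrum
#'
#' Joint least squares on the real and imaginary parts of
#' \eqn{E^*(f) = E_0 (1 + i\eta)(f/f_0)^\alpha + i 2\pi f \mu} over the fit
#' band, with the hysteresivity coupled to the exponent,
#' \eqn{\eta = \tan(\pi\alpha/2)}, and \eqn{\mu \ge 0}. For fixed `alpha`
#' the model is linear in `(E0, mu)`, so the fit profiles out the linear
#' part and searches `alpha` on a grid followed by golden-section
#' refinement; ties prefer the smallest `alpha`. Frequencies above `f_max`
#' (100 Hz by default, where the piezo response rolls off) are excluded.
#'
#' @param spectrum a `complex_spectrum` data.frame ([complex_modulus()] or
#'   [model_spectrum()]).
#' @param f_min,f_max fit band, Hz.
#' @param f0 reference frequency, Hz; `E0` is the storage modulus the model
#'   assigns at `f0`.
#' @param free_eta fit `eta` as a free parameter instead of coupling it to
#'   `alpha` (model variant; the default keeps the structural damping
#'   coupling).
#' @param weights `"absolute"` (equal weight, default) or `"relative"`
#'   (inverse modulus magnitude squared).
#' @return an object of class `structural_damping_fit` with fields `E0`,
#'   `alpha`, `eta`, `mu`, `f0`, `rms_residual` (Pa), `fit_band`, `n_freq`.
#' @export
fit_structural_damping <- function(spectrum, f_min = 1, f_max = 100,
                                   f0 = 1, free_eta = FALSE,
                                   weights = c("absolute", "relative")) {
  stopifnot(inherits(spectrum, "complex_spectrum"))
  weights <- match.arg(weights)
  use <- spectrum$valid & spectrum$f >= f_min - 1e-9 &
    spectrum$f <= f_max + 1e-9
  if (sum(use) < 4L)
    stop("fit_structural_damping: need >= 4 valid frequencies in band",
         call. = FALSE)
  f <- spectrum$f[use]
  Es <- spectrum$E_storage[use]
  El <- spectrum$E_loss[use]
  wts <- if (weights == "relative") 1 / (Es^2 + El^2) else NULL

  obj <- function(a) sd_profile(a, f, Es, El, f0, free_eta, wts)$rss
  grid <- seq(0, 0.95, by = 0.01)
  rss_grid <- vapply(grid, obj, numeric(1))
  best_i <- which.min(rss_grid)
  a_best <- grid[best_i]
  rss_best <- rss_grid[best_i]
  lo <- grid[max(1L, best_i - 1L)]
  hi <- grid[min(length(grid), best_i + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
    if (opt$objective < rss_best * (1 - 1e-12)) {
      a_best <- opt$minimum
      rss_best <- opt$objective
    }
  }
  sol <- sd_profile(a_best, f, Es, El, f0, free_eta, wts)
  if (!is.finite(sol$E0) || sol$E0 <= 0)
    stop("fit_structural_damping: non-physical fit (E0 <= 0)",
         call. = FALSE)
  structure(list(E0 = sol$E0, alpha = a_best,
                 eta = if (free_eta) sol$eta else tan(pi * a_best / 2),
                 mu = sol$mu, f0 = f0,
                 rms_residual = sqrt(sol$rss / (2 * length(f))),
                 fit_band = c(f_min, f_max), n_freq = length(f),
                 free_eta = free_eta),
            class = "structural_damping_fit")
}

#' @export
print.structural_damping_fit <- function(x, ...) {
  cat(sprintf(
    "<structural_damping_fit> E0 = %.4g Pa, alpha = %.4g, eta = %.4g, mu = %.4g Pa.s (f0 = %g Hz, rms %.3g Pa, %d freqs in %g-%g Hz)\n",
    x$E0, x$alpha, x$eta, x$mu, x$f0, x$rms_residual, x$n_freq,
    x$fit_band[1], x$fit_band[2]))
  invisible(x)
}

#' Evaluate a fitted structural damping model
#'
#' @param fit a [fit_structural_damping()] result.
#' @param f frequencies, Hz, all > 0.
#' @return a data.frame with `f`, `E_storage`, `E_loss` and `loss_tangent`;
#'   a loss tangent below 1 indicates solid-like, above 1 liquid-like
#'   behavior.
#' @export
evaluate_model <- function(fit, f) {
  stopifnot(inherits(fit, "structural_damping_fit"))
  if (any(f <= 0)) stop("evaluate_model: f must be > 0", call. = FALSE)
  Estar <- structural_damping_modulus(f, fit$E0, fit$alpha, fit$mu,
                                      f0 = fit$f0, eta = fit$eta)
  data.frame(f = f, E_storage = Re(Estar), E_loss = Im(Estar),
             loss_tangent = Im(Estar) / Re(Estar))
}
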