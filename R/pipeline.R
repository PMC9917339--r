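#' Full sweep-frequency analysis of one force curve
#'
#' Runs the complete chain on a raw curve: segmentation (if needed),
#' contact-point detection with continuous refinement, force--indentation
#' conversion and Hertz fit of the approach (with contact-point shift
#' refinement), per-frequency demodulation of the modulation segment,
#' hydrodynamic drag correction, conversion to a complex modulus spectrum at
#' the operating indentation, and the structural damping fit over the
#' analysis band.
#'
#' @param curve a [force_curve()].
#' @param drag `NULL` (no correction), a scalar `b0` in N s/m, or a
#'   [estimate_drag()] calibration.
#' @param f_min,f_max structural-damping fit band, Hz.
#' @param f0 reference frequency, Hz.
#' @param drift_correction linear pre-contact baseline in the contact-point
#'   search.
#' @param free_eta see [fit_structural_damping()].
#' @return a list of class `sweep_analysis` with elements `contact`,
#'   `hertz`, `demod`, `spectrum`, `fit` and `delta0`.
#' @export
analyze_sweep_curve <- function(curve, drag = NULL, f_min = 1, f_max = 100,
                                f0 = 1, drift_correction = FALSE,
                                free_eta = FALSE) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(curve$segments)) curve <- segment_curve(curve)
  contact <- find_contact_point(curve, drift_correction = drift_correction)
  fi <- to_force_indentation(curve, contact)
  hertz <- fit_hertz(fi$delta, fi$force, curve$tip, refine_z0 = TRUE)
  # the refined shift s means the effective contact is at z0 - s
  z0 <- contact$z0 - hertz$z0_shift
  demod <- demodulate(curve, z0 = z0, baseline = contact$baseline)
  if (!is.null(drag)) demod <- correct_drag(demod, drag)
  spectrum <- complex_modulus(demod, curve$tip)
  fit <- fit_structural_damping(spectrum, f_min = f_min, f_max = f_max,
                                f0 = f0, free_eta = free_eta)
  structure(list(contact = contact, hertz = hertz, demod = demod,
                 spectrum = spectrum, fit = fit,
                 delta0 = attr(spectrum, "delta0")),
            class = "sweep_analysis")
}

#' @export
print.sweep_analysis <- function(x, ...) {
  cat("<sweep_analysis>\n  ")
  print(x$hertz)
  cat("  ")
  print(x$fit)
  cat(sprintf("  operating indentation %.3g m, contact quality %.3f\n",
              x$delta0, x$contact$quality))
  invisible(x)
}
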