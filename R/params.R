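#' Viscoelastic parameter set of a single cell
#'
#' The per-cell ground truth used by the synthetic generator and recovered by
#' the analysis pipeline: an apparent Young's modulus for quasi-static Hertz
#' ramps and the structural damping triplet (`E0`, `alpha`, `mu`) governing
#' the frequency-dependent complex modulus
#' \eqn{E^*(f) = E_0 (1 + i\eta)(f/f_0)^\alpha + i 2\pi f \mu},
#' \eqn{\eta = \tan(\pi\alpha/2)}.
#'
#' @param E_app apparent Young's modulus, Pa.
#' @param E0 structural-damping scale factor at the reference frequency, Pa.
#' @param alpha power-law exponent, in `[0, 1)`.
#' @param mu Newtonian viscosity, Pa s, `>= 0`.
#' @param label cohort name (e.g. `"healthy"`, `"scar"`, `"dupuytren"`,
#'   `"custom"`).
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(E_app, E0, alpha, mu, label = "custom") {
  if (!is.finite(E_app) || E_app <= 0) stop("E_app must be > 0", call. = FALSE)
  if (!is.finite(E0) || E0 <= 0) stop("E0 must be > 0", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must be in [0, 1)", call. = FALSE)
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0", call. = FALSE)
  structure(list(E_app = E_app, E0 = E0, alpha = alpha, mu = mu,
                 label = as.character(label)),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "<cell_params> %s: E_app = %.4g Pa, E0 = %.4g Pa, alpha = %.3g, mu = %.3g Pa.s\n",
    x$label, x$E_app, x$E0, x$alpha, x$mu))
  invisible(x)
}

#' Cohort median parameter presets for palmar fibroblasts
#'
#' Median viscoelastic parameters of healthy, scar and Dupuytren palmar
#' fibroblasts (n = 90 cells per cohort): apparent Young's modulus, the
#' structural-damping scale factor `E0` and Newtonian viscosity `mu` from the
#' cohort sweep-frequency fits, and the power-law exponent `alpha`. The scar
#' viscosity is not reported alongside the healthy (7 Pa s) and Dupuytren
#' (13 Pa s) values and is set to the midpoint 10 Pa s.
#'
#' @param label cohort to return; one of `"healthy"`, `"scar"`, `"dupuytren"`.
#' @return a [cell_params()] object.
#' @examples
#' cohort_preset("healthy")
#' @export
cohort_preset <- function(label = c("healthy", "scar", "dupuytren")) {
  label <- match.arg(label)
  switch(label,
    healthy   = cell_params(E_app = 3345, E0 = 3308, alpha = 0.11, mu = 7,
                            label = "healthy"),
    scar      = cell_params(E_app = 3940, E0 = 3077, alpha = 0.13, mu = 10,
                            label = "scar"),
    dupuytren = cell_params(E_app = 5364, E0 = 4259, alpha = 0.12, mu = 13,
                            label = "dupuytren"))
}

#' Reference cohort medians as a table
#'
#' Cohort medians of apparent Young's modulus, storage and loss modulus at
#' 1 Hz, loss tangent at 1 Hz and power-law exponent for the three fibroblast
#' cohorts (n = 90 each), as used to parameterize the synthetic generator.
#'
#' @return a data.frame with one row per cohort.
#' @export
cohort_reference_table <- function() {
  data.frame(
    label         = c("healthy", "scar", "dupuytren"),
    E_app_pa      = c(3345, 3940, 5364),
    E_storage_1hz = c(3260, 3024, 4260),
    E_loss_1hz    = c(473, 576, 742),
    loss_tangent  = c(0.18, 0.19, 0.18),
    alpha         = c(0.11, 0.13, 0.12),
    E0_pa         = c(3308, 3077, 4259),
    mu_pa_s       = c(7, 10, 13),
    n_cells       = c(90L, 90L, 90L),
    stringsAsFactors = FALSE
  )
}

#' Cohort generator configuration
#'
#' Defines the ground-truth distribution a synthetic cohort is drawn from:
#' per-parameter medians and a common lognormal dispersion. Each parameter of
#' each cell is drawn independently as
#' `median * exp(rnorm(1, 0, dispersion_sigma))`, so the population median of
#' every parameter converges to the configured median.
#'
#' @param medians a [cell_params()] giving cohort medians.
#' @param dispersion_sigma standard deviation of the natural-log draws,
#'   dimensionless, `>= 0`.
#' @param n_cells number of cells, `>= 1`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(medians, dispersion_sigma = 0.5, n_cells = 90L) {
  if (!inherits(medians, "cell_params"))
    stop("medians must be a cell_params object", call. = FALSE)
  if (!is.finite(dispersion_sigma) || dispersion_sigma < 0)
    stop("dispersion_sigma must be >= 0", call. = FALSE)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  structure(list(medians = medians, dispersion_sigma = dispersion_sigma,
                 n_cells = n_cells),
            class = "cohort_config")
}

#' Inhibitor treatment configuration for time-course generation
#'
#' Parameterizes post-inhibitor stiffness kinetics and the mixture of cell
#' fates. Responding cells drop to `drop_factor` of baseline at
#' `response_time`; recovering cells then relax exponentially back toward
#' `recovery_fraction` of baseline; dying cells fall to a death floor and
#' stay there (and may detach from the substrate).
#'
#' @param concentration inhibitor concentration, micromolar (a label carried
#'   through to outputs).
#' @param fractions length-3 numeric `(dead, recovered, no_change)`, summing
#'   to 1.
#' @param drop_factor multiplicative stiffness drop for responding cells,
#'   in (0, 1).
#' @param recovery_fraction fraction of baseline stiffness regained
#'   asymptotically by recovering cells, in (0, 1].
#' @param response_time minutes after addition at which the drop completes.
#' @param recovery_tau exponential recovery time constant, minutes.
#' @param n_timepoints number of post-addition measurements (two
#'   pre-addition measurements are always generated).
#' @param timepoint_spacing minutes between consecutive measurements.
#' @param death_floor stiffness floor for dying cells, fraction of baseline.
#' @param detach_prob probability that a dying cell detaches from the
#'   substrate.
#' @param noise_sigma standard deviation of multiplicative lognormal
#'   measurement noise on tracked stiffness.
#' @return an object of class `treatment_config`.
#' @export
treatment_config <- function(concentration = 3,
                             fractions = c(dead = 0.60, recovered = 0.10,
                                           no_change = 0.30),
                             drop_factor = 0.1,
                             recovery_fraction = 0.5,
                             response_time = 30,
                             recovery_tau = 45,
                             n_timepoints = 5L,
                             timepoint_spacing = 30,
                             death_floor = 0.05,
                             detach_prob = 0.5,
                             noise_sigma = 0.05) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(!is.finite(fractions)) ||
      any(fractions < 0))
    stop("fractions must be 3 non-negative numbers", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  if (!is.finite(drop_factor) || drop_factor <= 0 || drop_factor >= 1)
    stop("drop_factor must be in (0, 1)", call. = FALSE)
  if (!is.finite(recovery_fraction) || recovery_fraction <= 0 ||
      recovery_fraction > 1)
    stop("recovery_fraction must be in (0, 1]", call. = FALSE)
  if (!is.finite(timepoint_spacing) || timepoint_spacing <= 0)
    stop("timepoint_spacing must be > 0", call. = FALSE)
  structure(list(concentration = concentration,
                 fractions = c(dead = fractions[1], recovered = fractions[2],
                               no_change = fractions[3]),
                 drop_factor = drop_factor,
                 recovery_fraction = recovery_fraction,
                 response_time = response_time,
                 recovery_tau = recovery_tau,
                 n_timepoints = as.integer(n_timepoints),
                 timepoint_spacing = timepoint_spacing,
                 death_floor = death_floor,
                 detach_prob = detach_prob,
                 noise_sigma = noise_sigma),
            class = "treatment_config")
}

#' Reference fate proportions after inhibitor addition
#'
#' Observed percentages of cells that die, recover or show no change after
#' addition of 1 or 3 micromolar of the MLCK inhibitor ML-7, per cohort
#' (n = 15 cells at 1 uM, n = 20 at 3 uM).
#'
#' @return a data.frame with columns label, concentration_um, dead, recovered,
#'   no_change (percent), n.
#' @export
fate_reference_table <- function() {
  data.frame(
    label = rep(c("healthy", "scar", "dupuytren"), 2),
    concentration_um = rep(c(1, 3), each = 3),
    dead      = c(20,  0, 13, 39, 39, 60),
    recovered = c(20, 20, 47, 34, 25, 10),
    no_change = c(60, 80, 40, 27, 36, 30),
    n = rep(c(15L, 20L), each = 3),
    stringsAsFactors = FALSE
  )
}
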