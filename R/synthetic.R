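#' Instrument configuration for the synthetic generator
#'
#' Describes the virtual AFM used to synthesize force curves: cantilever,
#' tip, approach/trigger settings, sampling, dwell, sweep schedule,
#' hydrodynamic drag and force noise. Defaults emulate sweep-frequency
#' rheology on fibroblasts with a stiff short cantilever (k = 0.1 N/m,
#' 75 nm paraboloid tip), 1 nN trigger force (operating indentation above
#' 500 nm for kPa-scale cells), 1 s dwell and a 1 Hz--1 kHz stepped sweep.
#'
#' @param spring_constant cantilever spring constant, N/m.
#' @param tip a [tip_geometry()].
#' @param trigger_force approach trigger threshold, N.
#' @param approach_velocity z ramp speed, m/s.
#' @param sample_rate sampling rate, Hz; must be at least 10x the highest
#'   sweep frequency.
#' @param dwell_time stress-relaxation hold before modulation, s.
#' @param sweep a [sweep_schedule()].
#' @param modulation_amplitude z oscillation amplitude, m; overrides the
#'   schedule amplitude when given.
#' @param b0 hydrodynamic drag coefficient at zero tip--surface separation,
#'   N s/m.
#' @param noise_sd_force additive Gaussian force noise (applied to the
#'   deflection channel as force / k), N.
#' @param pre_contact z travel before the contact point, m.
#' @param max_ramp maximum approach ramp length, m (trigger must be reached
#'   within it).
#' @param relaxation_factor dwell force plateau as a fraction of the trigger
#'   force.
#' @param relaxation_tau dwell relaxation time constant, s.
#' @param hysteresis_factor retract stiffness scale (> 1 makes the retract
#'   curve stiffer than the approach, mimicking viscoelastic hysteresis).
#' @return an object of class `instrument_config`.
#' @export
instrument_config <- function(spring_constant = 0.1,
                              tip = tip_geometry("paraboloid",
                                                 radius = 75e-9,
                                                 poisson = 0.5),
                              trigger_force = 1e-9,
                              approach_velocity = 20e-6,
                              sample_rate = 1e4,
                              dwell_time = 1,
                              sweep = sweep_schedule(),
                              modulation_amplitude = NULL,
                              b0 = 2e-6,
                              noise_sd_force = 25e-12,
                              pre_contact = 1.5e-6,
                              max_ramp = 6e-6,
                              relaxation_factor = 0.8,
                              relaxation_tau = 0.15,
                              hysteresis_factor = 1.3) {
  stopifnot(spring_constant > 0, trigger_force > 0, approach_velocity > 0,
            dwell_time >= 0, b0 >= 0, noise_sd_force >= 0,
            relaxation_factor > 0, relaxation_factor <= 1,
            hysteresis_factor >= 1)
  if (!inherits(tip, "tip_geometry")) stop("tip must be a tip_geometry")
  if (!inherits(sweep, "sweep_schedule"))
    stop("sweep must be a sweep_schedule")
  if (!is.null(modulation_amplitude)) {
    stopifnot(modulation_amplitude > 0)
    sweep$amplitude <- modulation_amplitude
  }
  if (sample_rate < 10 * max(sweep$frequencies))
    stop("sample_rate must be >= 10x the highest sweep frequency",
         call. = FALSE)
  structure(list(spring_constant = spring_constant, tip = tip,
                 trigger_force = trigger_force,
                 approach_velocity = approach_velocity,
                 sample_rate = sample_rate, dwell_time = dwell_time,
                 sweep = sweep, b0 = b0, noise_sd_force = noise_sd_force,
                 pre_contact = pre_contact, max_ramp = max_ramp,
                 relaxation_factor = relaxation_factor,
                 relaxation_tau = relaxation_tau,
                 hysteresis_factor = hysteresis_factor),
            class = "instrument_config")
}

#' Structural damping complex modulus
#'
#' Evaluates \eqn{E^*(f) = E_0 (1 + i\eta)(f/f_0)^\alpha + i 2\pi f \mu}
#' with hysteresivity \eqn{\eta = \tan(\pi\alpha/2)} coupled to the power-law
#' exponent. At `f = f0` the storage modulus equals `E0`; the Newtonian term
#' `mu` contributes only to the loss modulus.
#'
#' @param f frequency, Hz.
#' @param E0 scale factor at `f0`, Pa.
#' @param alpha power-law exponent in `[0, 1)`.
#' @param mu Newtonian viscosity, Pa s.
#' @param f0 reference frequency, Hz (default 1).
#' @param eta hysteresivity; defaults to `tan(pi * alpha / 2)` and should
#'   only be overridden for the free-eta model variant.
#' @return complex vector of moduli, Pa.
#' @export
structural_damping_modulus <- function(f, E0, alpha, mu, f0 = 1,
                                       eta = tan(pi * alpha / 2)) {
  if (any(f <= 0)) stop("f must be > 0", call. = FALSE)
  E0 * (1 + 1i * eta) * (f / f0)^alpha + 1i * 2 * pi * f * mu
}

# solve k d = coef * E * (zrel - d)^p for d, vectorized Newton iteration;
# zrel > 0 in contact
solve_contact_deflection <- function(zrel, k, coefE, p) {
  d <- rep(0, length(zrel))
  for (iter in 1:80) {
    delta <- pmax(zrel - d, 0)
    fx <- k * d - coefE * delta^p
    fp <- k + coefE * p * delta^(p - 1)
    step <- fx / fp
    d <- pmin(pmax(d - step, 0), zrel)
    if (max(abs(step)) < 1e-18) break
  }
  d
}

#' Generate a synthetic sweep-frequency force curve
#'
#' Produces a four-segment force curve with known ground truth: a
#' quasi-static Hertz approach ramp (apparent modulus `cell$E_app`) up to the
#' trigger force, a dwell during which the force relaxes toward a plateau, a
#' stepped-frequency modulation whose in-contact force response follows the
#' linearized contact transfer of the structural damping model plus the
#' hydrodynamic drag term \eqn{i \omega b_0 \hat z}, and a retract ramp with
#' configurable hysteresis. Generator ground truth (contact point, operating
#' indentation, per-frequency transfer) is stored in `meta$truth`.
#'
#' @param cell a [cell_params()].
#' @param instrument an [instrument_config()].
#' @param seed optional integer seed for the force noise.
#' @return a [force_curve()] with segments and schedule attached.
#' @export
generate_force_curve <- function(cell, instrument, seed = NULL) {
  stopifnot(inherits(cell, "cell_params"),
            inherits(instrument, "instrument_config"))
  if (!is.null(seed)) set.seed(seed)
  ins <- instrument
  fs <- ins$sample_rate
  dt <- 1 / fs
  k <- ins$spring_constant
  law <- contact_law(ins$tip)
  coefE <- law$coef * cell$E_app
  p <- law$exponent

  # contact geometry at trigger
  z0 <- ins$pre_contact
  d_trig <- ins$trigger_force / k
  delta_trig <- (ins$trigger_force / coefE)^(1 / p)
  z_trig <- z0 + delta_trig + d_trig
  if (z_trig > ins$max_ramp)
    stop("trigger force not reached within ramp range", call. = FALSE)

  # approach: strictly increasing z ramp sampled at fs, ending exactly at
  # the trigger position
  n_app <- ceiling(z_trig / (ins$approach_velocity * dt))
  z_app <- z_trig - ins$approach_velocity * dt * ((n_app - 1L):0L)
  d_app <- rep(0, n_app)
  in_contact <- z_app > z0
  d_app[in_contact] <- solve_contact_deflection(z_app[in_contact] - z0, k,
                                                coefE, p)

  # dwell: constant z, force relaxes toward plateau
  n_dwell <- max(2L, round(ins$dwell_time * fs))
  t_dwell <- seq_len(n_dwell) * dt
  d_plateau <- ins$relaxation_factor * d_trig
  d_dwell <- d_plateau + (d_trig - d_plateau) * exp(-t_dwell /
                                                    ins$relaxation_tau)
  # operating point for the modulation (carrier frozen at end of dwell)
  d_hold <- d_plateau + (d_trig - d_plateau) *
    exp(-ins$dwell_time / ins$relaxation_tau)
  delta0 <- (z_trig - z0) - d_hold

  # modulation: stepped-frequency sinusoid about the operating point
  sched <- ins$sweep
  a <- sched$amplitude
  n_mod <- ceiling(sched$total_time * fs - 1e-9)
  win <- schedule_windows(sched, 1L, fs)
  win$end[nrow(win)] <- n_mod
  z_mod <- numeric(n_mod)
  d_mod <- numeric(n_mod)
  transfer <- complex(length(win$f))
  Estar <- structural_damping_modulus(win$f, cell$E0, cell$alpha, cell$mu)
  for (j in seq_len(nrow(win))) {
    idx <- seq.int(win$start[j], win$end[j])
    tau <- (idx - 1L) / fs - win$t_start[j]
    H <- contact_stiffness(Estar[j], ins$tip, delta0)
    Td <- (H + 1i * 2 * pi * win$f[j] * ins$b0) / (k + H)
    transfer[j] <- Td
    phase <- 2 * pi * win$f[j] * tau
    z_mod[idx] <- a * sin(phase)
    d_mod[idx] <- a * Im(Td * exp(1i * phase))
  }
  z_mod <- z_trig + z_mod
  d_mod <- d_hold + d_mod

  # retract: strictly decreasing ramp out with scaled stiffness (hysteresis)
  n_ret <- max(2L, floor(z_trig / (ins$approach_velocity * dt)))
  z_ret <- z_trig - seq_len(n_ret) * ins$approach_velocity * dt
  z_ret <- pmax(z_ret, 0)
  d_ret <- rep(0, n_ret)
  rc <- z_ret > z0
  d_ret[rc] <- solve_contact_deflection(z_ret[rc] - z0, k,
                                        ins$hysteresis_factor * coefE, p)

  z <- c(z_app, rep(z_trig, n_dwell), z_mod, z_ret)
  d <- c(d_app, d_dwell, d_mod, d_ret)
  n <- length(z)
  if (ins$noise_sd_force > 0)
    d <- d + stats::rnorm(n, 0, ins$noise_sd_force / k)
  time <- (seq_len(n) - 1L) * dt
  segs <- data.frame(
    segment = c("approach", "dwell", "modulation", "retract"),
    start = as.integer(c(1L, n_app + 1L, n_app + n_dwell + 1L,
                         n_app + n_dwell + n_mod + 1L)),
    end = as.integer(c(n_app, n_app + n_dwell, n_app + n_dwell + n_mod, n)),
    stringsAsFactors = FALSE)
  force_curve(time, z, d, spring_constant = k, tip = ins$tip,
              segments = segs, schedule = sched,
              meta = list(
                label = cell$label,
                truth = list(cell = unclass(cell), z0 = z0,
                             delta0 = delta0, d_hold = d_hold, b0 = ins$b0,
                             transfer = list(f = win$f,
                                             re = Re(transfer),
                                             im = Im(transfer)))))
}

#' Draw a synthetic cohort of cell parameter sets
#'
#' Each parameter of each cell is drawn independently as
#' `median * exp(rnorm(1, 0, dispersion_sigma))`, giving lognormal
#' per-parameter dispersion about the cohort medians (the population median
#' of each parameter equals the configured median). `alpha` draws are capped
#' just below 1 to preserve the model domain.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return a list of [cell_params()] of length `config$n_cells`.
#' @export
draw_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  m <- config$medians
  s <- config$dispersion_sigma
  n <- config$n_cells
  draws <- matrix(exp(stats::rnorm(4L * n, 0, s)), nrow = n)
  lapply(seq_len(n), function(i) {
    cell_params(E_app = m$E_app * draws[i, 1],
                E0 = m$E0 * draws[i, 2],
                alpha = min(m$alpha * draws[i, 3], 0.999),
                mu = m$mu * draws[i, 4],
                label = m$label)
  })
}

#' Generate out-of-contact drag calibration curves
#'
#' Oscillates the cantilever at several tip--surface separations without
#' touching the sample. The out-of-contact force response is
#' \eqn{\hat F = i \omega b(h) \hat z} with either a saturating height
#' dependence \eqn{b(h) = b_0 h_s / (h_s + h)} or a linear one
#' \eqn{b(h) = b_0 (1 - h / h_s)} (clipped at 0); both decrease with height
#' and extrapolate to `b0` at contact.
#'
#' @param instrument an [instrument_config()]; `b0` and the sweep schedule
#'   are taken from it.
#' @param heights tip--surface separations, m, all > 0.
#' @param seed optional seed for force noise.
#' @param drag_model `"saturating"` or `"linear"`.
#' @param h_scale height scale `h_s`, m.
#' @return a list of elements `list(height =, curve =)`.
#' @export
generate_drag_curves <- function(instrument, heights, seed = NULL,
                                 drag_model = c("saturating", "linear"),
                                 h_scale = 10e-6) {
  stopifnot(inherits(instrument, "instrument_config"))
  drag_model <- match.arg(drag_model)
  if (length(heights) < 1L) stop("heights must be non-empty", call. = FALSE)
  if (any(heights <= 0)) stop("heights must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ins <- instrument
  fs <- ins$sample_rate
  sched <- ins$sweep
  a <- sched$amplitude
  k <- ins$spring_constant
  n_mod <- ceiling(sched$total_time * fs - 1e-9)
  win <- schedule_windows(sched, 1L, fs)
  win$end[nrow(win)] <- n_mod
  lapply(heights, function(h) {
    b_h <- switch(drag_model,
                  saturating = ins$b0 * h_scale / (h_scale + h),
                  linear = ins$b0 * max(0, 1 - h / h_scale))
    z <- numeric(n_mod)
    d <- numeric(n_mod)
    for (j in seq_len(nrow(win))) {
      idx <- seq.int(win$start[j], win$end[j])
      tau <- (idx - 1L) / fs - win$t_start[j]
      phase <- 2 * pi * win$f[j] * tau
      Td <- 1i * 2 * pi * win$f[j] * b_h / k
      z[idx] <- a * sin(phase)
      d[idx] <- a * Im(Td * exp(1i * phase))
    }
    if (ins$noise_sd_force > 0)
      d <- d + stats::rnorm(n_mod, 0, ins$noise_sd_force / k)
    curve <- force_curve((seq_len(n_mod) - 1L) / fs, z, d,
                         spring_constant = k, tip = ins$tip,
                         segments = data.frame(segment = "modulation",
                                               start = 1L, end = n_mod,
                                               stringsAsFactors = FALSE),
                         schedule = sched,
                         meta = list(height = h, truth = list(b = b_h)))
    list(height = h, curve = curve)
  })
}

#' Generate an inhibitor-response time course with known fates
#'
#' For each cell a fate (`dead`, `recovered`, `no_change`) is drawn from
#' `treatment$fractions`. Tracked stiffness is the storage modulus at 1 Hz
#' (equal to the cell's `E0` at baseline). Two pre-addition measurements are
#' always generated; responding cells descend linearly to the drop level at
#' `response_time`, recovering cells then relax exponentially toward
#' `recovery_fraction` of baseline, dying cells stay at the death floor and
#' may detach. Loss tangent moves opposite to stiffness
#' (`lt = lt0 * r^-0.25`). All measurements carry multiplicative lognormal
#' noise.
#'
#' @param cohort a list of [cell_params()] (e.g. from [draw_cohort()]).
#' @param treatment a [treatment_config()].
#' @param seed integer seed.
#' @return a list of `cell_track` objects; each carries its ground-truth
#'   fate in `$fate_true`.
#' @export
generate_timecourse <- function(cohort, treatment, seed = 1L) {
  stopifnot(inherits(treatment, "treatment_config"))
  set.seed(seed)
  tr <- treatment
  dtp <- tr$timepoint_spacing
  tps <- c(-2 * dtp, -dtp, seq_len(tr$n_timepoints) * dtp)
  fates <- sample(c("dead", "recovered", "no_change"),
                  size = length(cohort), replace = TRUE,
                  prob = tr$fractions)
  lapply(seq_along(cohort), function(i) {
    cell <- cohort[[i]]
    fate <- fates[i]
    r_det <- vapply(tps, function(t) {
      if (t <= 0 || fate == "no_change") return(1)
      low <- if (fate == "dead") tr$death_floor else tr$drop_factor
      if (t < tr$response_time) {
        1 + (low - 1) * t / tr$response_time
      } else if (fate == "dead") {
        low
      } else {
        low + (tr$recovery_fraction - low) *
          (1 - exp(-(t - tr$response_time) / tr$recovery_tau))
      }
    }, numeric(1))
    noise <- exp(stats::rnorm(length(tps), 0, tr$noise_sigma))
    e1 <- cell$E0 * r_det * noise
    lt0 <- tan(pi * cell$alpha / 2) + 2 * pi * cell$mu / cell$E0
    lt <- lt0 * r_det^(-0.25) *
      exp(stats::rnorm(length(tps), 0, tr$noise_sigma))
    detached <- rep(FALSE, length(tps))
    if (fate == "dead" && stats::runif(1) < tr$detach_prob)
      detached[tps >= tr$response_time + dtp] <- TRUE
    cell_track(cell_id = sprintf("%s_%04d", cell$label, i),
               label = cell$label,
               concentration = tr$concentration,
               timepoints = tps,
               E_storage_1hz = e1,
               loss_tangent = lt,
               detached = detached,
               fate_true = fate)
  })
}
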