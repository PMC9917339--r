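#' Segment a force curve from z-piezo kinematics
#'
#' Detects the four experiment phases: a monotone approach ramp, a
#' constant-z dwell, a hold with z oscillation (the sweep-frequency
#' modulation) and a monotone retract ramp. The approach is the initial run
#' of positive z increments and the retract the final run of negative ones.
#' The dwell/modulation boundary cannot be read off the kinematics alone --
#' the lowest sweep frequency starts with sub-resolution z increments -- so
#' when the curve carries a [sweep_schedule()] the modulation is the
#' `ceiling(total_time * sample_rate)` samples preceding the retract;
#' otherwise the boundary is placed at the first z excursion beyond the
#' stationarity tolerance. Idempotent: re-running re-derives the same
#' markers.
#'
#' @param curve a [force_curve()].
#' @return the curve with `$segments` set.
#' @export
segment_curve <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z_piezo
  n <- length(z)
  dz <- diff(z)
  zrange <- diff(range(z))
  if (zrange == 0)
    stop("segmentation error: z channel is constant", call. = FALSE)
  tol <- 1e-4 * zrange
  up <- dz > tol
  down <- dz < -tol
  if (!up[1])
    stop("segmentation error: curve does not start with an approach ramp",
         call. = FALSE)
  approach_end <- which(!up)[1] # sample index of last approach sample
  if (is.na(approach_end))
    stop("segmentation error: z never stops rising (no dwell segment)",
         call. = FALSE)
  if (!down[n - 1L])
    stop("segmentation error: curve does not end with a retract ramp",
         call. = FALSE)
  last_nondown <- max(which(!down))
  retract_start <- last_nondown + 1L
  if (retract_start <= approach_end + 1L)
    stop("segmentation error: no dwell segment", call. = FALSE)
  # the trailing down-run may capture one final modulation sample that
  # happens to descend into the retract; the true retract is a constant-
  # velocity line anchored one step below the hold level, so test both
  # candidate boundaries against that line
  z_hold <- z[approach_end + 1L]
  if (retract_start + 3L <= n) {
    vhat <- stats::median(-dz[retract_start:(n - 1L)])
    mis <- function(r) abs(z[r] - (z_hold - vhat)) +
      abs(z[r + 1L] - (z_hold - 2 * vhat))
    if (mis(retract_start + 1L) < mis(retract_start))
      retract_start <- retract_start + 1L
  }

  fs <- 1 / stats::median(diff(curve$time))
  if (!is.null(curve$schedule)) {
    n_mod <- ceiling(curve$schedule$total_time * fs - 1e-9)
    mod_start <- retract_start - n_mod
  } else {
    hold <- z[approach_end + 1L]
    off <- abs(z[(approach_end + 1L):(retract_start - 1L)] - hold) > tol
    first_off <- which(off)[1]
    if (is.na(first_off))
      stop("segmentation error: no modulation segment", call. = FALSE)
    mod_start <- approach_end + first_off
  }
  if (mod_start <= approach_end + 1L || mod_start >= retract_start)
    stop("segmentation error: no dwell segment", call. = FALSE)
  segs <- data.frame(
    segment = c("approach", "dwell", "modulation", "retract"),
    start = as.integer(c(1L, approach_end + 1L, mod_start, retract_start)),
    end = as.integer(c(approach_end, mod_start - 1L, retract_start - 1L, n)),
    stringsAsFactors = FALSE)
  validate_segments(segs, n)
  curve$segments <- segs
  curve
}
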