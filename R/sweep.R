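#' Stepped-frequency sweep schedule
#'
#' The modulation segment of a sweep-frequency force curve holds the tip in
#' contact and oscillates z at a sequence of discrete frequencies, each for an
#' integer number of cycles so that per-frequency demodulation is well posed.
#' The default schedule spans 1 Hz to 1 kHz at 9 logarithmically spaced
#' frequencies per decade with 2 cycles each, totalling 8.85 s -- the closest
#' integer-cycle approximation to the nominal 8.7 s sweep duration.
#'
#' @param f_min,f_max sweep band, Hz.
#' @param per_decade frequencies per decade (log spacing).
#' @param cycles integer cycles per frequency (scalar or per-frequency
#'   vector), `>= 2`.
#' @param amplitude z modulation amplitude, m.
#' @param frequencies optional explicit frequency vector (Hz, strictly
#'   increasing); overrides `f_min`/`f_max`/`per_decade`.
#' @return an object of class `sweep_schedule` with fields `frequencies`,
#'   `cycles`, `amplitude`, `durations` (s per frequency) and `total_time`.
#' @examples
#' s <- sweep_schedule()
#' s$total_time # 8.85 s
#' @export
sweep_schedule <- function(f_min = 1, f_max = 1000, per_decade = 9,
                           cycles = 2L, amplitude = 20e-9,
                           frequencies = NULL) {
  if (is.null(frequencies)) {
    n_dec <- log10(f_max / f_min)
    k <- seq(0, round(n_dec * per_decade))
    frequencies <- f_min * 10^(k / per_decade)
  }
  frequencies <- as.numeric(frequencies)
  if (any(diff(frequencies) <= 0))
    stop("sweep_schedule: frequencies must be strictly increasing",
         call. = FALSE)
  if (any(frequencies <= 0)) stop("frequencies must be > 0", call. = FALSE)
  cycles <- as.integer(rep_len(cycles, length(frequencies)))
  if (any(cycles < 2L))
    stop("sweep_schedule: need at least 2 cycles per frequency",
         call. = FALSE)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("sweep_schedule: amplitude must be > 0", call. = FALSE)
  durations <- cycles / frequencies
  structure(list(frequencies = frequencies, cycles = cycles,
                 amplitude = amplitude, durations = durations,
                 total_time = sum(durations)),
            class = "sweep_schedule")
}

#' @export
print.sweep_schedule <- function(x, ...) {
  cat(sprintf(
    "<sweep_schedule> %d frequencies, %.3g-%.3g Hz, %.3g s total, a = %.3g m\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$total_time, x$amplitude))
  invisible(x)
}

# per-frequency sample-index windows within a modulation segment that starts
# at index `start` and is sampled at `fs`; half-open in time, inclusive index
# ranges
schedule_windows <- function(schedule, start, fs) {
  t_edges <- c(0, cumsum(schedule$durations))
  data.frame(
    f = schedule$frequencies,
    cycles = schedule$cycles,
    t_start = t_edges[-length(t_edges)],
    start = start + ceiling(t_edges[-length(t_edges)] * fs - 1e-9),
    end = start + ceiling(t_edges[-1] * fs - 1e-9) - 1L)
}
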