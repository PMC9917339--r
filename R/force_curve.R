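#' Force-curve container
#'
#' One AFM indentation experiment: synchronous time, z-piezo and cantilever
#' deflection channels plus the instrument metadata needed for analysis.
#' z increases toward the sample; deflection is in meters (force is
#' `k * deflection` after baseline subtraction); all units SI.
#'
#' @param time time channel, s, strictly increasing.
#' @param z_piezo z-piezo extension channel, m.
#' @param deflection cantilever deflection channel, m.
#' @param spring_constant cantilever spring constant k, N/m.
#' @param tip a [tip_geometry()].
#' @param segments optional data.frame with columns `segment`
#'   (`approach`, `dwell`, `modulation`, `retract`), `start`, `end`
#'   (1-based inclusive sample indices, disjoint and ordered).
#' @param schedule optional [sweep_schedule()] describing the modulation
#'   segment.
#' @param meta named list of provenance metadata (cell id, cohort label,
#'   timepoint, treatment, generator ground truth for synthetic curves, ...).
#' @return an object of class `force_curve`.
#' @export
force_curve <- function(time, z_piezo, deflection, spring_constant, tip,
                        segments = NULL, schedule = NULL, meta = list()) {
  n <- length(time)
  if (length(z_piezo) != n || length(deflection) != n)
    stop("force_curve: channels must have equal length", call. = FALSE)
  if (n < 2L) stop("force_curve: need at least 2 samples", call. = FALSE)
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("force_curve: spring_constant must be > 0", call. = FALSE)
  if (!inherits(tip, "tip_geometry"))
    stop("force_curve: tip must be a tip_geometry", call. = FALSE)
  if (!is.null(segments)) validate_segments(segments, n)
  structure(list(time = as.numeric(time), z_piezo = as.numeric(z_piezo),
                 deflection = as.numeric(deflection),
                 spring_constant = spring_constant, tip = tip,
                 segments = segments, schedule = schedule, meta = meta),
            class = "force_curve")
}

validate_segments <- function(segments, n) {
  if (!is.data.frame(segments) ||
      !all(c("segment", "start", "end") %in% names(segments)))
    stop("segments must be a data.frame with segment/start/end", call. = FALSE)
  if (any(segments$start < 1L) || any(segments$end > n) ||
      any(segments$start > segments$end))
    stop("segment ranges out of bounds", call. = FALSE)
  o <- order(segments$start)
  s <- segments[o, ]
  if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
    stop("segment ranges overlap", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, %.3g s, k = %.3g N/m, tip = %s\n",
              length(x$time), diff(range(x$time)), x$spring_constant,
              x$tip$kind))
  if (!is.null(x$segments)) {
    with(x$segments, cat(paste0("  ", format(segment, width = 10),
                                " [", start, ", ", end, "]\n"), sep = ""))
  } else cat("  (unsegmented)\n")
  invisible(x)
}

segment_range <- function(curve, name) {
  if (is.null(curve$segments))
    stop("curve has no segments; run segment_curve() first", call. = FALSE)
  row <- curve$segments[curve$segments$segment == name, ]
  if (nrow(row) != 1L)
    stop("curve has no '", name, "' segment", call. = FALSE)
  seq.int(row$start, row$end)
}

#' Write a force curve to the plain-text container format
#'
#' The container is a pair of files: `<path>.csv` holding the channel table
#' (`time_s,z_m,deflection_m`, full double precision so that the round trip
#' is bit exact) and `<path>.json` holding spring constant, tip geometry,
#' segment index ranges (0-based, half-open), sweep schedule and provenance.
#'
#' @param curve a [force_curve()].
#' @param path file stem; `.csv`/`.json` are appended.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  csv <- paste0(path, ".csv")
  con <- file(csv, "w")
  on.exit(close(con))
  writeLines("time_s,z_m,deflection_m", con)
  writeLines(sprintf("%.17g,%.17g,%.17g",
                     curve$time, curve$z_piezo, curve$deflection), con)
  meta <- list(spring_constant = curve$spring_constant,
               tip = tip_to_list(curve$tip))
  if (!is.null(curve$segments)) {
    # 0-based half-open [start, end) ranges in the sidecar
    meta$segments <- list(segment = as.list(curve$segments$segment),
                          start = as.list(curve$segments$start - 1L),
                          end = as.list(curve$segments$end))
  }
  if (!is.null(curve$schedule)) meta$schedule <- unclass(curve$schedule)
  if (length(curve$meta)) meta$provenance <- curve$meta
  # I(17): 17 significant digits, enough for a bit-exact double round trip
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

tip_to_list <- function(tip) {
  out <- list(kind = tip$kind, poisson = tip$poisson)
  if (!is.null(tip$radius)) out$radius <- tip$radius
  if (!is.null(tip$half_angle)) out$half_angle <- tip$half_angle
  out
}

tip_from_list <- function(x) {
  if (is.null(x$kind))
    stop("force-curve metadata: tip 'kind' missing", call. = FALSE)
  if (!x$kind %in% c("sphere", "paraboloid", "cone"))
    stop("force-curve metadata: unknown tip kind '", x$kind, "'",
         call. = FALSE)
  tip_geometry(x$kind, radius = x$radius, half_angle = x$half_angle,
               poisson = if (is.null(x$poisson)) 0.5 else x$poisson)
}

#' Read a force curve from the plain-text container format
#'
#' @param path file stem as used by [write_force_curve()].
#' @return a [force_curve()].
#' @export
read_force_curve <- function(path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  if (!file.exists(csv)) stop("missing channel file: ", csv, call. = FALSE)
  if (!file.exists(js)) stop("missing metadata file: ", js, call. = FALSE)
  tab <- utils::read.csv(csv, colClasses = "numeric")
  for (ch in c("time_s", "z_m", "deflection_m"))
    if (!ch %in% names(tab))
      stop("force-curve container: missing channel '", ch, "'", call. = FALSE)
  if (anyNA(tab$time_s) || anyNA(tab$z_m) || anyNA(tab$deflection_m)) {
    short <- names(tab)[vapply(tab, anyNA, logical(1))]
    stop("force-curve container: truncated channel(s): ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (is.null(meta$spring_constant))
    stop("force-curve metadata: spring_constant missing", call. = FALSE)
  if (is.null(meta$tip))
    stop("force-curve metadata: tip missing", call. = FALSE)
  segments <- NULL
  if (!is.null(meta$segments)) {
    segments <- data.frame(
      segment = unlist(meta$segments$segment),
      start = as.integer(unlist(meta$segments$start)) + 1L,
      end = as.integer(unlist(meta$segments$end)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  schedule <- NULL
  if (!is.null(meta$schedule)) {
    schedule <- structure(as.list(meta$schedule), class = "sweep_schedule")
  }
  force_curve(tab$time_s, tab$z_m, tab$deflection_m,
              spring_constant = meta$spring_constant,
              tip = tip_from_list(as.list(meta$tip)),
              segments = segments, schedule = schedule,
              meta = if (is.null(meta$provenance)) list()
                     else as.list(meta$provenance))
}
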