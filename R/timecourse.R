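#' Per-cell stiffness track across an inhibitor time course
#'
#' One cell's tracked rheology before and after drug addition: timepoints in
#' minutes relative to addition (negative = pre-treatment), the storage
#' modulus at 1 Hz and the loss tangent at each timepoint, and a per-
#' timepoint detachment flag. The baseline is the mean pre-treatment
#' storage modulus.
#'
#' @param cell_id cell identifier.
#' @param label cohort label.
#' @param concentration inhibitor concentration, micromolar.
#' @param timepoints minutes relative to addition, strictly increasing,
#'   at least one negative (pre-treatment).
#' @param E_storage_1hz storage modulus at 1 Hz per timepoint, Pa.
#' @param loss_tangent loss tangent at 1 Hz per timepoint (optional).
#' @param detached logical per timepoint.
#' @param fate_true optional generator ground-truth fate.
#' @return an object of class `cell_track`.
#' @export
cell_track <- function(cell_id, label, concentration, timepoints,
                       E_storage_1hz, loss_tangent = NULL,
                       detached = NULL, fate_true = NULL) {
  o <- order(timepoints)
  timepoints <- timepoints[o]
  if (any(diff(timepoints) <= 0))
    stop("cell_track: timepoints must be strictly increasing", call. = FALSE)
  if (!any(timepoints < 0))
    stop("cell_track: no pre-treatment timepoint", call. = FALSE)
  n <- length(timepoints)
  if (length(E_storage_1hz) != n)
    stop("cell_track: E_storage_1hz length mismatch", call. = FALSE)
  E_storage_1hz <- E_storage_1hz[o]
  if (is.null(loss_tangent)) loss_tangent <- rep(NA_real_, n)
  else loss_tangent <- loss_tangent[o]
  if (is.null(detached)) detached <- rep(FALSE, n) else detached <- detached[o]
  baseline <- mean(E_storage_1hz[timepoints < 0])
  structure(list(cell_id = cell_id, label = label,
                 concentration = concentration, timepoints = timepoints,
                 E_storage_1hz = E_storage_1hz, loss_tangent = loss_tangent,
                 detached = detached, baseline = baseline,
                 fate_true = fate_true),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf(
    "<cell_track> %s (%s, %g uM): %d timepoints, baseline %.3g Pa%s\n",
    x$cell_id, x$label, x$concentration, length(x$timepoints), x$baseline,
    if (!is.null(x$fate_true)) paste0(", true fate ", x$fate_true) else ""))
  invisible(x)
}

#' Assemble cell tracks from fit tables and a manifest
#'
#' Joins a table of per-curve fit results to a manifest mapping curve ids to
#' cells and timepoints, and builds one [cell_track()] per cell. Rows are
#' sorted by timepoint; cells without a pre-treatment timepoint are dropped
#' and reported in the `rejected` attribute.
#'
#' @param fits data.frame with columns `curve_id`, `E_storage_1hz` and
#'   optionally `loss_tangent`, `detached`.
#' @param manifest data.frame with columns `curve_id`, `cell_id`, `label`,
#'   `timepoint_min` and optionally `concentration`.
#' @return a list of [cell_track()]; rejected cell ids (no pre-treatment
#'   point) in `attr(, "rejected")`.
#' @export
build_tracks <- function(fits, manifest) {
  stopifnot(is.data.frame(fits), is.data.frame(manifest))
  need <- c("curve_id", "cell_id", "label", "timepoint_min")
  if (!all(need %in% names(manifest)))
    stop("build_tracks: manifest needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tab <- merge(fits, manifest, by = "curve_id")
  if (!"loss_tangent" %in% names(tab)) tab$loss_tangent <- NA_real_
  if (!"detached" %in% names(tab)) tab$detached <- FALSE
  if (!"concentration" %in% names(tab)) tab$concentration <- NA_real_
  rejected <- character()
  tracks <- list()
  for (id in unique(tab$cell_id)) {
    sub <- tab[tab$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$timepoint_min), , drop = FALSE]
    if (!any(sub$timepoint_min < 0)) {
      rejected <- c(rejected, id)
      next
    }
    tracks[[length(tracks) + 1L]] <-
      cell_track(id, sub$label[1], sub$concentration[1],
                 sub$timepoint_min, sub$E_storage_1hz, sub$loss_tangent,
                 sub$detached)
  }
  if (length(rejected))
    warning("build_tracks: rejected (no pre-treatment point): ",
            paste(rejected, collapse = ", "), call. = FALSE)
  attr(tracks, "rejected") <- rejected
  tracks
}

#' Fate-classification thresholds
#'
#' Operational rules for assigning dead / recovered / no-change from the
#' relative stiffness trajectory `r(t) = E'(1 Hz, t) / baseline`. A cell is
#' unchanged if `r` never falls below `nochange_floor`; dead if it detaches,
#' or ends below `death_floor` without a meaningful rise after its minimum;
#' recovered if it softened and then rose by at least
#' `max(min_rise, recovery_coef * (1 - min r))`.
#'
#' @param nochange_floor minimum relative stiffness compatible with "no
#'   change".
#' @param death_floor final relative stiffness below which a non-recovering
#'   cell is dead.
#' @param min_rise smallest absolute post-minimum rise of `r` that counts
#'   as recovery.
#' @param recovery_coef fraction of the lost stiffness that must be
#'   regained.
#' @return a named list of thresholds.
#' @export
fate_thresholds <- function(nochange_floor = 0.7, death_floor = 0.2,
                            min_rise = 0.1, recovery_coef = 0.15) {
  list(nochange_floor = nochange_floor, death_floor = death_floor,
       min_rise = min_rise, recovery_coef = recovery_coef)
}

#' Classify the fate of one cell track
#'
#' Deterministic rule evaluation on the post-addition relative stiffness
#' trajectory; the returned label carries a trace of the criterion that
#' fired. Tracks with a single post-addition timepoint are classified with a
#' low-confidence flag.
#'
#' @param track a [cell_track()].
#' @param thresholds a [fate_thresholds()] list.
#' @return an object of class `fate_label`: `fate` (one of `dead`,
#'   `recovered`, `no_change`), `trace`, `low_confidence`.
#' @export
classify_fate <- function(track, thresholds = fate_thresholds()) {
  stopifnot(inherits(track, "cell_track"))
  th <- thresholds
  post <- track$timepoints > 0
  r <- track$E_storage_1hz[post] / track$baseline
  n_post <- sum(post)
  if (n_post < 1L)
    stop("classify_fate: no post-addition timepoints", call. = FALSE)
  low_conf <- n_post < 2L
  r_min <- min(r)
  i_min <- which.min(r)
  r_final <- r[n_post]
  rise <- if (i_min < n_post) max(r[i_min:n_post]) - r_min else 0
  fate <- NULL
  trace <- NULL
  if (any(track$detached[post])) {
    fate <- "dead"
    trace <- "detached flag set at a post-addition timepoint"
  } else if (r_min >= th$nochange_floor) {
    fate <- "no_change"
    trace <- sprintf("min r = %.3f >= nochange_floor %.2f", r_min,
                     th$nochange_floor)
  } else if (rise >= max(th$min_rise, th$recovery_coef * (1 - r_min))) {
    fate <- "recovered"
    trace <- sprintf(
      "min r = %.3f < %.2f and post-minimum rise %.3f >= %.3f",
      r_min, th$nochange_floor, rise,
      max(th$min_rise, th$recovery_coef * (1 - r_min)))
  } else if (r_final < th$death_floor) {
    fate <- "dead"
    trace <- sprintf("final r = %.3f < death_floor %.2f with rise %.3f < %.3f",
                     r_final, th$death_floor, rise,
                     max(th$min_rise, th$recovery_coef * (1 - r_min)))
  } else {
    fate <- "no_change"
    trace <- sprintf(
      "softened (min r = %.3f) but neither recovered nor below death floor",
      r_min)
  }
  structure(list(fate = fate, trace = trace, low_confidence = low_conf),
            class = "fate_label")
}

#' @export
print.fate_label <- function(x, ...) {
  cat(sprintf("<fate_label> %s%s -- %s\n", x$fate,
              if (x$low_confidence) " (low confidence)" else "", x$trace))
  invisible(x)
}

#' Per-cohort fate percentages
#'
#' Classifies every track and tabulates dead / recovered / no-change
#' percentages per cohort and concentration.
#'
#' @param tracks list of [cell_track()].
#' @param thresholds a [fate_thresholds()] list.
#' @return a data.frame with label, concentration, n and the three
#'   percentages (summing to 100 per row).
#' @export
fate_table <- function(tracks, thresholds = fate_thresholds()) {
  if (length(tracks) < 1L) stop("fate_table: no tracks", call. = FALSE)
  fates <- vapply(tracks, function(tr)
    classify_fate(tr, thresholds)$fate, character(1))
  labs <- vapply(tracks, function(tr) tr$label, character(1))
  conc <- vapply(tracks, function(tr) as.numeric(tr$concentration),
                 numeric(1))
  key <- paste(labs, conc, sep = "@")
  rows <- lapply(unique(key), function(kk) {
    sel <- key == kk
    n <- sum(sel)
    data.frame(label = labs[sel][1], concentration = conc[sel][1], n = n,
               dead = 100 * sum(fates[sel] == "dead") / n,
               recovered = 100 * sum(fates[sel] == "recovered") / n,
               no_change = 100 * sum(fates[sel] == "no_change") / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Long-format loss-tangent versus storage trajectories
#'
#' Flattens tracks into one row per (cell, timepoint) with the storage
#' modulus at 1 Hz and the loss tangent, for trajectory scatter plots of
#' drug response (time encoded in minutes after addition).
#'
#' @param tracks list of [cell_track()].
#' @return a data.frame with cell_id, label, concentration, time_min,
#'   E_storage_1hz, loss_tangent, detached.
#' @export
trajectory_scatter <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(cell_id = tr$cell_id, label = tr$label,
               concentration = tr$concentration,
               time_min = tr$timepoints,
               E_storage_1hz = tr$E_storage_1hz,
               loss_tangent = tr$loss_tangent,
               detached = tr$detached,
               stringsAsFactors = FALSE)
  }))
}
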