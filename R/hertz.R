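#' Fit a Hertz contact model to force--indentation data
#'
#' Least-squares fit of `F = c(tip) * E * delta^p` with `p = 3/2` for
#' spheres/paraboloids and `p = 2` for cones. The amplitude is linear given
#' the contact-point offset, so the fit is a closed-form projection;
#' `refine_z0 = TRUE` additionally optimizes a contact-point shift `s`
#' (indentation becomes `delta + s`), which absorbs residual contact-point
#' error.
#'
#' @param delta indentation, m (from [to_force_indentation()]).
#' @param force force, N.
#' @param tip a [tip_geometry()].
#' @param depth_range optional `c(min, max)` indentation window, m; default
#'   uses the full post-contact range.
#' @param refine_z0 optimize a contact-point shift jointly with E.
#' @return an object of class `hertz_fit` with `E_apparent` (Pa), `z0_shift`
#'   (m), `fit_range`, `rms_residual` (N) and `n_points`.
#' @export
fit_hertz <- function(delta, force, tip, depth_range = NULL,
                      refine_z0 = FALSE) {
  stopifnot(inherits(tip, "tip_geometry"), length(delta) == length(force))
  keep <- is.finite(delta) & is.finite(force)
  if (!is.null(depth_range))
    keep <- keep & delta >= depth_range[1] & delta <= depth_range[2]
  delta <- delta[keep]
  force <- force[keep]
  if (length(delta) < 10L)
    stop("fit_hertz: need at least 10 points in the fit range",
         call. = FALSE)
  law <- contact_law(tip)
  p <- law$exponent

  amp_fit <- function(s) {
    x <- pmax(delta + s, 0)^p
    cxx <- sum(x * x)
    if (cxx <= 0) return(list(amp = 0, rss = sum(force^2)))
    amp <- sum(x * force) / cxx
    list(amp = amp, rss = sum((force - amp * x)^2))
  }

  s <- 0
  if (refine_z0) {
    span <- diff(range(delta))
    opt <- stats::optimize(function(s) amp_fit(s)$rss,
                           c(-0.5 * span, 0.5 * span),
                           tol = .Machine$double.eps^0.5 * span)
    if (opt$objective <= amp_fit(0)$rss) s <- opt$minimum
  }
  fit <- amp_fit(s)
  E <- fit$amp / law$coef
  if (!is.finite(E) || E <= 0)
    stop("fit_hertz: non-physical fit (E <= 0)", call. = FALSE)
  structure(list(E_apparent = E, z0_shift = s,
                 fit_range = range(delta + s),
                 rms_residual = sqrt(fit$rss / length(delta)),
                 n_points = length(delta), tip = tip),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E = %.4g Pa over [%.3g, %.3g] m (%d pts, rms %.3g N)\n",
    x$E_apparent, x$fit_range[1], x$fit_range[2], x$n_points,
    x$rms_residual))
  invisible(x)
}

#' Median and quartiles of a force map's Hertz fits
#'
#' Summarizes the apparent Young's modulus over the curves of a force map by
#' the median with 25/75 percentiles, using the linear-interpolation
#' quantile rule (R type 7).
#'
#' @param fits a list of [fit_hertz()] results, or a numeric vector of
#'   moduli in Pa.
#' @return named numeric `c(median, p25, p75)` in Pa.
#' @export
map_median <- function(fits) {
  E <- if (is.numeric(fits)) fits
       else vapply(fits, function(f) f$E_apparent, numeric(1))
  if (length(E) < 1L) stop("map_median: empty input", call. = FALSE)
  q <- stats::quantile(E, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], p25 = q[2], p75 = q[3])
}
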