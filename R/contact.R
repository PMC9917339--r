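#' Locate the tip--sample contact point on the approach segment
#'
#' Piecewise model scan: for each candidate contact position z0 the approach
#' force is modeled as a baseline (constant, or linear in z when
#' `drift_correction = TRUE`) before contact and baseline + Hertz arc
#' `c * ((z - z0) - d)^p` after contact. The candidate minimizing the total
#' squared force residual wins; a continuous golden-section refinement
#' between neighboring samples then sharpens z0 below sample resolution
#' (on noise-free curves the residual vanishes at the true contact point, so
#' the refinement is essentially exact). Quality is
#' `1 - rss_best / rss_baseline_only`, near 1 for a clear contact.
#'
#' @param curve a segmented [force_curve()].
#' @param drift_correction fit a linear (rather than constant) pre-contact
#'   baseline.
#' @param refine continuous refinement of z0 between grid points.
#' @param min_baseline_points minimum pre-contact points required.
#' @return an object of class `contact_point` with fields `index` (sample
#'   index in the curve), `z0` (m), `method`, `quality`, and the baseline
#'   coefficients used for force correction.
#' @export
find_contact_point <- function(curve, drift_correction = FALSE,
                               refine = TRUE, min_baseline_points = 10L) {
  stopifnot(inherits(curve, "force_curve"))
  idx <- segment_range(curve, "approach")
  z <- curve$z_piezo[idx]
  d <- curve$deflection[idx]
  f <- curve$spring_constant * d
  n <- length(z)
  law <- contact_law(curve$tip)
  p <- law$exponent

  rss_at <- function(z0) {
    pre <- z <= z0
    npre <- sum(pre)
    if (npre < min_baseline_points || npre > n - 5L) return(Inf)
    if (drift_correction) {
      bfit <- stats::lm.fit(cbind(1, z[pre]), f[pre])
      base <- bfit$coefficients[1] + bfit$coefficients[2] * z
    } else {
      base <- rep(mean(f[pre]), n)
    }
    fc <- f - base
    delta <- pmax((z - z0) - fc / curve$spring_constant, 0)
    post <- !pre
    x <- delta[post]^p
    cxx <- sum(x * x)
    chat <- if (cxx > 0) max(sum(x * fc[post]) / cxx, 0) else 0
    sum(fc[pre]^2) + sum((fc[post] - chat * x)^2)
  }

  stride <- max(1L, n %/% 400L)
  cand <- unique(c(seq(min_baseline_points + 1L, n - 5L, by = stride),
                   n - 5L))
  rss <- vapply(z[cand], rss_at, numeric(1))
  if (all(!is.finite(rss)))
    stop("contact-point error: approach has no usable baseline",
         call. = FALSE)
  best <- cand[which.min(rss)]

  # reject flat curves with no post-contact force rise
  base_level <- mean(f[seq_len(min_baseline_points)])
  rise <- max(f) - base_level
  spread <- stats::sd(f[seq_len(min_baseline_points)])
  if (rise <= max(5 * spread, 1e-13))
    stop("contact-point error: no contact detected (flat force curve)",
         call. = FALSE)

  lo <- z[max(best - stride, min_baseline_points + 1L)]
  hi <- z[min(best + stride, n - 5L)]
  z0 <- z[best]
  if (refine && hi > lo) {
    opt <- stats::optimize(rss_at, c(lo, hi), tol = .Machine$double.eps^0.5 *
                             max(abs(hi), 1e-9))
    if (opt$objective <= min(rss, na.rm = TRUE)) z0 <- opt$minimum
  }
  rss0 <- rss_at(z0)
  pre <- z <= z0
  base_coef <- if (drift_correction) {
    stats::lm.fit(cbind(1, z[pre]), f[pre])$coefficients
  } else c(mean(f[pre]), 0)
  rss_null <- sum((f - mean(f))^2)
  structure(list(index = idx[which(z > z0)[1]], z0 = z0,
                 method = if (drift_correction)
                   "piecewise baseline(linear)+hertz" else
                   "piecewise baseline+hertz",
                 quality = max(0, 1 - rss0 / rss_null),
                 baseline = unname(base_coef)),
            class = "contact_point")
}

#' @export
print.contact_point <- function(x, ...) {
  cat(sprintf("<contact_point> z0 = %.4g m (sample %d), quality %.3f, %s\n",
              x$z0, x$index, x$quality, x$method))
  invisible(x)
}

#' Convert a curve to force--indentation coordinates
#'
#' Applies the standard AFM relations on the post-contact part of the
#' approach: force `F = k * d` with the pre-contact baseline subtracted from
#' the deflection, and indentation `delta = (z - z0) - d`.
#'
#' @param curve a segmented [force_curve()].
#' @param contact a [find_contact_point()] result.
#' @return a data.frame with columns `delta` (m) and `force` (N) for
#'   post-contact approach samples.
#' @export
to_force_indentation <- function(curve, contact) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(contact, "contact_point"))
  idx <- segment_range(curve, "approach")
  z <- curve$z_piezo[idx]
  f <- curve$spring_constant * curve$deflection[idx]
  base <- contact$baseline[1] + contact$baseline[2] * z
  fc <- f - base
  d <- fc / curve$spring_constant
  post <- z > contact$z0
  data.frame(delta = (z[post] - contact$z0) - d[post], force = fc[post])
}
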