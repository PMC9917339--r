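#' Summarize a cohort of per-cell parameters
#'
#' Median and 25/75 percentiles (linear-interpolation quantile rule, R type
#' 7) of each rheological parameter per cohort, plus a log10 histogram of
#' each parameter -- the representation conventionally used for cell
#' stiffness, whose distribution is close to lognormal.
#'
#' @param records a data.frame with a `label` column and numeric parameter
#'   columns (e.g. `E_app`, `E0`, `alpha`, `mu`, `E_storage_1hz`).
#' @param params parameter columns to summarize; default all numeric
#'   columns.
#' @param bins number of log-histogram bins.
#' @return a list of class `cohort_summary`: `stats` (long data.frame with
#'   label, parameter, n, median, p25, p75) and `histograms` (per
#'   label/parameter bin edges and counts, log10 axis).
#' @export
summarize_cohort <- function(records, params = NULL, bins = 20L) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  if (nrow(records) < 1L) stop("summarize_cohort: empty cohort",
                               call. = FALSE)
  if (is.null(params))
    params <- setdiff(names(records)[vapply(records, is.numeric,
                                            logical(1))], "label")
  out <- list()
  hists <- list()
  for (lab in unique(records$label)) {
    sub <- records[records$label == lab, , drop = FALSE]
    for (pm in params) {
      x <- sub[[pm]]
      x <- x[is.finite(x)]
      q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
      out[[length(out) + 1L]] <- data.frame(
        label = lab, parameter = pm, n = length(x),
        median = q[1], p25 = q[2], p75 = q[3],
        stringsAsFactors = FALSE)
      if (all(x > 0)) {
        h <- graphics::hist(log10(x), breaks = bins, plot = FALSE)
        hists[[paste(lab, pm, sep = ".")]] <-
          list(log10_breaks = h$breaks, counts = h$counts)
      }
    }
  }
  structure(list(stats = do.call(rbind, out), histograms = hists),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

# exact null distribution of the rank-sum of sample a by enumeration of all
# choose(n, na) assignments of the pooled (mid)ranks; handles ties
ranksum_exact_p <- function(ra, rb) {
  na <- length(ra)
  pooled <- c(ra, rb)
  w <- sum(ra)
  sets <- utils::combn(length(pooled), na)
  ws <- colSums(matrix(pooled[sets], nrow = na))
  eps <- 1e-9
  p_le <- mean(ws <= w + eps)
  p_ge <- mean(ws >= w - eps)
  min(1, 2 * min(p_le, p_ge))
}

# exact paired signed-rank p by enumeration of all 2^n sign assignments
signrank_exact_p <- function(r, sgn) {
  n <- length(r)
  v <- sum(r[sgn > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  eps <- 1e-9
  p_le <- mean(vs <= v + eps)
  p_ge <- mean(vs >= v - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Rank-based two-sample test
#'
#' Two-sided rank test comparing cohort medians: `mode = "independent"` is
#' the Wilcoxon--Mann--Whitney rank-sum test, `mode = "paired"` the Wilcoxon
#' signed-rank test on within-pair differences. Small samples
#' (`min(n) <= exact_limit`, default 8) use exact enumeration of the null
#' distribution (midranks, so ties are handled exactly); larger samples use
#' the normal approximation with tie-corrected variance and continuity
#' correction. Two-sided p-values are twice the smaller tail, capped at 1.
#'
#' @param a,b numeric samples (equal length for `mode = "paired"`).
#' @param mode `"independent"` or `"paired"`.
#' @param exact_limit largest `min(n)` for which enumeration is used.
#' @return a list with `p_value`, `statistic` (rank sum of `a`, or the
#'   positive-rank sum of differences), `mode` and `exact`.
#' @export
rank_test <- function(a, b, mode = c("independent", "paired"),
                      exact_limit = 8L) {
  mode <- match.arg(mode)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 1L || length(b) < 1L)
    stop("rank_test: samples must be non-empty", call. = FALSE)
  if (mode == "independent") {
    r <- rank(c(a, b))
    ra <- r[seq_along(a)]
    rb <- r[-seq_along(a)]
    w <- sum(ra)
    exact <- min(length(a), length(b)) <= exact_limit
    if (exact) {
      p <- ranksum_exact_p(ra, rb)
    } else {
      n1 <- length(a); n2 <- length(b); n <- n1 + n2
      mu <- n1 * (n + 1) / 2
      ties <- table(r)
      sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) /
                                  (n * (n - 1)))
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    list(p_value = p, statistic = w, mode = mode, exact = exact)
  } else {
    if (length(a) != length(b))
      stop("rank_test: paired mode requires equal lengths", call. = FALSE)
    d <- a - b
    d <- d[d != 0]
    if (length(d) == 0L)
      return(list(p_value = 1, statistic = 0, mode = mode, exact = TRUE))
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    exact <- length(d) <= exact_limit
    if (exact) {
      p <- signrank_exact_p(r, sign(d))
    } else {
      n <- length(d)
      mu <- n * (n + 1) / 4
      ties <- table(r)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(ties^3 - ties) / 48
      z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    list(p_value = p, statistic = v, mode = mode, exact = exact)
  }
}

#' Cohen's d effect size
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((na-1) sa^2 + (nb-1) sb^2) / (na + nb - 2))`. The sign
#' convention is first minus second.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return the effect size d.
#' @export
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("cohens_d: need at least 2 values per sample", call. = FALSE)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("cohens_d: zero pooled SD, d undefined", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Significance and effect-size annotations
#'
#' Applies the conventional marks: `"*"` iff `p < 0.01`; `"#"` iff
#' `0.2 < |d| < 0.5` (medium effect); `"##"` iff `0.5 < |d| < 1.0` (large
#' effect). Inequalities are strict, so boundary values receive no mark.
#'
#' @param p p-value(s).
#' @param d Cohen's d value(s).
#' @return character vector of annotations (`""` when no mark applies),
#'   significance and effect marks concatenated.
#' @export
significance_marks <- function(p, d) {
  stopifnot(length(p) == length(d))
  star <- ifelse(p < 0.01, "*", "")
  eff <- ifelse(abs(d) > 0.2 & abs(d) < 0.5, "#",
                ifelse(abs(d) > 0.5 & abs(d) < 1.0, "##", ""))
  paste0(star, eff)
}

#' Pairwise cohort comparisons
#'
#' Runs [rank_test()] and [cohens_d()] on every pair of cohorts for one
#' per-cell statistic (typically the force-map median modulus) and annotates
#' the results with [significance_marks()].
#'
#' @param records data.frame with `label` and the value column.
#' @param value name of the numeric column to compare.
#' @param mode passed to [rank_test()].
#' @return a data.frame with one row per cohort pair: labels, n's, p_value,
#'   statistic, cohens_d and annotation.
#' @export
pairwise_tests <- function(records, value, mode = "independent") {
  stopifnot(is.data.frame(records), "label" %in% names(records),
            value %in% names(records))
  labs <- unique(records$label)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- records[[value]][records$label == pr[1]]
    y <- records[[value]][records$label == pr[2]]
    if (mode == "paired") {
      m <- min(length(x), length(y))
      x <- x[seq_len(m)]; y <- y[seq_len(m)]
    }
    tst <- rank_test(x, y, mode = mode)
    d <- cohens_d(x, y)
    data.frame(label_a = pr[1], label_b = pr[2],
               n_a = length(x), n_b = length(y),
               p_value = tst$p_value, statistic = tst$statistic,
               cohens_d = d,
               annotation = significance_marks(tst$p_value, d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
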