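test_that("tracks enforce pre-treatment baselines and time ordering", {
  expect_error(cell_track("c1", "healthy", 1, c(10, 20), c(1, 2) * 1e3),
               "pre-treatment")
  expect_error(cell_track("c1", "healthy", 1, c(-10, -10, 20),
                          c(1, 1, 2) * 1e3), "strictly increasing")
  tk <- cell_track("c1", "healthy", 1, c(30, -30, -60),
                   c(500, 3000, 3100))
  expect_equal(tk$timepoints, c(-60, -30, 30)) # sorted
  expect_equal(tk$baseline, 3050)
})

test_that("build_tracks joins fit tables to a manifest and sorts rows", {
  fits <- data.frame(curve_id = c("a3", "a1", "a2", "b1"),
                     E_storage_1hz = c(800, 3000, 3100, 2000))
  manifest <- data.frame(curve_id = c("a1", "a2", "a3", "b1"),
                         cell_id = c("A", "A", "A", "B"),
                         label = "dupuytren",
                         timepoint_min = c(-30, -15, 30, 45),
                         concentration = 1)
  expect_warning(tracks <- build_tracks(fits, manifest), "rejected.*B")
  expect_length(tracks, 1L)
  expect_identical(attr(tracks, "rejected"), "B")
  tr <- tracks[[1]]
  expect_equal(tr$timepoints, c(-30, -15, 30))
  expect_equal(tr$E_storage_1hz, c(3000, 3100, 800))
  expect_equal(tr$baseline, 3050)
  # shuffled input produces the identical track
  o <- c(3, 1, 4, 2)
  expect_warning(t2 <- build_tracks(fits[o, ], manifest[o, ]), "rejected")
  expect_equal(t2[[1]], tr)
})

test_that("fate rules classify canonical trajectories", {
  mk <- function(r, detached = rep(FALSE, length(r)))
    cell_track("x", "dupuytren", 1, c(-60, -30, seq_along(r) * 30),
               c(1, 1, r) * 2000, detached = c(FALSE, FALSE, detached))
  # constant stiffness -> no change
  expect_equal(classify_fate(mk(c(1, 1, 1, 1)))$fate, "no_change")
  # deep drop with no rise -> dead
  expect_equal(classify_fate(mk(c(0.1, 0.05, 0.05)))$fate, "dead")
  # the documented inhibitor trajectory 2 kPa -> 0.2 kPa -> 0.5 kPa
  expect_equal(classify_fate(mk(c(0.1, 0.25)))$fate, "recovered")
  # detachment dominates
  lab <- classify_fate(mk(c(0.9, 0.9), detached = c(FALSE, TRUE)))
  expect_equal(lab$fate, "dead")
  expect_match(lab$trace, "detached")
  # softened but neither dead nor recovered
  expect_equal(classify_fate(mk(c(0.5, 0.5, 0.55)))$fate, "no_change")
  # single post timepoint -> low confidence
  expect_true(classify_fate(mk(1))$low_confidence)
})

test_that("fate tables conserve percentages and close the generator loop", {
  coh <- draw_cohort(cohort_config(cohort_preset("healthy"), 0.3, 50),
                     seed = 21)
  all_nc <- treatment_config(fractions = c(0, 0, 1))
  tracks <- generate_timecourse(coh, all_nc, seed = 22)
  tab <- fate_table(tracks)
  expect_equal(tab$no_change, 100)
  expect_equal(tab$dead + tab$recovered + tab$no_change, 100)

  # mixed fates: realized proportions match the drawn ground truth and the
  # classifier reproduces the generator's intent
  tr <- treatment_config(fractions = c(0.6, 0.1, 0.3))
  coh2 <- draw_cohort(cohort_config(cohort_preset("dupuytren"), 0.3, 400),
                      seed = 23)
  tracks2 <- generate_timecourse(coh2, tr, seed = 24)
  truth <- vapply(tracks2, function(t) t$fate_true, character(1))
  called <- vapply(tracks2, function(t) classify_fate(t)$fate, character(1))
  expect_gt(mean(truth == called), 0.97)
  tab2 <- fate_table(tracks2)
  expect_equal(tab2$dead + tab2$recovered + tab2$no_change, 100)
})

test_that("realized fate draws stay within exact binomial bounds", {
  tr <- treatment_config(fractions = c(0.6, 0.1, 0.3))
  coh <- draw_cohort(cohort_config(cohort_preset("dupuytren"), 0.2, 2000),
                     seed = 31)
  tracks <- generate_timecourse(coh, tr, seed = 32)
  truth <- vapply(tracks, function(t) t$fate_true, character(1))
  n <- length(tracks)
  for (pr in list(c("dead", 0.6), c("recovered", 0.1),
                  c("no_change", 0.3))) {
    k <- sum(truth == pr[1])
    p <- as.numeric(pr[2])
    # independent 99% binomial interval via quantiles of the exact law
    lo <- qbinom(0.005, n, p)
    hi <- qbinom(0.995, n, p)
    expect_true(k >= lo && k <= hi,
                info = sprintf("%s: %d outside [%d, %d]", pr[1], k, lo, hi))
  }
})

test_that("trajectory tables are long-format with one row per timepoint", {
  coh <- draw_cohort(cohort_config(cohort_preset("dupuytren"), 0.2, 30),
                     seed = 41)
  tracks <- generate_timecourse(coh, treatment_config(), seed = 42)
  scat <- trajectory_scatter(tracks)
  expect_equal(nrow(scat),
               sum(vapply(tracks, function(t) length(t$timepoints),
                          integer(1))))
  # responding cells: storage drops and loss tangent rises right after
  # addition
  resp <- vapply(tracks, function(t) t$fate_true != "no_change", logical(1))
  tr1 <- tracks[resp][[1]]
  first_post <- which(tr1$timepoints > 0)[1]
  expect_lt(tr1$E_storage_1hz[first_post] / tr1$baseline, 0.7)
  expect_gt(tr1$loss_tangent[first_post],
            mean(tr1$loss_tangent[tr1$timepoints < 0]))
  # no-change cells stay inside the noise band
  nc <- tracks[!resp][[1]]
  expect_true(all(abs(log(nc$E_storage_1hz / nc$baseline)) < 0.3))
  # fate percentages invariant to track order and common time shift
  tab <- fate_table(tracks)
  expect_equal(fate_table(rev(tracks)), tab[nrow(tab):1, ],
               ignore_attr = TRUE)
})
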