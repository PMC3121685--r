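test_that("adaptation coefficient is the no-intercept regression slope", {
  s <- sin(seq(0, pi, length.out = 101))   # bell-like ideal profile
  expect_equal(adaptation_coefficient(s, s), 1)
  expect_equal(adaptation_coefficient(rep(0, 101), s), 0)
  # noise orthogonal to the ideal leaves the slope exactly 0.5
  noise <- cos(seq(0, 2 * pi, length.out = 101))
  noise <- noise - s * sum(noise * s) / sum(s^2)
  expect_equal(adaptation_coefficient(0.5 * s + noise, s), 0.5)
  # scale equivariance
  expect_equal(adaptation_coefficient(3 * s, s), 3)
  expect_equal(adaptation_coefficient(s, 2 * s), 0.5)
  expect_error(adaptation_coefficient(s, rep(0, 101)), "identically zero")
  expect_error(adaptation_coefficient(s, s[-1]), "equal length")
})

test_that("inclusion filter retains exactly the compliant trials", {
  set.seed(17)
  n <- 100
  trials <- tibble::tibble(
    trial = 1:n,
    peak_speed = runif(n, 0.25, 0.40),
    reaction_time = runif(n, 0.15, 0.60))
  # plant 3 speed violations and 2 reaction-time violations, no overlap
  trials$peak_speed[c(4, 40, 77)] <- c(0.60, 0.15, 0.56)
  trials$reaction_time[c(12, 90)] <- c(0.05, 3.1)
  kept <- apply_inclusion(trials)
  expect_equal(nrow(kept), 95)
  expect_false(any(c(4, 40, 77, 12, 90) %in% kept$trial))
  rep <- exclusion_report(kept)
  expect_equal(rep$n_speed_excluded, 3)
  expect_equal(rep$n_rt_excluded, 2)
  expect_equal(rep$n_retained, 95)
  # all-compliant set passes untouched
  ok <- apply_inclusion(trials[-c(4, 40, 77, 12, 90), ])
  expect_equal(nrow(ok), 95)
  expect_equal(exclusion_report(ok)$prop_retained, 1)
})

test_that("inclusion bounds are strict and missing kinematics are flagged", {
  trials <- tibble::tibble(
    peak_speed = c(0.2, 0.55, 0.3, NA),
    reaction_time = c(0.3, 0.3, 0.075, 0.3))
  kept <- apply_inclusion(trials)
  expect_equal(nrow(kept), 0)  # bound values themselves are excluded
  expect_equal(exclusion_report(kept)$n_missing_kinematics, 1)
})

test_that("generalization pattern aggregates clamp probes per direction", {
  cl <- tibble::tibble(
    target = rep(c(60, 90, 120), each = 4),
    field_mode = "clamp",
    adaptation_at_probe = c(rep(0, 4), 0.4, 0.6, 0.5, 0.5, rep(0.2, 4)))
  pat <- generalization_pattern(cl)
  expect_equal(pat$direction, c(60, 90, 120))
  expect_equal(pat$adaptation, c(0, 0.5, 0.2))
  expect_equal(pat$n, rep(4L, 3))
  expect_equal(pat$se[2], sd(c(0.4, 0.6, 0.5, 0.5)) / 2)
  # single-trial directions flag an undefined standard error
  expect_warning(generalization_pattern(
    tibble::tibble(target = 90, field_mode = "clamp",
                   adaptation_at_probe = 1)), "single-trial")
})

test_that("peak separation finds extrema of a difference of Gaussians", {
  # brute-force oracle on a fine grid, independent of the implementation
  sg <- 22.8
  f <- function(th) exp(-(th - 30)^2 / (2 * sg^2)) -
    exp(-(th + 30)^2 / (2 * sg^2))
  th_fine <- seq(-180, 179.99, by = 0.01)
  oracle <- th_fine[which.max(f(th_fine))] - th_fine[which.min(f(th_fine))]
  probe <- seq(-180, 179.5, by = 0.5)
  pat <- tibble::tibble(direction = probe, value = f(probe))
  sep <- peak_separation(pat)
  expect_equal(as.numeric(sep), oracle, tolerance = 0.02)
  expect_gt(as.numeric(sep), 60)  # outward skew beyond the 60-deg spacing
  # extrema symmetric about the centre for an antisymmetric pattern
  expect_equal(attr(sep, "peak"), -attr(sep, "trough"))
  expect_error(peak_separation(tibble::tibble(direction = probe, value = 0)),
               "bimodality")
})

test_that("pattern correlation is location-invariant Pearson r", {
  d <- seq(-120, 120, by = 30)
  p <- tibble::tibble(direction = d, adaptation = sin(d * pi / 90))
  expect_equal(pattern_correlation(p, p), 1)
  neg <- p; neg$adaptation <- -p$adaptation
  expect_equal(pattern_correlation(p, neg), -1)
  off <- p; off$adaptation <- p$adaptation + 5
  expect_equal(pattern_correlation(p, off), 1)
  flat <- p; flat$adaptation <- 0
  expect_error(pattern_correlation(p, flat), "zero-variance")
  expect_error(pattern_correlation(p[1:2, ], p[1:2, ]), "3")
})

test_that("learning summaries average the stated probe windows", {
  ls <- learning_summary(rep(0.4, 10))
  expect_equal(ls$early, 0.4)
  expect_equal(ls$late, 0.4)
  up <- learning_summary(seq(0, 1, length.out = 20))
  expect_gt(up$late, up$early)
  expect_equal(nrow(tidy(up)), 20)
  expect_equal(glance(up)$early, up$early)
  expect_error(learning_summary(1:5), "6")
})
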