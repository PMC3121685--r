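test_that("interference schedule reproduces the published trial structure", {
  s <- interference_schedule(train_dir = 270, ratio_cw_ccw = c(7, 7),
                             seed = 11)
  expect_equal(sum(s$phase == "baseline"), 254)
  expect_equal(sum(s$phase == "training"), 672)
  expect_equal(sum(s$phase == "testing"), 160)
  expect_true(all(s$field_mode[s$phase == "testing"] == "clamp"))
  tr <- s[s$phase == "training", ]
  expect_equal(sum(tr$viscosity > 0), 336)  # exact 7:7 CW:CCW overall
  expect_equal(sum(tr$viscosity < 0), 336)
  # four testing blocks of exactly 40 consecutive clamp trials
  idx <- which(s$phase == "testing")
  starts <- idx[c(TRUE, diff(idx) > 1)]
  expect_length(starts, 4)
  expect_true(all(diff(starts) == 168 + 40))
  # training resumes after 168 trials between testing blocks
  expect_equal(starts[1], 254 + 168 + 1)
  # block lengths within 7 +/- 2 and strictly alternating fields
  for (seg_start in c(255, starts[1:3] + 40)) {
    seg <- s[seg_start:(seg_start + 167), ]
    blocks <- rle(seg$viscosity)
    expect_true(all(blocks$lengths >= 5 & blocks$lengths <= 9))
    expect_true(all(diff(sign(blocks$values)) != 0))
  }
  # field before each testing block balanced across the four blocks
  last_fields <- sign(s$viscosity[starts - 1])
  expect_equal(sum(last_fields > 0), 2)
  # baseline spread as evenly as possible over the nine directions
  counts <- table(s$target[s$phase == "baseline"])
  expect_length(counts, 9)
  expect_true(all(counts %in% c(28, 29)))
  # reproducible from the seed
  expect_identical(s, interference_schedule(train_dir = 270, seed = 11))
  expect_error(interference_schedule(ratio_cw_ccw = c(7, 8)), "14")
})

test_that("unbalanced ratios give exact per-cycle counts", {
  s <- interference_schedule(train_dir = 60, ratio_cw_ccw = c(5, 9),
                             seed = 2)
  tr <- s[s$phase == "training", ]
  expect_equal(sum(tr$viscosity > 0), 4 * 12 * 5)
  expect_equal(sum(tr$viscosity < 0), 4 * 12 * 9)
  # with a 5:9 ratio the jitter range collapses: blocks are exactly 5 and 9
  for (seg in split(tr, rep(1:4, each = 168))) {
    blocks <- rle(seg$viscosity)
    expect_true(all(blocks$lengths[blocks$values > 0] == 5))
    expect_true(all(blocks$lengths[blocks$values < 0] == 9))
  }
})

test_that("exponential smoothing recovers decay parameters", {
  n <- 1:125
  exact <- -17 * exp(-n / 8)
  sm <- smooth_error_history(exact)
  expect_equal(as.numeric(sm), exact, tolerance = 1e-6)
  # constant series: the large-tau limit returns the constant
  const <- smooth_error_history(rep(-5, 50))
  expect_equal(as.numeric(const), rep(-5, 50), tolerance = 0.05)
  # noisy decay: typical-case parameter recovery within the stated bands
  fits <- vapply(1:8, function(seed) {
    set.seed(seed)
    noisy <- -17 * exp(-n / 8) + rnorm(125, 0, 2)
    fit <- smooth_error_history(noisy)
    c(attr(fit, "a"), attr(fit, "tau"))
  }, numeric(2))
  expect_lt(median(abs(fits[1, ] - (-17))), 2)
  expect_lt(median(abs(fits[2, ] - 8) / 8), 0.25)
  expect_error(smooth_error_history(c(1, 2)), "3")
})

test_that("shifted-target schedules mirror about the desired direction", {
  sm <- c(-17, -15 * exp(-(2:125) / 10))
  sch <- shifted_schedules(90, sm, p_ec = 0.2, seed = 13)
  expect_named(sch, c("STT", "LST", "RST"))
  for (s in sch) {
    expect_equal(sum(s$phase == "baseline"), 75)
    expect_equal(sum(s$phase == "training"), 125)
    expect_true(all(s$target[s$field_mode == "clamp"] == 90))
  }
  ff <- sch$STT$field_mode == "curl"
  expect_true(all(sch$STT$target[ff] == 90))
  # LST and RST targets mirror: LST_n + RST_n = 2 * desired
  expect_equal(sch$LST$target[ff] + sch$RST$target[ff],
               rep(180, sum(ff)))
  # first force-field target: 90 - (-17) = 107 for LST, 73 for RST
  expect_equal(sch$LST$target[which(ff)[1]], 107)
  expect_equal(sch$RST$target[which(ff)[1]], 73)
  # zero shift collapses the three schedules onto STT
  sch0 <- shifted_schedules(90, 0, seed = 13)
  expect_identical(sch0$STT$target, sch0$LST$target)
  expect_identical(sch0$STT$target, sch0$RST$target)
  expect_error(shifted_schedules(90, 0, p_ec = 1.2), "0, 1")
})

test_that("error-clamp probes occur at the configured probability", {
  sch <- shifted_schedules(90, 0, p_ec = 0.2, n_baseline = 500,
                           n_training = 500, seed = 21)$STT
  p_hat <- mean(sch$field_mode == "clamp")
  expect_lt(abs(p_hat - 0.2), 0.05)
})

test_that("error-gain calibration hits the separation anchor", {
  sched <- interference_schedule(seed = 3)
  cfg <- calibrate_error_gain(sched, learning_params(), sim_config(),
                              target_separation = 25)
  rec <- simulate_experiment(sched, learning_params(), quiet_cfg(
    error_gain = cfg$error_gain), seed = 1)
  expect_equal(error_separation(rec), 25, tolerance = 0.02)
})

test_that("left-shifted training aligns actual motion with the goal", {
  params <- learning_params()
  cfg <- quiet_cfg(reference_viscosity = 22.5)
  stt <- shifted_schedules(90, 0, viscosity = 22.5, seed = 3)$STT
  pilot <- simulate_experiment(stt, params, cfg, seed = 1)
  tr <- pilot[pilot$phase == "training" & pilot$field_mode == "curl", ]
  sm <- smooth_error_history(tr$error, trials = tr$trial - 75,
                             eval_trials = 1:125)
  sch <- shifted_schedules(90, sm, viscosity = 22.5, seed = 3)
  mis <- vapply(sch, function(s) {
    r <- simulate_experiment(s, params, cfg, seed = 2)
    ff <- r[r$phase == "training" & r$field_mode == "curl", ]
    c(mean(ff$actual), mean(abs(ff$actual - 90)))
  }, numeric(2))
  # mean actual direction under LST within 2 degrees of the goal
  expect_lt(abs(mis[1, "LST"] - 90), 2)
  # RST misalignment about twice the STT misalignment
  expect_equal(unname(mis[2, "RST"] / mis[2, "STT"]), 2, tolerance = 0.25)
  expect_gt(mis[2, "STT"], mis[2, "LST"])
})
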