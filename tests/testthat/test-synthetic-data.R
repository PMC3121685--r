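test_that("subject datasets are deterministic and carry kinematics", {
  sched <- shifted_schedules(90, 0, seed = 5)$STT
  prof <- subject_profile("healthy")
  a <- generate_subject(prof, sched, seed = 42)
  b <- generate_subject(prof, sched, seed = 42)
  expect_identical(a$error, b$error)
  expect_identical(a$peak_speed, b$peak_speed)
  expect_identical(a$reaction_time, b$reaction_time)
  expect_true(all(c("movement_duration", "peak_speed",
                    "reaction_time") %in% names(a)))
  # peak speeds cluster near the task's mean peak speed
  expect_equal(median(a$peak_speed), 0.302, tolerance = 0.05)
  c <- generate_subject(prof, sched, seed = 43)
  expect_false(identical(a$error, c$error))
})

test_that("kinematic traces respect trajectory invariants", {
  sched <- mixed_schedule(12)
  prof <- subject_profile("healthy")
  subj <- generate_subject(prof, sched, seed = 9, keep_traces = TRUE)
  expect_true("trace" %in% names(subj))
  tr <- subj$trace[[1]]
  d <- sqrt(diff(range(tr$x))^2 + diff(range(tr$y))^2)
  expect_equal(d, 0.1, tolerance = 0.05)  # 1-mm jitter on a 10-cm reach
  # velocities consistent with position differences
  expect_equal(tr$vx[-nrow(tr)], diff(tr$x) / 0.005, tolerance = 1e-9)
  # clamp trials carry a lateral force profile
  icl <- which(subj$field_mode == "clamp")[1]
  expect_true(!is.null(subj$clamp_force[[icl]]))
})

test_that("planted kinematic outliers are exactly the excluded trials", {
  sched <- shifted_schedules(90, 0, seed = 5)$STT
  prof <- subject_profile("healthy")
  prof$speed_outlier_rate <- 0
  prof$rt_outlier_rate <- 0
  subj <- generate_subject(prof, sched, seed = 4)
  plant <- c(10, 50, 90, 130, 170, 190, 17, 33, 121, 161)
  subj$peak_speed[plant[1:5]] <- c(0.58, 0.17, 0.61, 0.19, 0.71)
  subj$reaction_time[plant[6:10]] <- c(0.06, 2.9, 0.05, 3.3, 0.02)
  kept <- apply_inclusion(subj)
  expect_equal(nrow(kept), nrow(subj) - 10)
  expect_false(any(plant %in% kept$trial))
  expect_equal(exclusion_report(kept)$n_speed_excluded, 5)
  expect_equal(exclusion_report(kept)$n_rt_excluded, 5)
})

test_that("cohorts reduce to subjects and shrink standard errors", {
  sched <- shifted_schedules(90, 0, seed = 5)$STT
  prof <- subject_profile("healthy")
  one <- generate_cohort(1, prof, sched, master_seed = 8, jitter_sd = 0)
  set.seed(8)
  seed1 <- sample.int(.Machine$integer.max - 1L, 1)
  solo <- generate_subject(prof, sched, seed = seed1)
  expect_equal(one$error, solo$error)
  # cohort-mean SE shrinks roughly like 1/sqrt(n)
  ses <- vapply(c(4, 16, 64), function(n) {
    co <- generate_cohort(n, prof, sched, master_seed = 12)
    cl <- co[co$field_mode == "clamp" & co$phase == "training", ]
    m <- tapply(cl$adaptation_at_probe, cl$subject, mean)
    sd(m) / sqrt(n)
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_equal(ses[1] / ses[3], 4, tolerance = 0.6)
})

test_that("the impaired preset learns less and errs more", {
  prof_h <- subject_profile("healthy")
  prof_i <- subject_profile("impaired")
  expect_lt(prof_i$params$gain, prof_h$params$gain)
  expect_gt(prof_i$config$motor_noise_sd, prof_h$config$motor_noise_sd)
  sched <- shifted_schedules(90, 0, viscosity = 22.5, seed = 5)$STT
  late_err <- vapply(list(prof_h, prof_i), function(p) {
    p$config$reference_viscosity <- 22.5
    co <- generate_cohort(6, p, sched, master_seed = 6)
    ff <- co[co$phase == "training" & co$field_mode == "curl" &
               co$trial > 150, ]
    mean(abs(ff$error))
  }, numeric(1))
  expect_gt(late_err[2], late_err[1])
})

test_that("the shifted-training advantage is amplified by impairment", {
  adv <- lapply(c("healthy", "impaired"), function(lab) {
    pr <- subject_profile(lab)
    r <- run_exp2(n_subjects = 10, n_pilot = 8, params = pr$params,
                  cfg = pr$config, seed = 4)
    s <- r$summary[r$summary$hypothesis == "MRL", ]
    e <- function(g) s$early[s$paradigm == g]
    l <- function(g) s$late[s$paradigm == g]
    c(early_rel = (e("LST") - e("STT")) / e("STT"),
      late_rel = (l("LST") - l("STT")) / l("STT"))
  })
  # relative LST-over-STT advantage larger early and persisting later
  expect_gt(adv[[2]]["early_rel"], adv[[1]]["early_rel"])
  expect_gt(adv[[2]]["late_rel"], adv[[1]]["late_rel"])
})

test_that("subject datasets serialize to CSV + JSON", {
  sched <- mixed_schedule(8)
  subj <- generate_subject(subject_profile("healthy"), sched, seed = 2,
                           keep_traces = TRUE)
  dir <- withr::local_tempdir()
  write_subject_dataset(subj, dir)
  expect_true(file.exists(file.path(dir, "trials.csv")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
  expect_length(list.files(file.path(dir, "traces")), 8)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 2)
  expect_equal(meta$label, "healthy")
  back <- read_trial_table(file.path(dir, "trials.csv"))
  expect_equal(nrow(back), 8)
})

test_that("fitting improves on its starting point and returns sane values", {
  cfg <- sim_config(reference_viscosity = 22.5)
  sched <- stt_generalization_schedule(viscosity = 22.5, seed = 7)
  coh <- generate_cohort(4, subject_profile("healthy", config = cfg),
                         sched, master_seed = 11)
  fit <- fit_learning_params(coh, cfg = cfg)
  expect_s3_class(fit, "learning_params")
  expect_true(fit$retention > 0.8 && fit$retention <= 1)
  expect_true(fit$gain > 0)
  expect_true(fit$primitive_sigma > 5)
})
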