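test_that("primitive activation is a wrap-aware unit-height Gaussian", {
  expect_equal(primitive_activation(0, 22.8), 1)
  expect_equal(primitive_activation(22.8, 22.8), exp(-1 / 2))
  d <- seq(-180, 180, by = 7.5)
  expect_equal(primitive_activation(d, 30), primitive_activation(-d, 30))
  # wrap-awareness: 355 degrees away is 5 degrees away
  expect_equal(primitive_activation(355, 20), primitive_activation(-5, 20))
  expect_error(primitive_activation(10, 0), "positive")
})

test_that("velocity-to-direction width conversion behaves sensibly", {
  sg <- primitive_sigma_from_velocity()
  # wider than the chord at peak speed, far narrower than flat tuning
  expect_gt(sg, (0.12 / 0.302) * 180 / pi)
  expect_lt(sg, 2 * (0.12 / 0.302) * 180 / pi)
  expect_gt(primitive_sigma_from_velocity(sigma_v = 0.2), sg)
})

test_that("state reads interpolate on a wrapped grid", {
  st <- adaptation_state(1)
  expect_true(all(st$value == 0))
  st$value <- cos(st$direction * pi / 180)
  expect_equal(state_at(st, c(0, 90, -180, 180)), c(1, 0, -1, -1),
               tolerance = 1e-6)
  expect_equal(state_at(st, 0.5), cos(0.5 * pi / 180), tolerance = 1e-3)
})

test_that("the update rule decays, localizes, and respects the reference", {
  params <- learning_params(retention = 0.9, hypothesis = "MRL")
  st <- adaptation_state(1)
  st$value <- rnorm(nrow(st))
  # zero error on a field trial: pure decay
  dec <- update_state(st, 90, 90, 0, 1, params)
  expect_equal(dec$value, 0.9 * st$value)
  # clamp / null trials decay regardless of stored error
  dec2 <- update_state(st, 90, 70, -20, 0, params)
  expect_equal(dec2$value, 0.9 * st$value)
  # single trial on a naive state peaks at the reference direction
  naive <- adaptation_state(1)
  mrl <- update_state(naive, 90, 70, -20, 1, params)
  expect_equal(mrl$direction[which.max(abs(mrl$value))], 70)
  prl <- update_state(naive, 90, 70, -20, 1,
                      learning_params(hypothesis = "PRL"))
  expect_equal(prl$direction[which.max(abs(prl$value))], 90)
  # increment sign follows the error
  expect_lt(min(mrl$value), 0)
})

test_that("iterated updates equal the closed-form superposition", {
  for (seed in 1:20) {
    hist <- random_history(20, seed)
    for (hyp in c("MRL", "PRL")) {
      params <- learning_params(retention = 0.93, hypothesis = hyp)
      st <- adaptation_state(1)
      for (k in seq_len(nrow(hist))) {
        st <- update_state(st, hist$planned[k], hist$actual[k],
                           hist$error[k], hist$field_sign[k], params)
      }
      cf <- closed_form_state(hist, params, grid_step = 1)
      expect_equal(st$value, cf$value, tolerance = 1e-12)
    }
  }
  # empty history is the naive state
  empty <- closed_form_state(random_history(0, 1), learning_params())
  expect_true(all(empty$value == 0))
})

test_that("the learning rule is linear in the error history", {
  params <- learning_params(retention = 0.95)
  h1 <- random_history(15, 101)
  h2 <- h1
  set.seed(202)
  h2$error <- rnorm(15, 0, 10)
  h2$error[h2$field_sign == 0] <- 0
  hsum <- h1
  hsum$error <- h1$error + h2$error
  s1 <- closed_form_state(h1, params)
  s2 <- closed_form_state(h2, params)
  ssum <- closed_form_state(hsum, params)
  expect_equal(ssum$value, s1$value + s2$value, tolerance = 1e-12)
})

test_that("balanced opposite errors cancel under PRL but not MRL", {
  # sign-balanced CW/CCW errors at one target, full retention for exactness
  errs <- c(-15, 15, -10, 10, -20, 20)
  hist <- tibble::tibble(planned = 90,
                         actual = wrap_angle(90 + errs),
                         error = errs,
                         field_sign = rep(c(1L, -1L), 3))
  params <- learning_params(retention = 1, hypothesis = "PRL")
  prl <- closed_form_state(hist, params)
  expect_equal(max(abs(prl$value)), 0, tolerance = 1e-12)
  mrl <- closed_form_state(hist, learning_params(retention = 1))
  expect_gt(max(abs(mrl$value)), 0.1)
  # MRL: one negative extremum below the target, one positive above
  expect_lt(ang_diff(mrl$direction[which.min(mrl$value)], 90), 0)
  expect_gt(ang_diff(mrl$direction[which.max(mrl$value)], 90), 0)
})

test_that("predicted generalization scales states by the reference field", {
  st <- adaptation_state(1)
  z <- predicted_generalization(st, c(0, 45, 90), 9)
  expect_equal(z$adaptation, c(0, 0, 0))
  st$value <- rep(9, nrow(st))
  one <- predicted_generalization(st, c(0, 45, 90), 9)
  expect_equal(one$adaptation, c(1, 1, 1))
  expect_error(predicted_generalization(st, 0, 0), "non-zero")
})
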