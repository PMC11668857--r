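test_that("hybrid reward matches hand-evaluated cases to 1e-9", {
  p <- reward_params() # alpha 100, beta 30, mu 200, delta 100, all gates on
  # sharpest frame, n = beta, no stop: only the clearest-image bonus remains
  expect_equal(compute_reward(1, 30, FALSE, "sharpest", p), 100, tolerance = 1e-9)
  # least sharp frame at n = beta: -alpha - delta
  expect_equal(compute_reward(0, 30, FALSE, "least_sharp", p), -200, tolerance = 1e-9)
  # mid-sharpness, n = 2 beta, correct stop
  expect_equal(compute_reward(0.5, 60, TRUE, "neither", p),
               -50 - 30 * log(2) + 200, tolerance = 1e-9)
})

test_that("time component changes sign exactly at n = beta", {
  p <- reward_params(sharpness_on = FALSE, stop_on = FALSE, extra_on = FALSE)
  expect_gt(compute_reward(0.5, 29, FALSE, "neither", p), 0)
  expect_equal(compute_reward(0.5, 30, FALSE, "neither", p), 0, tolerance = 1e-12)
  expect_lt(compute_reward(0.5, 31, FALSE, "neither", p), 0)
})

test_that("stop coefficient contributes only on a correct stop", {
  p <- reward_params()
  base <- compute_reward(0.4, 10, FALSE, "neither", p)
  expect_equal(compute_reward(0.4, 10, TRUE, "neither", p) - base, 200)
  p_off <- reward_params(stop_on = FALSE)
  expect_equal(compute_reward(0.4, 10, TRUE, "neither", p_off),
               compute_reward(0.4, 10, FALSE, "neither", p_off))
})

test_that("reward is monotonically non-decreasing in normalized sharpness", {
  for (orient in c("corrected", "literal")) {
    p <- reward_params(orientation = orient)
    r <- vapply(seq(0, 1, by = 0.05), compute_reward, numeric(1),
                n = 5, stop_correct = FALSE, extreme = "neither", params = p)
    if (orient == "corrected") expect_true(all(diff(r) >= 0))
    else expect_true(all(diff(r) <= 0)) # the printed form penalizes sharpness
  }
})

test_that("ablation gates select the documented component subsets", {
  expect_identical(variant_gates(1),
                   list(sharpness_on = TRUE, time_on = FALSE, stop_on = FALSE, extra_on = FALSE))
  expect_identical(variant_gates(2)$stop_on, TRUE)
  expect_identical(variant_gates(3)$time_on, TRUE)
  expect_identical(variant_gates(4)$extra_on, TRUE)
  expect_identical(variant_gates(5),
                   list(sharpness_on = TRUE, time_on = TRUE, stop_on = TRUE, extra_on = TRUE))
  expect_false(variant_gates(2)$time_on || variant_gates(2)$extra_on)
  expect_error(variant_gates(0), "variant")
  expect_error(variant_gates(6), "variant")
})

test_that("reward inputs are validated", {
  p <- reward_params()
  expect_error(compute_reward(1.5, 5, FALSE, "neither", p), "fc_norm")
  expect_error(compute_reward(0.5, 0, FALSE, "neither", p), "step count")
  expect_error(compute_reward(0.5, 5, FALSE, "weird", p), "extreme")
  expect_error(reward_params(alpha = -1), "alpha")
  expect_error(reward_params(beta = 0), "beta")
})
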