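test_that("action-set constructions reproduce the reference sets exactly", {
  expect_identical(build_action_set(5, 7, "logarithmic")$control_factors,
                   c(-25L, -5L, -1L, 0L, 1L, 5L, 25L))
  expect_identical(build_action_set(3, 7, "logarithmic")$control_factors,
                   c(-9L, -3L, -1L, 0L, 1L, 3L, 9L))
  expect_identical(build_action_set(3, 7, "multiple")$control_factors,
                   c(-6L, -3L, -1L, 0L, 1L, 3L, 6L))
  expect_identical(build_action_set(5, 7, "multiple")$control_factors,
                   c(-10L, -5L, -1L, 0L, 1L, 5L, 10L))
  # base 2: the two constructions coincide
  expect_identical(build_action_set(2, 7, "logarithmic")$control_factors,
                   build_action_set(2, 7, "multiple")$control_factors)
  expect_identical(build_action_set(2, 7, "multiple")$control_factors,
                   c(-4L, -2L, -1L, 0L, 1L, 2L, 4L))
  # minimal basic set for any base
  for (b in c(2, 5, 9)) for (m in c("logarithmic", "multiple"))
    expect_identical(build_action_set(b, 3, m)$control_factors, c(-1L, 0L, 1L))
})

test_that("action sets satisfy the structural invariants for many configurations", {
  for (b in 2:7) for (n_A in c(3, 5, 7, 9)) for (m in c("logarithmic", "multiple")) {
    f <- build_action_set(b, n_A, m)$control_factors
    expect_length(f, n_A)
    expect_identical(f, sort(f))
    expect_true(0L %in% f && 1L %in% f && -1L %in% f)
    expect_setequal(f, -f) # symmetric about zero
  }
  expect_error(build_action_set(5, 6, "logarithmic"), "odd")
  expect_error(build_action_set(5, 1, "logarithmic"), "odd")
  expect_error(build_action_set(1, 7, "logarithmic"), "b must")
})

test_that("action-space admissibility bounds the largest factor by half the state range", {
  expect_true(check_action_space(5, 7, 100))   # 25 <= 50
  expect_false(check_action_space(5, 9, 100))  # 125 > 50
  expect_true(check_action_space(2, 3, 4))
})

test_that("actions move the frame index with boundary clipping", {
  expect_identical(apply_action(30, 5, 100), 35L)
  expect_identical(apply_action(98, 5, 100), 100L)
  expect_identical(apply_action(1, -25, 100), 1L)
  expect_error(apply_action(0, 1, 100), "out of range")
  expect_error(apply_action(101, 1, 100), "out of range")
})

test_that("logarithmic sets reach any target quickly (breadth-first search oracle)", {
  n <- 100
  for (b in c(2, 3, 5)) {
    aset <- build_action_set(b, 7, "logarithmic")
    d <- bfs_min_moves(aset, n, 50)
    expect_true(all(is.finite(d)))
    expect_identical(d[50], 0L)
    # any deviation reducible in O(b log_b d) moves
    dev <- abs(seq_len(n) - 50)
    bound <- 2 * b * (1 + log(pmax(dev, 1), base = b))
    expect_true(all(d <= bound))
    # moving one unit from an adjacent index takes one move
    expect_identical(d[49], 1L)
  }
})
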