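test_that("rendered stacks have the promised geometry and voltage grid", {
  tex <- make_texture("speckle", 32, 0.5, seed = 1)
  st <- render_stack(tex, n_frames = 100, focus_index = 50, v_start = 35,
                     v_step = 0.1, seed = 2)
  expect_s3_class(st, "focal_stack")
  expect_length(st$frames, 100)
  expect_equal(diff(range(st$voltage_grid)), 9.9) # 100 frames at 0.1 V
  expect_lt(max(abs(diff(st$voltage_grid)) - 0.1), 1e-9)
  expect_true(all(vapply(st$frames, function(f) all(f >= 0 & f <= 1), logical(1))))
})

test_that("noiseless stacks are strictly unimodal at the focus index", {
  for (fam in texture_families()) {
    tex <- make_texture(fam, 64, if (fam == "regular_grid") 0.9 else 0.5, seed = 4)
    st <- render_stack(tex, n_frames = 100, focus_index = 50, noise_sd = 0, seed = 5)
    for (m in c("energy", "tenengrad", "variance", "brenner")) {
      v <- sharpness_curve(st, m)$values
      expect_identical(which.max(v), 50L)
      expect_true(all(diff(v[1:50]) > 0), label = paste(fam, m, "rising flank"))
      expect_true(all(diff(v[50:100]) < 0), label = paste(fam, m, "falling flank"))
    }
  }
})

test_that("render_stack validates its inputs", {
  tex <- make_texture("speckle", 16, 0.5, seed = 1)
  expect_error(render_stack(tex, n_frames = 100, focus_index = 120), "out of range")
  expect_error(render_stack(tex, n_frames = 2, focus_index = 1), "n_frames")
  expect_error(render_stack(tex, n_frames = 10, focus_index = 5, v_step = 0), "v_step")
})

test_that("augmentation preserves geometry and is exactly invertible/identity where promised", {
  lst <- mk_tiny_list(1, n_frames = 10, size = 16, seed = 3)
  st <- lst$stacks[[1]]
  twice <- augment_stack(augment_stack(st, "hflip", seed = 1), "hflip", seed = 1)
  expect_equal(twice$frames, st$frames)
  g1 <- augment_stack(st, "gamma", seed = 2, gamma_range = c(1, 1))
  expect_equal(g1$frames, st$frames)
  cr_a <- augment_stack(st, "crop", seed = 9)
  cr_b <- augment_stack(st, "crop", seed = 9)
  expect_equal(cr_a$frames, cr_b$frames)
  for (aug in list(twice, g1, cr_a)) {
    expect_identical(aug$focus_index, st$focus_index)
    expect_identical(aug$voltage_grid, st$voltage_grid)
    expect_length(aug$frames, length(st$frames))
  }
  expect_error(augment_stack(st, "rotate17", seed = 1), "unknown augmentation")
})

test_that("dataset lists are balanced, reproducible and centrally focused", {
  lst <- build_dataset_list(20, c("regular_grid", "bar_target"), n_frames = 50,
                            size = 16, seed = 1)
  expect_length(lst$stacks, 20)
  expect_equal(as.numeric(lst$family_counts), c(10, 10)) # half-split
  focus <- vapply(lst$stacks, function(s) s$focus_index, integer(1))
  expect_true(all(focus >= ceiling(0.1 * 50) & focus <= floor(0.9 * 50)))
  # bit-identical regeneration
  lst2 <- build_dataset_list(20, c("regular_grid", "bar_target"), n_frames = 50,
                             size = 16, seed = 1)
  expect_identical(lst, lst2)
  one <- build_dataset_list(1, "speckle", n_frames = 20, size = 16, seed = 2)
  expect_length(one$stacks, 1)
  expect_error(build_dataset_list(5, character(0)), "families")
  expect_error(build_dataset_list(0, "speckle"), "n_stacks")
  aug <- augment_dataset_list(lst, variants = list("hflip"), seed = 1)
  expect_length(aug$stacks, 40)
  expect_identical(aug$stacks[[21]]$focus_index, lst$stacks[[1]]$focus_index)
})

test_that("stack IO round-trips losslessly up to 8-bit quantization", {
  lst <- mk_tiny_list(1, n_frames = 12, size = 16, seed = 6)
  st <- lst$stacks[[1]]
  d <- withr::local_tempdir()
  write_stack(st, d)
  expect_true(file.exists(file.path(d, "stack.json")))
  back <- read_stack(d)
  expect_identical(back$focus_index, st$focus_index)
  expect_equal(back$voltage_grid, st$voltage_grid)
  expect_length(back$frames, 12)
  err <- max(mapply(function(a, b) max(abs(a - b)), back$frames, st$frames))
  expect_lte(err, 1 / 255 + 1e-9)
})

test_that("stack IO flags missing frames and recovers shuffled listings", {
  lst <- mk_tiny_list(1, n_frames = 8, size = 16, seed = 7)
  st <- lst$stacks[[1]]
  d <- withr::local_tempdir()
  write_stack(st, d)
  # shuffle the sidecar listing: read must restore voltage order
  sc <- jsonlite::read_json(file.path(d, "stack.json"), simplifyVector = TRUE)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  sc$files <- sc$files[perm]
  sc$voltage_grid <- sc$voltage_grid[perm]
  sc$focus_index <- which(perm == (st$focus_index)) - 1L # listing-order index
  jsonlite::write_json(sc, file.path(d, "stack.json"), auto_unbox = TRUE, digits = NA)
  back <- read_stack(d)
  expect_equal(back$voltage_grid, st$voltage_grid)
  expect_identical(back$focus_index, st$focus_index)
  expect_equal(back$frames[[3]], st$frames[[3]], tolerance = 1 / 255)
  # delete one frame: error names the missing file
  unlink(file.path(d, sc$files[1]))
  expect_error(read_stack(d), "missing frame")
  expect_error(read_stack(withr::local_tempdir()), "sidecar")
})
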