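test_that("the compiled and pure-R integrators agree exactly", {
  sp <- shape_spec("outline_cross", c(12, 12), 14)
  seqn <- make_flicker_sequence(sp, duration = 0.5, canvas = c(24, 24))
  tr_c <- run_simulation(seqn, fast_params("cpp"))
  tr_r <- run_simulation(seqn, fast_params("r"))
  n <- length(tr_c$percepts)
  expect_identical(tr_c$times, tr_r$times)
  expect_equal(tr_c$percepts[[n]]$on_fill, tr_r$percepts[[n]]$on_fill,
               tolerance = 1e-12)
  expect_equal(tr_c$percepts[[n]]$off_fill, tr_r$percepts[[n]]$off_fill,
               tolerance = 1e-12)
  expect_equal(tr_c$state$gates$z_vertical, tr_r$state$gates$z_vertical,
               tolerance = 1e-12)
  expect_equal(tr_c$boundaries[[n]]$vertical, tr_r$boundaries[[n]]$vertical,
               tolerance = 1e-12)
})

test_that("an all-background movie produces no boundaries and a flat percept", {
  frames <- list(frame(matrix(0.5, 16, 16), 0.5),
                 frame(matrix(0.5, 16, 16), 0.5))
  tr <- run_simulation(stimulus_sequence(frames), fast_params())
  for (b in tr$boundaries) {
    expect_true(all(b$vertical == 0))
    expect_true(all(b$horizontal == 0))
  }
  for (p in tr$percepts) expect_true(all(p$brightness == 0))
})

test_that("simulation reruns are bit-identical", {
  seqn <- build_demo("ag_movie4_size",
                     overrides = list(adapt_duration = 0.5,
                                      test_duration = 0.25, isi = 0))
  p <- fast_params()
  tr1 <- run_simulation(seqn, p)
  tr2 <- run_simulation(seqn, p)
  n <- length(tr1$percepts)
  expect_identical(tr1$percepts[[n]]$on_fill, tr2$percepts[[n]]$on_fill)
  expect_identical(tr1$state$gates$z_vertical, tr2$state$gates$z_vertical)
})

test_that("resuming from a saved state equals one uninterrupted run", {
  # validates the threshold harness's reuse of the adaptation state
  sp <- shape_spec("outline_square", c(12, 12), 14)
  adapt <- make_flicker_sequence(sp, duration = 0.5, canvas = c(24, 24))
  test_fr <- render_shape(shape_spec("filled_square", c(12, 12), 14,
                                     luminance = 0.55), c(24, 24),
                          duration = 0.25)
  p <- fast_params()
  full <- run_simulation(stimulus_sequence(c(adapt$frames, list(test_fr))), p)
  part1 <- run_simulation(adapt, p)
  part2 <- run_simulation(stimulus_sequence(list(test_fr)), p,
                          initial_state = part1$state)
  n <- length(full$percepts)
  expect_identical(full$percepts[[n]]$on_fill,
                   part2$percepts[[length(part2$percepts)]]$on_fill)
  expect_identical(full$state$gates$z_horizontal,
                   part2$state$gates$z_horizontal)
})

test_that("sample_every records intermediate snapshots on the dt grid", {
  frames <- list(frame(matrix(0.5, 8, 8), 1))
  tr <- run_simulation(stimulus_sequence(frames), fast_params(),
                       sample_every = 0.25)
  expect_equal(tr$times, c(0.25, 0.5, 0.75, 1))
})
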