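zero_boundaries <- function(h, w) {
  structure(list(vertical = matrix(0, h, w), horizontal = matrix(0, h, w)),
            class = "boundary_field")
}

test_that("permeability implements divisive boundary gating with the right orientation", {
  fp <- fill_params(couple = 100, block = 10)
  h <- 6; w <- 6
  p0 <- permeability(zero_boundaries(h, w), fp)
  expect_true(all(p0$right[, -w] == 100))
  expect_true(all(p0$down[-h, ] == 100))

  # a vertical boundary along column 3 blocks horizontal but not vertical flow
  b <- zero_boundaries(h, w)
  b$vertical[, 3] <- 1e9
  p <- permeability(b, fp)
  expect_true(all(p$right[, 2:3] < 1e-6))
  expect_true(all(p$down[-h, 3] == 100))
  # symmetry: permeability depends on the unordered endpoint pair
  b2 <- zero_boundaries(h, w)
  b2$vertical <- matrix(runif(h * w), h, w)
  p2 <- permeability(b2, fp)
  expect_equal(p2$right[2, 3],
               fp$couple / (1 + fp$block * (b2$vertical[2, 3] + b2$vertical[2, 4])))
})

test_that("filling-in has the expected fixed points and stability guard", {
  fp <- fill_params(decay = 1, couple = 10, block = 0, input_gain = 5)
  h <- 5; w <- 5
  perm <- permeability(zero_boundaries(h, w), fp)
  zsrc <- structure(list(on = matrix(0, h, w), off = matrix(0, h, w)),
                    class = "opponent_field")
  st <- empty_percept(c(h, w))
  st2 <- step_filling(st, zsrc, perm, fp, 0.01)
  expect_equal(st2$on_fill, matrix(0, h, w))

  # uniform source, no boundaries: steady state C*s/A everywhere
  src <- structure(list(on = matrix(0.2, h, w), off = matrix(0, h, w)),
                   class = "opponent_field")
  for (i in 1:2000) st <- step_filling(st, src, perm, fp, 0.02)
  expect_equal(st$on_fill, matrix(5 * 0.2 / 1, h, w), tolerance = 1e-8)
  expect_equal(st$brightness, st$on_fill - st$off_fill)

  expect_error(step_filling(st, src, perm, fp, 0.5), "unstable")
})

test_that("the direct steady-state solve handles trivial cases", {
  fp <- fill_params(decay = 2, couple = 10, block = 0, input_gain = 4)
  perm1 <- permeability(zero_boundaries(1, 1), fp)
  src1 <- structure(list(on = matrix(0.3, 1, 1), off = matrix(0, 1, 1)),
                    class = "opponent_field")
  ss <- steady_state_oracle(src1, perm1, fp)
  expect_equal(ss$on_fill[1, 1], 4 * 0.3 / 2)

  z <- structure(list(on = matrix(0, 3, 3), off = matrix(0, 3, 3)),
                 class = "opponent_field")
  ss0 <- steady_state_oracle(z, permeability(zero_boundaries(3, 3), fp), fp)
  expect_equal(ss0$on_fill, matrix(0, 3, 3))

  fp0 <- fill_params(decay = 0.5)
  fp0$decay <- 0
  expect_error(steady_state_oracle(z, permeability(zero_boundaries(3, 3), fp0),
                                   fp0), "decay > 0")
})

test_that("time-stepped filling converges to the direct linear solve", {
  set.seed(11)
  fp <- fill_params(decay = 1, couple = 20, block = 5, input_gain = 5)
  for (i in 1:5) {
    src <- random_opponent(8, 8)
    perm <- random_perm(8, 8, fp)
    ss <- steady_state_oracle(src, perm, fp)
    st <- empty_percept(c(8, 8))
    for (k in 1:6000) st <- step_filling(st, src, perm, fp, 0.01)
    expect_lt(max(abs(st$on_fill - ss$on_fill)), 1e-6)
    expect_lt(max(abs(st$off_fill - ss$off_fill)), 1e-6)
  }
})

test_that("free diffusion strictly homogenizes a frozen field", {
  fp <- fill_params(decay = 1, couple = 20, block = 0, input_gain = 5)
  fp$decay <- 0                       # isolate the diffusion term
  set.seed(3)
  perm <- permeability(zero_boundaries(6, 6), fp)
  src <- structure(list(on = matrix(0, 6, 6), off = matrix(0, 6, 6)),
                   class = "opponent_field")
  st <- empty_percept(c(6, 6))
  st$on_fill <- matrix(runif(36), 6, 6)
  v <- var(as.vector(st$on_fill))
  for (i in 1:50) {
    st <- step_filling(st, src, perm, fp, 0.01)
    v2 <- var(as.vector(st$on_fill))
    expect_lt(v2, v)
    v <- v2
  }
})

test_that("a closed boundary rectangle traps brightness; a gap collapses it", {
  fp <- fill_params()
  h <- 32; w <- 32
  b <- zero_boundaries(h, w)
  # rectangle rows 10..22, cols 10..22, strength 1
  b$horizontal[c(10, 22), 10:22] <- 1   # top/bottom sides block vertical flow
  b$vertical[10:22, c(10, 22)] <- 1     # left/right sides block horizontal flow
  src <- structure(list(on = matrix(0, h, w), off = matrix(0, h, w)),
                   class = "opponent_field")
  src$on[12:20, 12:20] <- 0.1
  inside <- matrix(FALSE, h, w); inside[12:20, 12:20] <- TRUE
  outside <- matrix(FALSE, h, w); outside[1:6, ] <- TRUE

  run_ss <- function(b) {
    perm <- permeability(b, fp)
    ss <- steady_state_oracle(src, perm, fp)
    mean(ss$brightness[inside]) - mean(ss$brightness[outside])
  }
  closed <- run_ss(b)
  b_open <- b
  b_open$vertical[10:22, 22] <- 0       # remove the right side
  open <- run_ss(b_open)
  expect_gt(closed, 10 * open)

  # trapping increases with blocking strength
  fp_weak <- fill_params(block = 100)
  perm_w <- permeability(b, fp_weak)
  ss_w <- steady_state_oracle(src, perm_w, fp_weak)
  weak <- mean(ss_w$brightness[inside]) - mean(ss_w$brightness[outside])
  expect_gt(closed, weak)
})

test_that("brightness readout maps percepts back to luminance", {
  per <- empty_percept(c(4, 4))
  expect_equal(readout_brightness(per, 0.5, 0.2)$luminance,
               matrix(0.5, 4, 4))
  per$on_fill <- matrix(1, 4, 4); per$off_fill <- matrix(1, 4, 4)
  expect_equal(readout_brightness(per, 0.5, 0.2)$luminance,
               matrix(0.5, 4, 4))
  per$off_fill <- matrix(0, 4, 4)
  expect_true(all(readout_brightness(per, 0.5, 0.2)$luminance > 0.5))
})
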