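test_that("oriented contrast responds to edges with the matching orientation", {
  dp <- dipole_params()
  uni <- to_opponent(matrix(0.5, 8, 8))
  d0 <- oriented_contrast(uni, dp)
  expect_true(all(d0$vertical == 0) && all(d0$horizontal == 0))

  # vertical step edge: left half 0.6, right half 0.5
  lum <- matrix(0.5, 8, 8); lum[, 1:4] <- 0.6
  d <- oriented_contrast(to_opponent(lum), dp)
  inner <- 2:7
  expect_true(all(d$vertical[inner, c(4, 5)] > 0))
  expect_true(all(d$vertical[inner, c(2, 3, 6, 7)] == 0))
  expect_true(all(d$horizontal[inner, inner] == 0))
  # independent evaluation of the central-difference formula at one pixel
  s <- lum - 0.5
  expect_equal(d$vertical[4, 4], dp$drive_gain * abs(s[4, 5] - s[4, 3]))

  # a 45-degree corner drives both orientations equally at the corner pixel
  lum2 <- matrix(0.5, 9, 9); lum2[1:5, 1:5] <- 0.7
  d2 <- oriented_contrast(to_opponent(lum2), dp)
  expect_equal(d2$vertical[5, 5], d2$horizontal[5, 5])
})

test_that("gates follow the mass-action equation to its closed-form equilibrium", {
  dp <- dipole_params(alpha = 0.5, beta = 1, tonic = 0)
  dims <- c(2, 2)
  # zero signal, fresh gates: z = 1 is a fixed point
  g <- fresh_gates(dims)
  zero <- structure(list(vertical = matrix(0, 2, 2),
                         horizontal = matrix(0, 2, 2)),
                    class = "oriented_drive")
  for (i in 1:100) g <- step_gates(g, zero, dp, 0.01)
  expect_equal(g$z_vertical, matrix(1, 2, 2))

  # constant signal S: equilibrium alpha / (alpha + beta S), from any start
  for (S in c(0.5, 2, 10)) {
    drv <- structure(list(vertical = matrix(S, 2, 2),
                          horizontal = matrix(S, 2, 2)),
                     class = "oriented_drive")
    tau <- 1 / (dp$alpha + dp$beta * S)
    dt <- min(0.01, tau / 20)
    g <- fresh_gates(dims)
    for (i in seq_len(ceiling(10 * tau / dt))) g <- step_gates(g, drv, dp, dt)
    z_inf <- gate_equilibrium(dp, S)
    expect_equal(g$z_vertical[1, 1], z_inf, tolerance = 0.01)
    if (abs(dp$beta * S - dp$alpha) < 1e-12)
      expect_equal(z_inf, 0.5)
  }
  # beta * S = alpha gives the symmetric equilibrium 1/2
  expect_equal(gate_equilibrium(dp, dp$alpha / dp$beta), 0.5)
})

test_that("gate stepping enforces its stability guard and bounds", {
  dp <- dipole_params(alpha = 1, beta = 1, tonic = 0)
  big <- structure(list(vertical = matrix(200, 2, 2),
                        horizontal = matrix(0, 2, 2)),
                   class = "oriented_drive")
  expect_error(step_gates(fresh_gates(c(2, 2)), big, dp, 0.01), "unstable")

  # property: z stays in (0, 1] for random bounded inputs at admissible dt
  set.seed(7)
  g <- fresh_gates(c(4, 4))
  for (i in 1:200) {
    drv <- structure(list(vertical = matrix(runif(16, 0, 20), 4, 4),
                          horizontal = matrix(runif(16, 0, 20), 4, 4)),
                     class = "oriented_drive")
    g <- step_gates(g, drv, dp, 0.02)
    expect_true(all(g$z_vertical > 0 & g$z_vertical <= 1))
    expect_true(all(g$z_horizontal > 0 & g$z_horizontal <= 1))
  }
})

test_that("dipole output is opponent, thresholded, and single-orientation", {
  dp <- dipole_params(tonic = 0.2, out_threshold = 0.03)
  dims <- c(3, 3)
  g <- fresh_gates(dims)
  eq <- structure(list(vertical = matrix(1, 3, 3),
                       horizontal = matrix(1, 3, 3)),
                  class = "oriented_drive")
  out <- dipole_output(eq, g, dp)
  expect_true(all(out$vertical == 0) && all(out$horizontal == 0))

  onesided <- structure(list(vertical = matrix(2, 3, 3),
                             horizontal = matrix(0, 3, 3)),
                        class = "oriented_drive")
  out2 <- dipole_output(onesided, g, dp)
  expect_true(all(out2$vertical > 0))
  expect_true(all(out2$horizontal == 0))
  expect_true(all(out2$vertical * out2$horizontal == 0))
})

test_that("the dipole trace shows habituation, an offset drop, and an orientation rebound", {
  tr <- simulate_dipole_trace()   # strong vertical 4 s, weak vertical 2 s
  on_phase <- tr[tr$time > 0.5 & tr$time < 4, ]
  expect_true(all(diff(on_phase$y_vertical) < 0))     # habituation
  y_before <- tr$y_vertical[max(which(tr$time < 4))]
  y_after <- tr$y_vertical[min(which(tr$time > 4.01))]
  expect_lt(y_after, y_before / 2)                    # dramatic drop at offset
  expect_gt(max(tr$out_horizontal[tr$time > 4]), 0)   # rebound after-response
  expect_equal(max(tr$out_horizontal[tr$time < 3.9]), 0)

  # zero input, equal gates: both channels constant and equal (without a
  # tonic input the gates have nothing to habituate to)
  tr0 <- simulate_dipole_trace(data.frame(duration = 2, vertical = 0,
                                          horizontal = 0),
                               params = dipole_params(tonic = 0))
  expect_equal(tr0$y_vertical, tr0$y_horizontal)
  expect_equal(var(tr0$y_vertical), 0)
})
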