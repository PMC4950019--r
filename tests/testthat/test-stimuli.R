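test_that("rendering is binary for sharp shapes and trivial for zero contrast", {
  canvas <- c(64, 64)
  sp <- shape_spec("outline_cross", c(32, 32), 40, luminance = 0.5)
  expect_equal(unique(as.vector(render_shape(sp, canvas)$luminance)), 0.5)

  sp1 <- shape_spec("outline_cross", c(32, 32), 40, luminance = 1)
  lum <- render_shape(sp1, canvas)$luminance
  expect_setequal(unique(as.vector(lum)), c(0.5, 1.0))
})

test_that("Gaussian blur strictly reduces the maximum luminance gradient", {
  canvas <- c(64, 64)
  grad_max <- function(m) {
    gx <- m[, -1] - m[, -ncol(m)]
    gy <- m[-1, ] - m[-nrow(m), ]
    max(abs(gx), abs(gy))
  }
  sharp <- render_shape(shape_spec("outline_cross", c(32, 32), 40), canvas)
  blurred <- render_shape(shape_spec("outline_cross", c(32, 32), 40,
                                     blur_sigma = 3), canvas)
  expect_lt(grad_max(blurred$luminance), grad_max(sharp$luminance))
  # blur at sigma -> closed-form bound: max slope of a blurred unit step is
  # h / (sigma * sqrt(2*pi))
  step <- matrix(0.5, 32, 32); step[, 17:32] <- 1
  sm <- erasim:::separable_gaussian_blur(step, 4)
  expect_lt(grad_max(sm), 0.5 / (4 * sqrt(2 * pi)) * 1.05)
})

test_that("shapes exceeding the canvas raise an informative error", {
  expect_error(render_shape(shape_spec("disk", c(10, 10), 40), c(32, 32)),
               "exceeds canvas")
  expect_error(shape_spec("annulus", c(10, 10), 20, inner_size = 30),
               "inner_size")
})

test_that("flicker sequences alternate polarity and integrate to gray", {
  sp <- shape_spec("outline_square", c(16, 16), 20)
  s1 <- make_flicker_sequence(sp, duration = 4, half_period = 0.5,
                              canvas = c(32, 32))
  expect_length(s1$frames, 8)
  pol <- vapply(s1$frames, function(f) f$luminance[7, 16], numeric(1))
  expect_equal(pol, rep(c(1, 0), 4))

  s2 <- make_flicker_sequence(sp, duration = 6, half_period = 0.5,
                              canvas = c(32, 32))
  expect_length(s2$frames, 12)

  # per-pixel time average over a full cycle equals the background
  m <- s1$annotations$adapted_region
  avg <- Reduce(`+`, lapply(s1$frames, function(f) f$luminance * f$duration)) /
    total_duration(s1)
  expect_equal(avg[m], rep(0.5, sum(m)))
  expect_error(make_flicker_sequence(sp, 4, half_period = 0), "positive")
  expect_error(make_flicker_sequence(sp, 0.3, half_period = 0.25),
               "full flicker cycle")
})

test_that("rendering is deterministic", {
  sp <- shape_spec("polar_checkerboard", c(32, 32), 50, rings = c(16, 32),
                   blur_sigma = 1.5)
  f1 <- render_shape(sp, c(64, 64))
  f2 <- render_shape(sp, c(64, 64))
  expect_identical(f1$luminance, f2$luminance)
})

test_that("the demo catalog rejects unknown ids and lists valid ones", {
  expect_error(build_demo("nope"), "ag_movie2_crosses")
})

test_that("demo test frames differ from background only inside target masks", {
  for (demo in demo_ids()) {
    seqn <- build_demo(demo)
    ann <- seqn$annotations
    expect_true(all(vapply(ann, is.logical, TRUE)), info = demo)
    tnames <- grep("^target_", names(ann), value = TRUE)
    expect_gt(length(tnames), 0)
    targets <- Reduce(`|`, ann[tnames])
    test_frame <- seqn$frames[[length(seqn$frames)]]$luminance
    expect_true(all(test_frame[!targets] == 0.5), info = demo)
    # each surround is disjoint from its own target
    for (sn in grep("^surround_", names(ann), value = TRUE)) {
      tn <- sub("^surround_", "target_", sn)
      expect_false(any(ann[[sn]] & ann[[tn]]), info = paste(demo, sn))
    }
  }
})

test_that("the two-holed slab demo has equal and half-sized test squares", {
  seqn <- build_demo("rds_two_holed_annulus")
  a_equal <- sum(seqn$annotations$target_equal)
  a_half <- sum(seqn$annotations$target_half)
  expect_equal(a_equal / a_half, 4, tolerance = 0.1)
})

test_that("no-adapt override replaces adaptation with uniform background", {
  seqn <- build_demo("ag_movie4_size", overrides = list(adapt = FALSE))
  first <- seqn$frames[[1]]$luminance
  expect_true(all(first == 0.5))
  expect_equal(total_duration(seqn),
               total_duration(build_demo("ag_movie4_size")))
})

test_that("real-contour adaptor covers the test square edge; inducers touch it sparsely", {
  seqn <- build_demo("illusory_vs_real")
  ad <- seqn$annotations$adapted_region
  edge_of <- function(mask) {
    em <- erasim:::edge_masks(mask)
    em$vertical | em$horizontal
  }
  e_real <- edge_of(seqn$annotations$target_real)
  e_ill <- edge_of(seqn$annotations$target_illusory)
  cover_real <- mean(ad[erasim:::dilate_mask(e_real, 1)])
  cover_ill <- mean(ad[erasim:::dilate_mask(e_ill, 1)])
  expect_gt(cover_real, 4 * (cover_ill + 0.01))
  expect_lt(cover_ill, 0.05)
})
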