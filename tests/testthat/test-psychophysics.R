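test_that("target visibility is the absolute mean brightness difference", {
  per <- empty_percept(c(8, 8))
  tmask <- matrix(FALSE, 8, 8); tmask[3:5, 3:5] <- TRUE
  smask <- matrix(FALSE, 8, 8); smask[1, ] <- TRUE
  expect_equal(target_visibility(per, tmask, smask), 0)
  per$on_fill[tmask] <- 0.25
  expect_equal(target_visibility(per, tmask, smask), 0.25)
  expect_error(target_visibility(per, tmask, matrix(FALSE, 8, 8)),
               "non-empty")
  expect_error(target_visibility(per, tmask, tmask), "disjoint")
})

test_that("experiment specs validate their search bounds", {
  expect_error(experiment_spec("ag_movie4_size", bounds = c(0, 0.5)))
  expect_error(experiment_spec("ag_movie4_size", bounds = c(0.1, 0.6)))
  sp <- experiment_spec("ag_movie4_size", target = "matched")
  expect_s3_class(sp, "experiment_spec")
})

test_that("bisection brackets the visibility criterion to tolerance", {
  # no-adapt control on a small geometry: visibility grows with contrast, so
  # the returned threshold must be the smallest visible contrast up to tol
  sp <- experiment_spec("ag_movie4_size", target = "mismatched",
                        adapt = FALSE,
                        overrides = list(adapt_duration = 0.5, isi = 0,
                                         test_duration = 0.5))
  p <- fast_params()
  res <- contrast_threshold(sp, p, tol = 2e-3)
  expect_false(res$not_visible_at_max)
  th <- res$threshold_contrast
  expect_gt(th, 0.002); expect_lt(th, 0.5)

  ov <- sp$overrides; ov$adapt <- FALSE
  recipe <- erasim:::demo_recipe(sp$demo_id, ov)
  st <- erasim:::adaptation_state(recipe, p)
  expect_gte(erasim:::visibility_at(recipe, th, p, st, "mismatched"),
             res$criterion)
  expect_lt(erasim:::visibility_at(recipe, max(th - 4e-3, 1e-4), p, st,
                                   "mismatched"),
            res$criterion)
})

test_that("battery tables have the stated factorial layout", {
  expect_error(run_experiment_battery("nope"), "rds_fig5")
  c5 <- erasim:::battery_conditions("rds_fig5")
  expect_equal(nrow(c5), 4)
  c6 <- erasim:::battery_conditions("rds_exp1_fig6")
  expect_equal(nrow(c6), 12)
  expect_equal(sum(!c6$adapted), 2)
  expect_setequal(unique(c6$adaptor_deg[c6$adapted]), c(2, 4, 10, 12, 15))
  c7 <- erasim:::battery_conditions("rds_exp2_fig7")
  expect_equal(nrow(c7), 4)
})

test_that("demo claims cover the catalog and flag the half-square expected failure", {
  for (demo in demo_ids()) {
    cls <- erasim:::demo_claims(demo)
    expect_gt(length(cls), 0)
    recipe <- erasim:::demo_recipe(demo, list())
    nms <- vapply(recipe$targets, function(t) t$name, character(1))
    for (cl in cls) expect_true(cl$target %in% nms, info = demo)
  }
  ag5 <- erasim:::demo_claims("ag_movie5_halfsquare")
  expect_true(any(vapply(ag5, function(cl) cl$expected_fail, TRUE)))
})
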