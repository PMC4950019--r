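#' Available demo identifiers
#'
#' The catalog of adaptation/test movies: flicker-adaptation conditions with
#' outline crosses, blurred surfaces, size-mismatched squares, a half-square
#' outline, a bipartite field, brightness pyramids and annuli; flicker-disk
#' and polar-checkerboard threshold geometries; a two-holed flickering
#' slab; and the illusory-versus-real contour comparison.
#'
#' @return Character vector of demo ids accepted by [build_demo()].
#' @export
demo_ids <- function() {
  c("ag_movie2_crosses", "ag_movie3_blur", "ag_movie4_size",
    "ag_movie5_halfsquare", "ag_movie6_bipartite", "ag_movie7_pyramids",
    "ag_movie8_annuli", "rds_two_holed_annulus", "rds_exp1_disks",
    "rds_exp2_checkerboard", "illusory_vs_real")
}

default_overrides <- function() {
  list(adapt = TRUE, test_contrast = 0.05, half_period = 0.25,
       adapt_duration = NULL, test_duration = 1, isi = 0.25,
       px_per_deg = NULL,
       adaptor_deg = NULL, test_deg = NULL, inner_check_deg = NULL,
       blur_sigma = 6)
}

# A recipe fully describes one demo: canvas, adaptor specs, a test-frame
# builder parameterised by contrast, and named (target, surround) mask pairs
# for the visibility measurements.
demo_recipe <- function(demo_id, overrides = list()) {
  if (!demo_id %in% demo_ids())
    stop(sprintf("unknown demo id '%s'; valid ids: %s", demo_id,
                 paste(demo_ids(), collapse = ", ")))
  ov <- utils::modifyList(default_overrides(), overrides)
  bg <- 0.5
  build <- switch(demo_id,
    ag_movie2_crosses = recipe_ag2, ag_movie3_blur = recipe_ag3,
    ag_movie4_size = recipe_ag4, ag_movie5_halfsquare = recipe_ag5,
    ag_movie6_bipartite = recipe_ag6, ag_movie7_pyramids = recipe_ag7,
    ag_movie8_annuli = recipe_ag8,
    rds_two_holed_annulus = recipe_rds_annulus,
    rds_exp1_disks = recipe_rds_disks,
    rds_exp2_checkerboard = recipe_rds_checks,
    illusory_vs_real = recipe_illusory)
  r <- build(ov, bg)
  r$demo_id <- demo_id
  r$background <- bg
  r$adapt <- isTRUE(ov$adapt)
  r$half_period <- ov$half_period
  r$test_duration <- ov$test_duration
  r$test_contrast <- ov$test_contrast
  r$isi <- ov$isi
  if (!is.null(ov$adapt_duration)) r$adapt_duration <- ov$adapt_duration
  r
}

target_entry <- function(name, mask, surround) {
  list(name = name, mask = mask, surround = surround)
}

std_targets <- function(masks, canvas, inner = 1, outer = 6) {
  all_m <- Reduce(`|`, masks)
  lapply(names(masks), function(nm)
    target_entry(nm, masks[[nm]],
                 mask_ring(masks[[nm]], inner, outer, exclude = all_m)))
}

recipe_ag2 <- function(ov, bg) {
  canvas <- c(128, 128); size <- 24
  ctr <- list(adapted_bright = c(32, 64), adapted_dark = c(96, 64),
              unadapted_bright = c(64, 32), unadapted_dark = c(64, 96))
  adapt_specs <- lapply(ctr[1:2], function(cc)
    shape_spec("outline_cross", cc, size, line_width = 3))
  sgn <- c(adapted_bright = 1, adapted_dark = -1,
           unadapted_bright = 1, unadapted_dark = -1)
  test_builder <- function(contrast)
    lapply(names(ctr), function(nm)
      shape_spec("filled_cross", ctr[[nm]], size,
                 luminance = bg + sgn[[nm]] * contrast))
  masks <- lapply(ctr, function(cc)
    shape_mask(shape_spec("filled_cross", cc, size), canvas))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder,
       targets = std_targets(masks, canvas))
}

recipe_ag3 <- function(ov, bg) {
  canvas <- c(64, 128); size <- 24
  ctr <- list(sharp_adapted = c(32, 32), blur_adapted = c(32, 96))
  adapt_specs <- list(
    shape_spec("outline_square", ctr$sharp_adapted, size, line_width = 2),
    shape_spec("filled_square", ctr$blur_adapted, size,
               blur_sigma = ov$blur_sigma))
  test_builder <- function(contrast)
    lapply(ctr, function(cc)
      shape_spec("filled_square", cc, size, luminance = bg + contrast))
  masks <- lapply(ctr, function(cc)
    shape_mask(shape_spec("filled_square", cc, size), canvas))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder, targets = std_targets(masks, canvas))
}

recipe_ag4 <- function(ov, bg) {
  canvas <- c(64, 128)
  ctr <- list(matched = c(32, 32), mismatched = c(32, 96))
  sizes <- c(matched = 24, mismatched = 12)
  adapt_specs <- lapply(ctr, function(cc)
    shape_spec("outline_square", cc, 24, line_width = 2))
  test_builder <- function(contrast)
    lapply(names(ctr), function(nm)
      shape_spec("filled_square", ctr[[nm]], sizes[[nm]],
                 luminance = bg + contrast))
  masks <- lapply(names(ctr), function(nm)
    shape_mask(shape_spec("filled_square", ctr[[nm]], sizes[[nm]]), canvas))
  names(masks) <- names(ctr)
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder, targets = std_targets(masks, canvas))
}

recipe_ag5 <- function(ov, bg) {
  canvas <- c(64, 64); size <- 20; cc <- c(32, 32)
  adapt_specs <- list(shape_spec("half_square_outline", cc, size,
                                 line_width = 2))
  test_builder <- function(contrast)
    list(shape_spec("filled_square", cc, size, luminance = bg + contrast))
  sq <- shape_mask(shape_spec("filled_square", cc, size), canvas)
  g <- offset_grids(canvas, cc)
  masks <- list(square = sq,
                adapted_half = sq & g$dc <= -2,
                unadapted_half = sq & g$dc >= 2)
  ring <- mask_ring(sq, 2, 10)
  targets <- list(target_entry("square", sq, ring),
                  target_entry("adapted_half", masks$adapted_half, ring),
                  target_entry("unadapted_half", masks$unadapted_half, ring))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder, targets = targets)
}

recipe_ag6 <- function(ov, bg) {
  canvas <- c(64, 64); size <- 40; cc <- c(32, 32.5)
  adapt_specs <- list(shape_spec("vertical_line", cc, size + 8, line_width = 2))
  test_builder <- function(contrast)
    list(shape_spec("bipartite_field", cc, size, luminance = bg + contrast))
  region <- shape_mask(shape_spec("bipartite_field", cc, size), canvas)
  g <- offset_grids(canvas, cc)
  # the brightness judgment concerns the step at the divide, so compare
  # flanking bands beside it rather than the full half-fields
  left <- region & g$dc >= -12 & g$dc <= -2
  right <- region & g$dc <= 12 & g$dc >= 2
  targets <- list(target_entry("left_vs_right", left, right),
                  target_entry("field", region, mask_ring(region, 2, 10)))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder, targets = targets,
       default_contrast = 0.03)
}

recipe_ag7 <- function(ov, bg) {
  canvas <- c(64, 64); cc <- c(32, 32); outer <- 24; inner <- 12
  adapt_specs <- list(
    shape_spec("outline_square", cc, outer, line_width = 2),
    shape_spec("outline_square", cc, inner, line_width = 2))
  # contrast parameterises the peak (innermost) step; outer steps scale
  test_builder <- function(contrast)
    list(shape_spec("pyramid_steps", cc, outer, inner_size = inner,
                    luminance = bg + contrast, steps = 2))
  pyr <- shape_mask(shape_spec("pyramid_steps", cc, outer, inner_size = inner),
                    canvas)
  targets <- list(target_entry("pyramid", pyr, mask_ring(pyr, 2, 10)))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder, targets = targets,
       default_contrast = 0.15)
}

recipe_ag8 <- function(ov, bg) {
  canvas <- c(64, 128); outer <- 36; inner <- 20
  ctr <- list(left = c(32, 32), right = c(32, 96))
  ring_w <- (outer - inner) / 2
  adapt_specs <- list(
    # small outline square matching the INNER edge of the left annulus
    shape_spec("outline_square", ctr$left, inner, line_width = 2),
    # large outline square matching the OUTER edge of the right annulus
    shape_spec("outline_square", ctr$right, outer, line_width = 2))
  # square annuli: thick square outlines whose inner/outer edges the
  # adaptors match
  test_builder <- function(contrast)
    lapply(ctr, function(cc)
      shape_spec("outline_square", cc, outer, line_width = ring_w,
                 luminance = bg + contrast))
  ring_l <- shape_mask(shape_spec("outline_square", ctr$left, outer,
                                  line_width = ring_w), canvas)
  ring_r <- shape_mask(shape_spec("outline_square", ctr$right, outer,
                                  line_width = ring_w), canvas)
  hole_l <- shape_mask(shape_spec("filled_square", ctr$left, inner - 6),
                       canvas)
  targets <- list(
    target_entry("left_hole_vs_ring", hole_l, ring_l),
    target_entry("left_ring", ring_l,
                 mask_ring(ring_l, 1, 6, exclude = ring_l | hole_l |
                             dilate_mask(hole_l, 8))),
    target_entry("right_ring", ring_r,
                 mask_ring(ring_r, 1, 6,
                           exclude = ring_r |
                             shape_mask(shape_spec("filled_square",
                                                   ctr$right, inner + 6),
                                        canvas))))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder, targets = targets)
}

recipe_rds_annulus <- function(ov, bg) {
  p <- if (is.null(ov$px_per_deg)) 6 else ov$px_per_deg
  slab_w <- round(20 * p); hole <- round(4 * p)
  canvas <- c(round(13 * p), round(23 * p))
  cc <- round(canvas / 2)
  off <- round(slab_w / 4)
  adapt_specs <- list(shape_spec("two_holed_annulus", cc, slab_w,
                                 inner_size = hole))
  ctr <- list(equal = c(cc[1], cc[2] - off), half = c(cc[1], cc[2] + off))
  sizes <- c(equal = hole, half = round(hole / 2))
  test_builder <- function(contrast)
    lapply(names(ctr), function(nm)
      shape_spec("filled_square", ctr[[nm]], sizes[[nm]],
                 luminance = bg + contrast))
  masks <- lapply(names(ctr), function(nm)
    shape_mask(shape_spec("filled_square", ctr[[nm]], sizes[[nm]]), canvas))
  names(masks) <- names(ctr)
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 6,
       test_builder = test_builder,
       targets = std_targets(masks, canvas, 2, max(4, round(p))))
}

recipe_rds_disks <- function(ov, bg) {
  p <- if (is.null(ov$px_per_deg)) 4 else ov$px_per_deg
  side <- 2 * ceiling(17 * p / 2)
  canvas <- c(side, side); cc <- c(side, side) / 2
  ad_deg <- if (is.null(ov$adaptor_deg)) 2 else ov$adaptor_deg
  te_deg <- if (is.null(ov$test_deg)) 2 else ov$test_deg
  ad <- round(ad_deg * p); te <- round(te_deg * p)
  adapt_specs <- list(shape_spec("disk", cc, ad))
  test_builder <- function(contrast)
    list(shape_spec("disk", cc, te, luminance = bg + contrast))
  m <- shape_mask(shape_spec("disk", cc, te), canvas)
  targets <- list(target_entry("disk", m, mask_ring(m, 1, max(3, round(p)))))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 6,
       test_builder = test_builder, targets = targets)
}

recipe_rds_checks <- function(ov, bg) {
  p <- if (is.null(ov$px_per_deg)) 4 else ov$px_per_deg
  side <- 2 * ceiling(17 * p / 2)
  canvas <- c(side, side); cc <- c(side, side) / 2
  te_deg <- if (is.null(ov$test_deg)) 2.5 else ov$test_deg
  ic_deg <- if (is.null(ov$inner_check_deg)) 1.5 else ov$inner_check_deg
  outer <- round(15 * p); te <- round(te_deg * p)
  rings <- unique(c(round(ic_deg * p), te))
  adapt_specs <- list(shape_spec("polar_checkerboard", cc, outer,
                                 rings = rings, sectors = 8))
  test_builder <- function(contrast)
    list(shape_spec("disk", cc, te, luminance = bg + contrast))
  m <- shape_mask(shape_spec("disk", cc, te), canvas)
  targets <- list(target_entry("disk", m, mask_ring(m, 1, max(3, round(p)))))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 6,
       test_builder = test_builder, targets = targets)
}

recipe_illusory <- function(ov, bg) {
  canvas <- c(64, 128); size <- 56; cut <- 28; test_side <- 20
  ctr <- list(illusory = c(32, 32), real = c(32, 96))
  adapt_specs <- list(
    shape_spec("concentric_square_inducers", ctr$illusory, size,
               inner_size = cut, line_width = 2, spacing = 9),
    shape_spec("concentric_square_inducers", ctr$real, size,
               inner_size = cut, line_width = 2, spacing = 9),
    shape_spec("outline_square", ctr$real, test_side, line_width = 2))
  test_builder <- function(contrast)
    lapply(ctr, function(cc)
      shape_spec("filled_square", cc, test_side, luminance = bg + contrast))
  masks <- lapply(ctr, function(cc)
    shape_mask(shape_spec("filled_square", cc, test_side), canvas))
  list(canvas = canvas, adapt_specs = adapt_specs, adapt_duration = 4,
       test_builder = test_builder, targets = std_targets(masks, canvas))
}

# assemble the full movie for a recipe at a given test contrast
recipe_sequence <- function(recipe, contrast = NULL) {
  if (is.null(contrast))
    contrast <- if (!is.null(recipe$default_contrast)) recipe$default_contrast
                else recipe$test_contrast
  canvas <- recipe$canvas; bg <- recipe$background
  adapt_frames <- if (recipe$adapt)
    flicker_frames(recipe$adapt_specs, recipe$adapt_duration,
                   recipe$half_period, bg, canvas)
  else uniform_frames(recipe$adapt_duration, bg, canvas)
  if (!is.null(recipe$isi) && recipe$isi > 0)
    adapt_frames <- c(adapt_frames, uniform_frames(recipe$isi, bg, canvas))
  test_frame <- render_shapes(recipe$test_builder(contrast), canvas, bg,
                              duration = recipe$test_duration)
  ann <- list()
  for (tg in recipe$targets) {
    ann[[paste0("target_", tg$name)]] <- tg$mask
    ann[[paste0("surround_", tg$name)]] <- tg$surround
  }
  adapted <- Reduce(`|`, lapply(recipe$adapt_specs, shape_mask,
                                canvas = canvas))
  ann$adapted_region <- adapted
  occupied <- Reduce(`|`, c(lapply(ann, identity)))
  ann$background_region <- !dilate_mask(occupied, 2)
  stimulus_sequence(c(adapt_frames, list(test_frame)), annotations = ann)
}

#' Build a complete adaptation + test movie from the demo catalog
#'
#' Assembles the flicker-adaptation phase and the faint test frame for one
#' demo, with annotation masks for each test target, its surround, the
#' adapted region and the open background.  Setting
#' \code{overrides$adapt = FALSE} yields the no-adapt control (the
#' adaptation phase is replaced by a uniform background of equal duration).
#'
#' @param demo_id One of [demo_ids()].
#' @param overrides Named list of parameter overrides: \code{adapt},
#'   \code{test_contrast}, \code{adapt_duration}, \code{test_duration},
#'   \code{half_period}, \code{px_per_deg}, and demo-specific geometry
#'   (\code{adaptor_deg}, \code{test_deg}, \code{inner_check_deg},
#'   \code{blur_sigma}).
#' @return A [stimulus_sequence()].
#' @export
#' @examples
#' seq <- build_demo("ag_movie4_size", overrides = list(adapt_duration = 1))
#' names(seq$annotations)
build_demo <- function(demo_id, overrides = list()) {
  recipe <- demo_recipe(demo_id, overrides)
  seqn <- recipe_sequence(recipe)
  attr(seqn, "recipe") <- recipe
  seqn
}
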