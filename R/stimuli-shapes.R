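#' Parametric shape specification
#'
#' Describes one achromatic shape to be painted on a uniform background.
#' Geometry is in pixels with a row/column, origin top-left, pixel-centre
#' convention; luminance is in [0, 1] with 0.5 the canonical mid-gray
#' background.
#'
#' @param kind One of \code{"outline_cross"}, \code{"filled_cross"},
#'   \code{"outline_square"}, \code{"filled_square"},
#'   \code{"half_square_outline"}, \code{"vertical_line"}, \code{"annulus"},
#'   \code{"two_holed_annulus"}, \code{"disk"}, \code{"polar_checkerboard"},
#'   \code{"concentric_square_inducers"}, \code{"pyramid_steps"},
#'   \code{"bipartite_field"}.
#' @param center Pixel coordinates \code{c(row, col)} of the shape centre.
#' @param size Outer extent in pixels (side length for squares and crosses,
#'   diameter for disks and annuli, overall width for the two-holed slab).
#' @param inner_size Inner extent in pixels for annuli, holes, pyramid tops
#'   and the cut-out of the inducer pattern; 0 when not applicable.
#' @param line_width Stroke width in pixels for outline kinds (>= 1).
#' @param luminance Shape luminance in [0, 1].  Kinds with two tones
#'   (checkerboard, bipartite field) use \code{luminance} and
#'   \code{1 - luminance}; flipping the two renders the opposite flicker
#'   polarity.
#' @param blur_sigma Standard deviation in pixels of an isotropic Gaussian
#'   applied to the rendered shape (0 = sharp edges).
#' @param rings For \code{polar_checkerboard}: ring boundary diameters in
#'   pixels (the outermost defaults to \code{size}).
#' @param sectors For \code{polar_checkerboard}: number of angular sectors.
#' @param spacing For \code{concentric_square_inducers}: spacing in pixels
#'   between successive concentric (diamond-oriented) square outlines.
#' @param steps For \code{pyramid_steps}: number of luminance steps from the
#'   background to \code{luminance}.
#' @return An object of class \code{shape_spec}.
#' @export
#' @examples
#' sp <- shape_spec("outline_cross", center = c(32, 32), size = 40,
#'                  luminance = 1)
#' fr <- render_shape(sp, canvas = c(64, 64), background = 0.5)
#' range(fr$luminance)
shape_spec <- function(kind, center, size, inner_size = 0, line_width = 2,
                       luminance = 1, blur_sigma = 0,
                       rings = NULL, sectors = 8, spacing = 8, steps = 2) {
  kinds <- c("outline_cross", "filled_cross", "outline_square",
             "filled_square", "half_square_outline", "vertical_line",
             "annulus", "two_holed_annulus", "disk", "polar_checkerboard",
             "concentric_square_inducers", "pyramid_steps", "bipartite_field")
  kind <- match.arg(kind, kinds)
  stopifnot(length(center) == 2, size > 0, inner_size >= 0,
            luminance >= 0, luminance <= 1, blur_sigma >= 0)
  if (inner_size > 0 && inner_size >= size)
    stop("inner_size must be smaller than size")
  outline_kinds <- c("outline_cross", "outline_square", "half_square_outline",
                     "vertical_line", "annulus", "concentric_square_inducers")
  if (kind %in% outline_kinds && line_width < 1)
    stop("line_width must be >= 1 for outline kinds")
  structure(list(kind = kind, center = as.numeric(center), size = size,
                 inner_size = inner_size, line_width = line_width,
                 luminance = luminance, blur_sigma = blur_sigma,
                 rings = rings, sectors = sectors, spacing = spacing,
                 steps = steps),
            class = "shape_spec")
}

# 8-neighbour erosion of a logical mask, n passes (Chebyshev distance)
erode_mask <- function(mask, n) {
  m <- mask
  for (i in seq_len(n)) {
    p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    r <- 2:(nrow(m) + 1); c <- 2:(ncol(m) + 1)
    m <- p[r, c] & p[r - 1, c] & p[r + 1, c] & p[r, c - 1] & p[r, c + 1] &
      p[r - 1, c - 1] & p[r - 1, c + 1] & p[r + 1, c - 1] & p[r + 1, c + 1]
  }
  m
}

# 8-neighbour dilation, n passes
dilate_mask <- function(mask, n) {
  !erode_mask(!mask, n)
}

outline_of <- function(region, width) {
  region & !erode_mask(region, width)
}

# pixel-offset grids for a canvas relative to a centre
offset_grids <- function(canvas, center) {
  dr <- matrix(seq_len(canvas[1]) - center[1], canvas[1], canvas[2])
  dc <- matrix(seq_len(canvas[2]) - center[2], canvas[1], canvas[2],
               byrow = TRUE)
  list(dr = dr, dc = dc)
}

square_region <- function(g, side) {
  abs(g$dr) <= (side - 1) / 2 & abs(g$dc) <= (side - 1) / 2
}

cross_region <- function(g, size, arm) {
  hs <- (size - 1) / 2; ha <- (arm - 1) / 2
  (abs(g$dr) <= ha & abs(g$dc) <= hs) | (abs(g$dc) <= ha & abs(g$dr) <= hs)
}

disk_region <- function(g, diameter) {
  g$dr^2 + g$dc^2 <= ((diameter - 1) / 2)^2
}

#' Pixel mask covered by a shape
#'
#' Logical matrix of the pixels a [shape_spec()] paints (before any blur).
#' For multi-tone kinds this is the full covered region.
#'
#' @param spec A [shape_spec()].
#' @param canvas Canvas dimensions \code{c(height, width)}.
#' @return A logical matrix of dimension \code{canvas}.
#' @export
shape_mask <- function(spec, canvas) {
  g <- offset_grids(canvas, spec$center)
  lw <- spec$line_width
  switch(spec$kind,
    filled_square = square_region(g, spec$size),
    outline_square = outline_of(square_region(g, spec$size), lw),
    half_square_outline = {
      # square outline with the right side removed: the one-sided gap of
      # the half-square demonstration
      o <- outline_of(square_region(g, spec$size), lw)
      o & g$dc < (spec$size - 1) / 2 - lw
    },
    filled_cross = cross_region(g, spec$size, round(spec$size / 3)),
    outline_cross = outline_of(cross_region(g, spec$size,
                                            round(spec$size / 3)), lw),
    vertical_line = abs(g$dc) <= (lw - 1) / 2 &
      abs(g$dr) <= (spec$size - 1) / 2,
    disk = disk_region(g, spec$size),
    annulus = disk_region(g, spec$size) & !disk_region(g, spec$inner_size),
    two_holed_annulus = {
      slab_h <- round(spec$size / 2)
      slab <- abs(g$dr) <= (slab_h - 1) / 2 & abs(g$dc) <= (spec$size - 1) / 2
      off <- round(spec$size / 4)
      ih <- (spec$inner_size - 1) / 2
      hole1 <- abs(g$dr) <= ih & abs(g$dc + off) <= ih
      hole2 <- abs(g$dr) <= ih & abs(g$dc - off) <= ih
      slab & !hole1 & !hole2
    },
    polar_checkerboard = disk_region(g, spec$size),
    concentric_square_inducers = {
      l1 <- abs(g$dr) + abs(g$dc)
      hs <- inducer_ring_halfsizes(spec)
      m <- matrix(FALSE, canvas[1], canvas[2])
      for (h in hs) m <- m | abs(l1 - h) <= lw / 2
      cut <- abs(g$dr) <= (spec$inner_size - 1) / 2 &
        abs(g$dc) <= (spec$inner_size - 1) / 2
      m & !cut
    },
    pyramid_steps = square_region(g, spec$size),
    bipartite_field = square_region(g, spec$size)
  )
}

inducer_ring_halfsizes <- function(spec) {
  # rings that survive the central cut-out and fit inside `size`
  lo <- spec$inner_size / 2 + spec$spacing / 2
  hi <- spec$size / 2
  if (lo > hi) stop("inducer pattern: no rings fit between inner_size and size")
  seq(lo, hi, by = spec$spacing)
}

separable_gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {           # along rows (down columns), replicate pad
    n <- nrow(m)
    pad <- rbind(m[rep(1, r), , drop = FALSE], m,
                 m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(x))))
}

#' Render a shape onto a uniform background
#'
#' Paints the shape at its luminance over a uniform background canvas and,
#' when \code{blur_sigma > 0}, smooths the result with an isotropic Gaussian.
#' Rendering is fully deterministic.
#'
#' @param spec A [shape_spec()].
#' @param canvas Canvas dimensions \code{c(height, width)}.
#' @param background Background luminance in [0, 1].
#' @param duration Frame duration in seconds.
#' @return A [frame()].
#' @export
render_shape <- function(spec, canvas, background = 0.5, duration = 1) {
  stopifnot(background >= 0, background <= 1)
  check_extent(spec, canvas)
  lum <- matrix(background, canvas[1], canvas[2])
  lum <- paint_shape(lum, spec, background)
  if (spec$blur_sigma > 0) lum <- separable_gaussian_blur(lum, spec$blur_sigma)
  frame(lum, duration)
}

check_extent <- function(spec, canvas) {
  half_rc <- switch(spec$kind,
    two_holed_annulus = c(spec$size / 4, spec$size / 2),
    vertical_line = c(spec$size / 2, spec$line_width / 2),
    c(spec$size / 2, spec$size / 2))
  lo_r <- spec$center[1] - half_rc[1]; hi_r <- spec$center[1] + half_rc[1]
  lo_c <- spec$center[2] - half_rc[2]; hi_c <- spec$center[2] + half_rc[2]
  if (lo_r < 0.5 || lo_c < 0.5 || hi_r > canvas[1] + 0.5 || hi_c > canvas[2] + 0.5)
    stop(sprintf(paste0("shape '%s' exceeds canvas: rows [%.1f, %.1f], ",
                        "cols [%.1f, %.1f] vs canvas %d x %d"),
                 spec$kind, lo_r, hi_r, lo_c, hi_c, canvas[1], canvas[2]))
  invisible(TRUE)
}

# paint one (possibly multi-tone) shape onto an existing luminance matrix
paint_shape <- function(lum, spec, background) {
  canvas <- dim(lum)
  if (spec$kind == "polar_checkerboard") {
    g <- offset_grids(canvas, spec$center)
    r <- sqrt(g$dr^2 + g$dc^2)
    th <- atan2(g$dr, g$dc)
    diams <- sort(unique(c(spec$rings, spec$size)))
    ring_idx <- matrix(findInterval(r, diams / 2), canvas[1], canvas[2])
    sec_idx <- floor((th + pi) / (2 * pi / spec$sectors))
    parity <- (ring_idx + sec_idx) %% 2
    region <- disk_region(g, spec$size)
    vals <- ifelse(parity == 0, spec$luminance, 1 - spec$luminance)
    lum[region] <- vals[region]
  } else if (spec$kind == "bipartite_field") {
    g <- offset_grids(canvas, spec$center)
    region <- square_region(g, spec$size)
    lum[region & g$dc <= 0] <- spec$luminance
    lum[region & g$dc > 0] <- 1 - spec$luminance
  } else if (spec$kind == "pyramid_steps") {
    g <- offset_grids(canvas, spec$center)
    ns <- max(1L, spec$steps)
    sides <- if (ns == 1) spec$size else
      seq(spec$size, spec$inner_size, length.out = ns)
    for (i in seq_len(ns)) {
      lev <- background + i / ns * (spec$luminance - background)
      lum[square_region(g, sides[i])] <- lev
    }
  } else {
    lum[shape_mask(spec, canvas)] <- spec$luminance
  }
  lum
}

# render a list of shape specs composed on one background; blur is applied
# per shape so sharp and blurred elements can share a frame
render_shapes <- function(specs, canvas, background = 0.5, duration = 1) {
  lum <- matrix(background, canvas[1], canvas[2])
  for (sp in specs) {
    check_extent(sp, canvas)
    one <- paint_shape(matrix(background, canvas[1], canvas[2]), sp, background)
    if (sp$blur_sigma > 0) one <- separable_gaussian_blur(one, sp$blur_sigma)
    lum <- lum + (one - background)
  }
  frame(pmin(pmax(lum, 0), 1), duration)
}
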