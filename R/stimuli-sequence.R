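#' Stimulus frame
#'
#' One grayscale luminance image with a presentation duration.
#'
#' @param luminance Numeric matrix with values in [0, 1]
#'   (0 = black, 0.5 = background gray, 1 = white).
#' @param duration Presentation time in seconds, > 0.
#' @return An object of class \code{erasim_frame}.
#' @export
frame <- function(luminance, duration) {
  stopifnot(is.matrix(luminance), is.numeric(luminance))
  if (any(luminance < 0 | luminance > 1))
    stop("frame luminance must lie in [0, 1]")
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("frame duration must be a positive scalar (seconds)")
  structure(list(luminance = luminance, duration = duration),
            class = "erasim_frame")
}

#' Stimulus sequence (movie)
#'
#' An ordered list of [frame()]s sharing one grid, plus named boolean
#' annotation masks (e.g. \code{target_*}, \code{surround_*},
#' \code{adapted_region}) used by the visibility measurements.
#'
#' @param frames List of [frame()] objects with identical dimensions.
#' @param annotations Named list of logical matrices matching the grid.
#' @return An object of class \code{stimulus_sequence} with elements
#'   \code{frames}, \code{shape} (grid \code{c(height, width)}) and
#'   \code{annotations}.
#' @export
stimulus_sequence <- function(frames, annotations = list()) {
  stopifnot(length(frames) >= 1,
            all(vapply(frames, inherits, TRUE, "erasim_frame")))
  dims <- vapply(frames, function(f) dim(f$luminance), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share an identical grid shape")
  shape <- dims[, 1]
  for (nm in names(annotations)) {
    m <- annotations[[nm]]
    if (!is.matrix(m) || !is.logical(m) || !all(dim(m) == shape))
      stop(sprintf("annotation '%s' must be a logical matrix matching the grid", nm))
  }
  structure(list(frames = frames, shape = shape, annotations = annotations),
            class = "stimulus_sequence")
}

#' Total duration of a sequence
#' @param sequence A [stimulus_sequence()].
#' @return Sum of frame durations in seconds.
#' @export
total_duration <- function(sequence) {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  sum(vapply(sequence$frames, function(f) f$duration, numeric(1)))
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("stimulus_sequence: %d frames, %d x %d px, %.2f s total\n",
              length(x$frames), x$shape[1], x$shape[2], total_duration(x)))
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Flickering adaptation sequence for one shape
#'
#' Alternates the shape between white (luminance 1) and black (luminance 0)
#' on the gray background, each polarity shown for \code{half_period}
#' seconds.  Over any full cycle the time-average luminance inside the shape
#' equals the background, so flicker adaptation carries no net luminance
#' signal.
#'
#' @param spec A [shape_spec()]; its \code{luminance} field is overridden by
#'   the alternation.
#' @param duration Total flicker duration (s); must be at least one full
#'   cycle (\code{2 * half_period}).
#' @param half_period Duration of each polarity (s); default 0.25 s (2 Hz
#'   full cycles).
#' @param background Background luminance.
#' @param canvas Canvas dimensions \code{c(height, width)}.
#' @return A [stimulus_sequence()] whose \code{adapted_region} annotation is
#'   the shape's pixel mask.
#' @export
make_flicker_sequence <- function(spec, duration, half_period = 0.25,
                                  background = 0.5,
                                  canvas = c(128, 128)) {
  if (half_period <= 0) stop("half_period must be positive")
  if (duration < 2 * half_period)
    stop("duration must cover at least one full flicker cycle")
  frames <- flicker_frames(list(spec), duration, half_period, background,
                           canvas)
  stimulus_sequence(frames,
                    annotations = list(adapted_region = shape_mask(spec, canvas)))
}

# alternating white/black frames for a list of specs on one canvas
flicker_frames <- function(specs, duration, half_period, background, canvas) {
  n <- floor(duration / half_period + 1e-9)
  lums <- c(1, 0)
  lapply(seq_len(n), function(i) {
    sps <- lapply(specs, function(sp) { sp$luminance <- lums[(i - 1) %% 2 + 1]; sp })
    render_shapes(sps, canvas, background, duration = half_period)
  })
}

uniform_frames <- function(duration, background, canvas, chunk = 0.5) {
  n <- max(1L, ceiling(duration / chunk))
  d <- duration / n
  lapply(seq_len(n), function(i)
    frame(matrix(background, canvas[1], canvas[2]), d))
}

#' Surround ring of a target mask
#'
#' Annular neighbourhood used as the comparison region when measuring target
#' visibility: pixels within \code{outer} dilations of the target but beyond
#' \code{inner}, minus any excluded pixels.
#'
#' @param mask Logical target mask.
#' @param inner,outer Dilation radii in pixels.
#' @param exclude Optional logical mask of pixels to drop (e.g. other
#'   targets).
#' @return Logical matrix.
#' @export
mask_ring <- function(mask, inner = 2, outer = 10, exclude = NULL) {
  ring <- dilate_mask(mask, outer) & !dilate_mask(mask, inner)
  if (!is.null(exclude)) ring <- ring & !exclude
  ring
}

# split the boundary pixels of a region mask by the orientation of the edge
# they sit on: a vertical edge is a transition along the horizontal direction
edge_masks <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  r <- 2:(h + 1); cc <- 2:(w + 1)
  vert <- xor(pad[r, cc], pad[r, cc - 1]) | xor(pad[r, cc], pad[r, cc + 1])
  horiz <- xor(pad[r, cc], pad[r - 1, cc]) | xor(pad[r, cc], pad[r + 1, cc])
  list(vertical = vert & !horiz, horizontal = horiz & !vert)
}
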