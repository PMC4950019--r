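#' Export a stimulus sequence as PNG frames with a JSON sidecar
#'
#' Writes each frame as an 8-bit grayscale PNG (\code{frame_0001.png}, ...)
#' plus \code{sequence.json} listing per-frame durations and run-length
#' encoded annotation masks.
#'
#' @param sequence A [stimulus_sequence()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix for the frames.
#' @return The directory path, invisibly.
#' @export
write_sequence <- function(sequence, dir, prefix = "frame") {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(sequence$frames))
  for (i in seq_along(sequence$frames)) {
    files[i] <- sprintf("%s_%04d.png", prefix, i)
    png::writePNG(sequence$frames[[i]]$luminance, file.path(dir, files[i]))
  }
  rle_mask <- function(m) {
    r <- rle(as.logical(m))
    list(dim = dim(m), values = r$values, lengths = r$lengths)
  }
  meta <- list(shape = sequence$shape,
               durations = vapply(sequence$frames, function(f) f$duration,
                                  numeric(1)),
               files = files,
               annotations = lapply(sequence$annotations, rle_mask))
  jsonlite::write_json(meta, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export a boundary snapshot as a two-channel PNG
#'
#' Green encodes vertical boundary strength and blue horizontal boundary
#' strength, each normalised by \code{scale}.
#'
#' @param boundaries A \code{boundary_field}.
#' @param path Output PNG path.
#' @param scale Boundary strength mapped to full intensity.
#' @return \code{path}, invisibly.
#' @export
write_boundary_png <- function(boundaries, path, scale = NULL) {
  v <- boundaries$vertical; hb <- boundaries$horizontal
  if (is.null(scale)) scale <- max(v, hb, 1e-12)
  img <- array(0, c(nrow(v), ncol(v), 3))
  img[, , 2] <- pmin(v / scale, 1)
  img[, , 3] <- pmin(hb / scale, 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Export a percept snapshot as a grayscale PNG
#' @param percept A \code{percept_field}.
#' @param path Output PNG path.
#' @param background,gain Passed to [readout_brightness()].
#' @return \code{path}, invisibly.
#' @export
write_percept_png <- function(percept, path, background = 0.5, gain = 0.2) {
  png::writePNG(readout_brightness(percept, background, gain)$luminance, path)
  invisible(path)
}

#' Three-column contact sheet of a simulation trace
#'
#' Writes one PNG whose rows are sampled times and whose columns show the
#' stimulus, the boundary response (green = vertical, blue = horizontal) and
#' the filled-in percept.
#'
#' @param trace A \code{simulation_trace} from [run_simulation()].
#' @param path Output PNG path.
#' @param rows Number of sampled times (spread over the trace).
#' @return \code{path}, invisibly.
#' @export
write_contact_sheet <- function(trace, path, rows = 3) {
  idx <- unique(round(seq(1, length(trace$times), length.out = rows)))
  # stimulus frame active at each snapshot time
  ends <- cumsum(vapply(trace$sequence$frames, function(f) f$duration,
                        numeric(1)))
  pars <- trace$params
  h <- trace$sequence$shape[1]; w <- trace$sequence$shape[2]
  pad <- 2
  sheet <- array(1, c(length(idx) * (h + pad) - pad, 3 * (w + pad) - pad, 3))
  bscale <- max(vapply(trace$boundaries[idx], function(b)
    max(b$vertical, b$horizontal), numeric(1)), 1e-12)
  for (i in seq_along(idx)) {
    k <- idx[i]
    fi <- min(which(ends >= trace$times[k] - 1e-9))
    r0 <- (i - 1) * (h + pad)
    stim <- trace$sequence$frames[[fi]]$luminance
    for (ch in 1:3) sheet[r0 + 1:h, 1:w, ch] <- stim
    b <- trace$boundaries[[k]]
    sheet[r0 + 1:h, (w + pad) + 1:w, 1] <- 0
    sheet[r0 + 1:h, (w + pad) + 1:w, 2] <- pmin(b$vertical / bscale, 1)
    sheet[r0 + 1:h, (w + pad) + 1:w, 3] <- pmin(b$horizontal / bscale, 1)
    per <- readout_brightness(trace$percepts[[k]], pars$background,
                              pars$readout_gain)$luminance
    for (ch in 1:3) sheet[r0 + 1:h, 2 * (w + pad) + 1:w, ch] <- per
  }
  png::writePNG(sheet, path)
  invisible(path)
}

#' Bar chart of a threshold battery
#'
#' Grouped bars of contrast threshold per condition, adapt versus no-adapt.
#' Conditions where the target never reached criterion at maximum contrast
#' are drawn at the search ceiling (0.5) and flagged.
#'
#' @param battery Data frame from [run_experiment_battery()].
#' @return A ggplot object.
#' @export
plot_battery <- function(battery) {
  b <- battery
  b$threshold_plot <- ifelse(b$not_visible_at_max, 0.5, b$threshold_contrast)
  b$condition <- if ("adaptor_deg" %in% names(b))
    ifelse(b$adapted, sprintf("adapt %g deg", b$adaptor_deg), "no adapt")
  else if ("inner_check_deg" %in% names(b))
    ifelse(b$adapted, sprintf("checks %g deg", b$inner_check_deg), "no adapt")
  else b$target
  b$panel <- if ("test_deg" %in% names(b))
    sprintf("test %g deg", b$test_deg) else b$battery_id
  ggplot2::ggplot(b, ggplot2::aes(x = .data$condition,
                                  y = .data$threshold_plot,
                                  fill = .data$adapted)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "contrast threshold (model units)",
                  fill = "adapted") +
    ggplot2::theme_minimal()
}
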