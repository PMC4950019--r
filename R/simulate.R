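#' Initial model state
#'
#' Fully recovered transmitter gates and an empty (zero) filling-in stage.
#'
#' @param dims Grid dimensions \code{c(height, width)}.
#' @return An object of class \code{model_state} with elements \code{gates}
#'   and \code{percept}.
#' @export
model_state <- function(dims) {
  structure(list(gates = fresh_gates(dims), percept = empty_percept(dims)),
            class = "model_state")
}

# integrate one constant-stimulus interval with the compiled core
integrate_frame_engine <- function(state, drive, source, params, nsteps) {
  d <- params$dipole; f <- params$fill
  max_sig <- max(drive$vertical, drive$horizontal) + d$tonic
  if (params$dt * (d$alpha + d$beta * max_sig) >= 1)
    stop("gate step unstable at this dt; reduce dt")
  if (params$engine == "cpp") {
    res <- integrate_frame_cpp(state$gates$z_vertical + 0,
                               state$gates$z_horizontal + 0,
                               state$percept$on_fill + 0,
                               state$percept$off_fill + 0,
                               drive$vertical, drive$horizontal,
                               source$on, source$off,
                               d$alpha, d$beta, d$tonic, d$out_threshold,
                               f$decay, f$couple, f$block, f$input_gain,
                               params$dt, as.integer(nsteps),
                               as.integer(params$fill_substeps))
    state$gates$z_vertical <- res$z_vertical
    state$gates$z_horizontal <- res$z_horizontal
    state$percept <- structure(list(on_fill = res$on_fill,
                                    off_fill = res$off_fill,
                                    brightness = res$on_fill - res$off_fill),
                               class = "percept_field")
    boundaries <- structure(list(vertical = res$bv, horizontal = res$bh),
                            class = "boundary_field")
  } else {
    boundaries <- NULL
    dtf <- params$dt / params$fill_substeps
    for (i in seq_len(nsteps)) {
      boundaries <- dipole_output(drive, state$gates, d)
      perm <- permeability(boundaries, f)
      for (s in seq_len(params$fill_substeps))
        state$percept <- step_filling(state$percept, source, perm, f, dtf)
      state$gates <- step_gates(state$gates, drive, d, params$dt)
    }
  }
  list(state = state, boundaries = boundaries)
}

#' Run the full model on a stimulus sequence
#'
#' Integrates front end, boundary system and filling-in over every frame of
#' the movie.  Within a frame the stimulus is constant, so the opponent
#' decomposition and the oriented drive are computed once per frame and the
#' dynamics advanced with the configured Euler steps.  The simulation is
#' fully deterministic.
#'
#' @param sequence A [stimulus_sequence()].
#' @param params An [erasim_params()].
#' @param sample_every Snapshot cadence in seconds; \code{NULL} records one
#'   snapshot at the end of each frame.
#' @param initial_state Optional \code{model_state} to resume from (used by
#'   the threshold harness to reuse an adaptation phase).
#' @return An object of class \code{simulation_trace}: \code{times}
#'   (snapshot times, s), \code{boundaries} and \code{percepts} (lists of
#'   snapshots aligned with \code{times}), \code{sequence}, \code{params}
#'   and the final \code{state}.
#' @export
#' @examples
#' seq <- make_flicker_sequence(
#'   shape_spec("outline_square", c(16, 16), 20), duration = 0.5,
#'   canvas = c(32, 32))
#' tr <- run_simulation(seq, erasim_params(engine = "r"))
#' tr$times
run_simulation <- function(sequence, params = erasim_params(),
                           sample_every = NULL, initial_state = NULL) {
  stopifnot(inherits(sequence, "stimulus_sequence"),
            inherits(params, "erasim_params"))
  state <- if (is.null(initial_state)) model_state(sequence$shape)
           else initial_state
  times <- numeric(0)
  boundaries <- list()
  percepts <- list()
  t <- 0
  for (fr in sequence$frames) {
    source <- to_opponent(fr, params$background)
    drive <- oriented_contrast(source, params$dipole)
    chunks <- if (is.null(sample_every)) fr$duration else
      rep(sample_every, length.out = max(1, ceiling(fr$duration / sample_every)))
    if (!is.null(sample_every))
      chunks[length(chunks)] <- fr$duration - sample_every * (length(chunks) - 1)
    for (chunk in chunks) {
      nsteps <- max(1L, round(chunk / params$dt))
      res <- integrate_frame_engine(state, drive, source, params, nsteps)
      state <- res$state
      t <- t + nsteps * params$dt
      times <- c(times, t)
      boundaries[[length(boundaries) + 1L]] <-
        if (!is.null(res$boundaries)) res$boundaries
        else dipole_output(drive, state$gates, params$dipole)
      percepts[[length(percepts) + 1L]] <- state$percept
    }
  }
  structure(list(times = times, boundaries = boundaries, percepts = percepts,
                 sequence = sequence, params = params, state = state),
            class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("simulation_trace: %d snapshots over %.2f s on a %d x %d grid\n",
              length(x$times), max(x$times), x$sequence$shape[1],
              x$sequence$shape[2]))
  invisible(x)
}
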