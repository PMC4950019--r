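#' Gated-dipole parameters
#'
#' Parameters of the habituating gated dipole circuit that generates
#' adaptable oriented boundary signals.  Each image pixel carries one such
#' circuit with a vertically and a horizontally tuned channel.  First-layer
#' activity for a channel is \code{drive + tonic}; it passes through a
#' transmitter gate \code{z} obeying mass-action habituation
#' \deqn{dz/dt = alpha (1 - z) - beta (drive + tonic) z,}
#' and the thresholded third-layer output subtracts the orthogonal channel:
#' \deqn{out_o = max(0, y_o - y_{perp} - \Gamma), \quad y_o = (drive_o + tonic) z_o.}
#'
#' @param alpha Gate recovery rate (1/s).  Slow recovery makes adaptation
#'   persist across the test interval.
#' @param beta Gate depletion rate per unit gated signal (1/s).
#' @param tonic Constant common input to both channels; it is the energy
#'   source for rebound after-responses when cross-channel inhibition drops.
#' @param out_threshold Output threshold \eqn{\Gamma} of the third layer.
#' @param drive_gain Scale factor from opponent-channel contrast differences
#'   to first-layer oriented drive.
#' @param pool_sigma Spatial extent (pixels) of the 1-D pooling of each
#'   orientation's drive along its own edge direction (the elongated
#'   receptive-field axis); 0 disables pooling.
#'
#' @return An object of class \code{dipole_params}.
#' @seealso [fill_params()], [erasim_params()], [simulate_dipole_trace()]
#' @export
#' @examples
#' p <- dipole_params()
#' gate_equilibrium(p, signal = 1)
dipole_params <- function(alpha = 0.05, beta = 0.1, tonic = 0.2,
                          out_threshold = 0.04, drive_gain = 40,
                          pool_sigma = 2) {
  stopifnot(alpha > 0, beta > 0, drive_gain > 0, tonic >= 0,
            out_threshold >= 0, pool_sigma >= 0)
  structure(list(alpha = alpha, beta = beta, tonic = tonic,
                 out_threshold = out_threshold, drive_gain = drive_gain,
                 pool_sigma = pool_sigma),
            class = "dipole_params")
}

#' Equilibrium gate level under a constant signal
#'
#' Closed-form fixed point of the mass-action gate equation,
#' \eqn{z^* = alpha / (alpha + beta S)} for constant total signal \eqn{S}.
#'
#' @param params A [dipole_params()] object.
#' @param signal Constant total first-layer signal (drive + tonic), >= 0.
#' @return Equilibrium gate level in (0, 1].
#' @export
gate_equilibrium <- function(params, signal) {
  stopifnot(inherits(params, "dipole_params"), all(signal >= 0))
  params$alpha / (params$alpha + params$beta * signal)
}

#' Filling-in parameters
#'
#' Parameters of the boundary-gated diffusion that spreads opponent surface
#' (brightness) signals on a 4-neighbour pixel lattice:
#' \deqn{dx_p/dt = -A x_p + \sum_{q \in N4(p)} P_{pq} (x_q - x_p) + C s_p,}
#' where the permeability between horizontal neighbours is
#' \eqn{P = D / (1 + E (V_p + V_q))} with \eqn{V} the vertical boundary
#' strengths (vertical boundaries block horizontal flow) and symmetrically
#' for vertical flow and horizontal boundaries.
#'
#' @param decay Passive decay rate \eqn{A} (1/s).
#' @param couple Baseline inter-pixel permeability \eqn{D} (1/s).  With decay
#'   \eqn{A}, the free-diffusion length scale is \eqn{\sqrt{D/A}} pixels; it
#'   must exceed the extent of shapes that are supposed to blend into the
#'   background once their boundaries are erased.
#' @param block Boundary blocking strength \eqn{E} (dimensionless).
#' @param input_gain Feed gain \eqn{C} (1/s) from the opponent input to the
#'   filling-in stage.
#' @return An object of class \code{fill_params}.
#' @seealso [permeability()], [step_filling()], [steady_state_oracle()]
#' @export
fill_params <- function(decay = 0.5, couple = 1500, block = 1000, input_gain = 5) {
  stopifnot(decay >= 0, couple > 0, block >= 0, input_gain > 0)
  structure(list(decay = decay, couple = couple, block = block,
                 input_gain = input_gain),
            class = "fill_params")
}

#' Full model configuration
#'
#' Bundles dipole and filling-in parameters with the integration and
#' stimulus-rendering settings shared by every simulation.
#'
#' @param dipole A [dipole_params()] object.
#' @param fill A [fill_params()] object.
#' @param dt Boundary-system Euler step (s).  The filling-in stage sub-steps
#'   within each boundary step so that its own stability guard
#'   \eqn{dt (A + 4D + C) < 1} holds.
#' @param background Background (reference) luminance in [0, 1].
#' @param readout_gain Gain from signed filled-in activity to displayed
#'   luminance.  The default \code{decay / input_gain} makes a fully trapped
#'   uniform region round-trip to its stimulus luminance at steady state.
#' @param px_per_deg Pixels per degree of visual angle used when geometry is
#'   given in degrees.
#' @param engine \code{"cpp"} for the compiled core (default) or \code{"r"}
#'   for the reference pure-R integrator (identical results, used for
#'   cross-checking).
#' @return An object of class \code{erasim_params}.
#' @export
#' @examples
#' pars <- erasim_params()
#' pars$fill_substeps          # sub-steps honouring the stability guard
erasim_params <- function(dipole = dipole_params(), fill = fill_params(),
                          dt = 0.005, background = 0.5,
                          readout_gain = fill$decay / fill$input_gain,
                          px_per_deg = 10, engine = c("cpp", "r")) {
  stopifnot(inherits(dipole, "dipole_params"), inherits(fill, "fill_params"),
            dt > 0, background >= 0, background <= 1, px_per_deg > 0)
  engine <- match.arg(engine)
  rate <- fill$decay + 4 * fill$couple + fill$input_gain
  # sub-step count such that dt_fill * rate < 1 with a 25% margin
  nsub <- max(1L, ceiling(dt * rate / 0.8))
  structure(list(dipole = dipole, fill = fill, dt = dt,
                 fill_substeps = nsub, background = background,
                 readout_gain = readout_gain, px_per_deg = px_per_deg,
                 engine = engine),
            class = "erasim_params")
}

#' @export
print.erasim_params <- function(x, ...) {
  d <- x$dipole; f <- x$fill
  cat("erasim model configuration\n")
  cat(sprintf("  dipole: alpha=%.3g beta=%.3g tonic=%.3g threshold=%.3g gain=%.3g\n",
              d$alpha, d$beta, d$tonic, d$out_threshold, d$drive_gain))
  cat(sprintf("  fill:   decay=%.3g couple=%.3g block=%.3g input_gain=%.3g\n",
              f$decay, f$couple, f$block, f$input_gain))
  cat(sprintf("  dt=%.4gs (%d filling sub-steps), background=%.2f, %g px/deg, engine=%s\n",
              x$dt, x$fill_substeps, x$background, x$px_per_deg, x$engine))
  invisible(x)
}

#' Read / write a model configuration as YAML
#'
#' Round-trip serialization of an [erasim_params()] object, used by the
#' command-line interface.
#'
#' @param params An [erasim_params()] object.
#' @param path File path.
#' @return \code{write_params} returns \code{path} invisibly;
#'   \code{read_params} returns an [erasim_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "erasim_params"))
  x <- list(dipole = unclass(params$dipole), fill = unclass(params$fill),
            dt = params$dt, background = params$background,
            readout_gain = params$readout_gain, px_per_deg = params$px_per_deg,
            engine = params$engine)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  erasim_params(dipole = do.call(dipole_params, x$dipole),
                fill = do.call(fill_params, x$fill),
                dt = x$dt, background = x$background,
                readout_gain = x$readout_gain, px_per_deg = x$px_per_deg,
                engine = x$engine)
}

#' Stable hash of a model configuration
#'
#' Deterministic short hash used in provenance blocks of CLI outputs.
#' @param params An [erasim_params()] object.
#' @return A character scalar.
#' @export
params_hash <- function(params) {
  stopifnot(inherits(params, "erasim_params"))
  s <- jsonlite::toJSON(list(d = unclass(params$dipole), f = unclass(params$fill),
                             dt = params$dt, bg = params$background,
                             g = params$readout_gain, ppd = params$px_per_deg),
                        auto_unbox = TRUE, digits = NA)
  raw <- as.integer(charToRaw(as.character(s)))
  # polynomial rolling hash mod 2^31 - 1; plenty for a provenance tag and
  # exact in double precision
  h <- 17
  for (b in raw) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
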