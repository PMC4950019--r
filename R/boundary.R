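#' Oriented contrast drive from an opponent field
#'
#' Converts the signed opponent signal \code{S = on - off} into drives for
#' vertically and horizontally tuned boundary cells by central differencing:
#' a vertical edge (luminance changing along the horizontal direction)
#' excites vertically tuned cells,
#' \deqn{V(r,c) = g |S(r, c+1) - S(r, c-1)|, \quad
#'       H(r,c) = g |S(r+1, c) - S(r-1, c)|,}
#' with one-sided differences at the image border.
#'
#' Each orientation's drive is then pooled along its own edge direction with
#' a short one-dimensional Gaussian (\code{pool_sigma} pixels), emulating the
#' elongated receptive field of an oriented cell.  Along a straight edge the
#' pooling is the identity; on staircase-rasterised curves it breaks the
#' exact vertical/horizontal ties that full cross-orientation opponency
#' would otherwise null out, leaving only narrow gaps near 45 degrees.
#'
#' @param field An \code{opponent_field} from [to_opponent()].
#' @param params A [dipole_params()] supplying \code{drive_gain} and
#'   \code{pool_sigma}.
#' @return An object of class \code{oriented_drive} with non-negative
#'   matrices \code{vertical} and \code{horizontal}.
#' @export
oriented_contrast <- function(field, params = dipole_params()) {
  stopifnot(inherits(field, "opponent_field"), inherits(params, "dipole_params"))
  s <- field$on - field$off
  h <- nrow(s); w <- ncol(s)
  right <- s[, c(2:w, w), drop = FALSE]
  left <- s[, c(1, 1:(w - 1)), drop = FALSE]
  down <- s[c(2:h, h), , drop = FALSE]
  up <- s[c(1, 1:(h - 1)), , drop = FALSE]
  v <- params$drive_gain * abs(right - left)
  hh <- params$drive_gain * abs(down - up)
  if (params$pool_sigma > 0) {
    v <- pool_1d(v, params$pool_sigma, along = "rows")
    hh <- pool_1d(hh, params$pool_sigma, along = "cols")
  }
  structure(list(vertical = v, horizontal = hh), class = "oriented_drive")
}

# 1-D Gaussian smoothing along rows (down each column) or along columns,
# with replicate padding; kernel radius 3 sigma
pool_1d <- function(x, sigma, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") return(t(pool_1d(t(x), sigma, "rows")))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(x)
  pad <- rbind(x[rep(1, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(x))
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
  out
}

#' One Euler step of the habituating transmitter gates
#'
#' Integrates the mass-action gate equation
#' \code{dz/dt = alpha (1 - z) - beta (drive + tonic) z} for both
#' orientations with an explicit Euler step, then clamps to (0, 1].
#'
#' @param gates A \code{gate_state} (list with matrices \code{z_vertical},
#'   \code{z_horizontal}) as produced by [fresh_gates()].
#' @param drive An \code{oriented_drive}.
#' @param params A [dipole_params()].
#' @param dt Time step in seconds; must satisfy the stability guard
#'   \code{dt * (alpha + beta * max_signal) < 1}.
#' @return Updated \code{gate_state}.
#' @export
step_gates <- function(gates, drive, params, dt) {
  stopifnot(dt > 0)
  max_sig <- max(drive$vertical, drive$horizontal) + params$tonic
  if (dt * (params$alpha + params$beta * max_sig) >= 1)
    stop(sprintf(paste0("gate step unstable: dt * (alpha + beta * max_signal)",
                        " = %.3f >= 1; use a smaller dt"),
                 dt * (params$alpha + params$beta * max_sig)))
  upd <- function(z, d) {
    zn <- z + dt * (params$alpha * (1 - z) -
                      params$beta * (d + params$tonic) * z)
    pmin(pmax(zn, .Machine$double.eps), 1)
  }
  structure(list(z_vertical = upd(gates$z_vertical, drive$vertical),
                 z_horizontal = upd(gates$z_horizontal, drive$horizontal)),
            class = "gate_state")
}

#' Fully recovered gate state
#' @param dims Grid dimensions \code{c(height, width)}.
#' @return A \code{gate_state} with all gates at 1.
#' @export
fresh_gates <- function(dims) {
  one <- matrix(1, dims[1], dims[2])
  structure(list(z_vertical = one, z_horizontal = one), class = "gate_state")
}

#' Thresholded opponent output of the gated dipole
#'
#' Second-layer activity is the gated first-layer signal
#' \code{y_o = (drive_o + tonic) * z_o}; the third layer subtracts the
#' orthogonal channel and an output threshold:
#' \code{out_o = max(0, y_o - y_perp - Gamma)}.  At most one orientation is
#' positive per pixel; exact ties yield zero in both.
#'
#' @param drive An \code{oriented_drive}.
#' @param gates A \code{gate_state}.
#' @param params A [dipole_params()].
#' @return An object of class \code{boundary_field} with non-negative
#'   matrices \code{vertical} and \code{horizontal}.
#' @export
dipole_output <- function(drive, gates, params) {
  yv <- (drive$vertical + params$tonic) * gates$z_vertical
  yh <- (drive$horizontal + params$tonic) * gates$z_horizontal
  structure(list(vertical = pmax(yv - yh - params$out_threshold, 0),
                 horizontal = pmax(yh - yv - params$out_threshold, 0)),
            class = "boundary_field")
}

#' Single-pixel gated-dipole time course
#'
#' Integrates one dipole circuit under a piecewise-constant schedule of
#' vertical and horizontal drives and returns the unthresholded
#' second-layer activities together with gate levels and thresholded
#' outputs.  The default schedule follows the canonical adaptation protocol:
#' a strong vertical drive for 4 s followed by a weak vertical drive for
#' 2 s, which produces a transient rebound in the horizontal channel at the
#' input decrement.
#'
#' @param schedule Data frame with columns \code{duration} (s),
#'   \code{vertical} and \code{horizontal} (drive levels).
#' @param params A [dipole_params()].
#' @param dt Euler step (s).
#' @return A data frame with columns \code{time}, \code{y_vertical},
#'   \code{y_horizontal} (unthresholded), \code{z_vertical},
#'   \code{z_horizontal}, \code{out_vertical}, \code{out_horizontal}.
#' @export
#' @examples
#' tr <- simulate_dipole_trace()
#' # rebound: horizontal output becomes transiently positive after t = 4 s
#' max(tr$out_horizontal[tr$time > 4])
simulate_dipole_trace <- function(schedule = data.frame(duration = c(4, 2),
                                                        vertical = c(20, 2),
                                                        horizontal = c(0, 0)),
                                  params = dipole_params(), dt = 0.005) {
  stopifnot(all(c("duration", "vertical", "horizontal") %in% names(schedule)),
            all(schedule$duration > 0))
  zv <- 1; zh <- 1; nstep <- 0L   # time = nstep * dt, kept exact
  rows <- vector("list", sum(ceiling(schedule$duration / dt)) + 1L)
  k <- 0L
  rec <- function(dv, dh) {
    yv <- (dv + params$tonic) * zv
    yh <- (dh + params$tonic) * zh
    k <<- k + 1L
    rows[[k]] <<- data.frame(time = nstep * dt, y_vertical = yv,
                             y_horizontal = yh,
                             z_vertical = zv, z_horizontal = zh,
                             out_vertical = max(yv - yh - params$out_threshold, 0),
                             out_horizontal = max(yh - yv - params$out_threshold, 0))
  }
  for (i in seq_len(nrow(schedule))) {
    dv <- schedule$vertical[i]; dh <- schedule$horizontal[i]
    n <- round(schedule$duration[i] / dt)
    for (j in seq_len(n)) {
      rec(dv, dh)
      zv <- zv + dt * (params$alpha * (1 - zv) -
                         params$beta * (dv + params$tonic) * zv)
      zh <- zh + dt * (params$alpha * (1 - zh) -
                         params$beta * (dh + params$tonic) * zh)
      zv <- min(max(zv, .Machine$double.eps), 1)
      zh <- min(max(zh, .Machine$double.eps), 1)
      nstep <- nstep + 1L
    }
  }
  rec(schedule$vertical[nrow(schedule)], schedule$horizontal[nrow(schedule)])
  do.call(rbind, rows[seq_len(k)])
}
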