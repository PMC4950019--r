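#' Boundary-gated lattice permeabilities
#'
#' Diffusion permeability between 4-neighbours, divisively gated by the
#' boundary strength of the blocking orientation at the two endpoints:
#' horizontal flow between \code{(r,c)} and \code{(r,c+1)} is
#' \code{D / (1 + E * (V(r,c) + V(r,c+1)))} (vertical boundaries block
#' horizontal flow); vertical flow uses horizontal boundary strengths
#' analogously.  Permeability is symmetric in the two endpoints.
#'
#' @param boundaries A \code{boundary_field} from [dipole_output()].
#' @param params A [fill_params()].
#' @return An object of class \code{perm_maps} with matrices \code{right}
#'   (flow \code{(r,c) <-> (r,c+1)}; last column 0) and \code{down}
#'   (flow \code{(r,c) <-> (r+1,c)}; last row 0).
#' @export
permeability <- function(boundaries, params) {
  stopifnot(inherits(params, "fill_params"))
  v <- boundaries$vertical; hb <- boundaries$horizontal
  h <- nrow(v); w <- ncol(v)
  right <- matrix(0, h, w)
  down <- matrix(0, h, w)
  right[, -w] <- params$couple /
    (1 + params$block * (v[, -w, drop = FALSE] + v[, -1, drop = FALSE]))
  down[-h, ] <- params$couple /
    (1 + params$block * (hb[-h, , drop = FALSE] + hb[-1, , drop = FALSE]))
  structure(list(right = right, down = down), class = "perm_maps")
}

#' Empty percept state
#' @param dims Grid dimensions \code{c(height, width)}.
#' @return A \code{percept_field} with zero ON and OFF activity.
#' @export
empty_percept <- function(dims) {
  z <- matrix(0, dims[1], dims[2])
  structure(list(on_fill = z, off_fill = z, brightness = z),
            class = "percept_field")
}

#' One Euler step of boundary-gated filling-in
#'
#' Independently diffuses the ON and OFF surface channels on the 4-neighbour
#' lattice:
#' \deqn{x_p \leftarrow x_p + dt [ -A x_p + \sum_{q} P_{pq} (x_q - x_p) + C s_p ],}
#' with border pixels coupling only to existing neighbours.  Signed
#' brightness is \code{on_fill - off_fill}.
#'
#' @param percept A \code{percept_field}.
#' @param source An \code{opponent_field} providing per-channel inputs.
#' @param perm A \code{perm_maps} from [permeability()].
#' @param params A [fill_params()].
#' @param dt Time step (s); must satisfy
#'   \code{dt * (decay + 4 * couple + input_gain) < 1}.
#' @return Updated \code{percept_field}.
#' @export
step_filling <- function(percept, source, perm, params, dt) {
  stopifnot(dt > 0)
  if (dt * (params$decay + 4 * params$couple + params$input_gain) >= 1)
    stop(sprintf(paste0("filling-in step unstable: dt * (A + 4D + C) = %.3f",
                        " >= 1; use a smaller dt or more sub-steps"),
                 dt * (params$decay + 4 * params$couple + params$input_gain)))
  on <- fill_step_channel(percept$on_fill, source$on, perm, params, dt)
  off <- fill_step_channel(percept$off_fill, source$off, perm, params, dt)
  structure(list(on_fill = on, off_fill = off, brightness = on - off),
            class = "percept_field")
}

fill_step_channel <- function(x, src, perm, params, dt) {
  h <- nrow(x); w <- ncol(x)
  flux <- matrix(0, h, w)
  dr <- perm$right[, -w, drop = FALSE] * (x[, -1, drop = FALSE] - x[, -w, drop = FALSE])
  flux[, -w] <- flux[, -w] + dr
  flux[, -1] <- flux[, -1] - dr
  dd <- perm$down[-h, , drop = FALSE] * (x[-1, , drop = FALSE] - x[-h, , drop = FALSE])
  flux[-h, ] <- flux[-h, ] + dd
  flux[-1, ] <- flux[-1, ] - dd
  x + dt * (-params$decay * x + flux + params$input_gain * src)
}

#' Exact steady state of the filling-in stage
#'
#' Assembles the sparse linear system \code{(A I + L(P)) x = C s}, where
#' \code{L(P)} is the graph Laplacian of the permeability-weighted lattice,
#' and solves it directly.  Intended as an independent oracle for
#' [step_filling()] on small grids.
#'
#' @param source An \code{opponent_field}.
#' @param perm A \code{perm_maps}.
#' @param params A [fill_params()].
#' @return A \code{percept_field} at steady state.
#' @export
steady_state_oracle <- function(source, perm, params) {
  h <- nrow(source$on); w <- ncol(source$on)
  if (h * w > 64 * 64)
    stop("steady_state_oracle is restricted to grids of at most 64 x 64")
  if (params$decay <= 0)
    stop("steady state requires decay > 0 (system may be singular otherwise)")
  idx <- function(r, c) (c - 1) * h + r
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(p, q, wgt) {
    ii <<- c(ii, p, q, p, q); jj <<- c(jj, q, p, p, q)
    vv <<- c(vv, -wgt, -wgt, wgt, wgt)
  }
  for (c in seq_len(w - 1)) for (r in seq_len(h)) {
    wgt <- perm$right[r, c]
    if (wgt != 0) add(idx(r, c), idx(r, c + 1), wgt)
  }
  for (c in seq_len(w)) for (r in seq_len(h - 1)) {
    wgt <- perm$down[r, c]
    if (wgt != 0) add(idx(r, c), idx(r + 1, c), wgt)
  }
  lap <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(h * w, h * w))
  sys <- lap + Matrix::Diagonal(h * w, params$decay)
  solve_ch <- function(src) {
    matrix(as.numeric(Matrix::solve(sys, params$input_gain * as.vector(src))),
           h, w)
  }
  on <- solve_ch(source$on)
  off <- solve_ch(source$off)
  structure(list(on_fill = on, off_fill = off, brightness = on - off),
            class = "percept_field")
}

#' Render the filled-in percept as a luminance frame
#'
#' Displayed luminance is
#' \code{clip(background + gain * (on_fill - off_fill), 0, 1)}.  The default
#' gain (\code{decay / input_gain}, see [erasim_params()]) makes a fully
#' trapped uniform region reproduce its stimulus luminance at steady state.
#'
#' @param percept A \code{percept_field}.
#' @param background Background luminance.
#' @param gain Brightness-to-luminance gain.
#' @return A [frame()] of duration 1.
#' @export
readout_brightness <- function(percept, background = 0.5, gain = 0.2) {
  lum <- background + gain * (percept$on_fill - percept$off_fill)
  frame(pmin(pmax(lum, 0), 1), duration = 1)
}
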