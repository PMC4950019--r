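#' Opponent ON/OFF decomposition of a luminance frame
#'
#' Splits luminance into rectified brighter-than-background (ON) and
#' darker-than-background (OFF) channels:
#' \code{on = max(0, L - background)}, \code{off = max(0, background - L)}.
#' At every pixel at most one channel is nonzero, and
#' \code{L = background + on - off} exactly.
#'
#' @param frame A [frame()] or a luminance matrix in [0, 1].
#' @param background Reference luminance.
#' @return An object of class \code{opponent_field} with matrices \code{on}
#'   and \code{off}.
#' @export
#' @examples
#' f <- frame(matrix(c(0.5, 1, 0.45, 0.5), 2, 2), duration = 1)
#' op <- to_opponent(f, background = 0.5)
#' op$on; op$off
to_opponent <- function(frame, background = 0.5) {
  lum <- if (inherits(frame, "erasim_frame")) frame$luminance else frame
  stopifnot(is.matrix(lum), all(lum >= 0 & lum <= 1))
  structure(list(on = pmax(lum - background, 0),
                 off = pmax(background - lum, 0)),
            class = "opponent_field")
}
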