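#' Build the measurement antenna array
#'
#' The default geometry is the four-layer, 60-element transceiver array of
#' z-oriented point electric dipoles at 300 MHz: 32 elements on a 0.12 m
#' circle at z = -0.06 m (11.25 deg step), 16 on a 0.115 m circle at z = 0
#' (22.5 deg step), 8 on a 0.10 m circle at z = 0.06 m (45 deg step) and 4 on
#' a 0.06 m circle at z = 0.10 m (90 deg step). Angles start on the +x axis.
#' Every element acts as both transmitter and receiver.
#'
#' @param layers A data frame with columns `n`, `radius_m`, `z_m` describing
#'   circular layers, or `NULL` for the default four-layer setup.
#' @param frequency_hz Operating frequency (Hz).
#' @param min_radius_m Antennas closer than this to the domain centre are
#'   rejected: the array must surround, not penetrate, the head region.
#' @return An `antenna_array`: positions (N x 3), z dipole orientations,
#'   frequency, and a `layer` index per element.
#' @examples
#' arr <- build_array()
#' nrow(arr$positions)
#' @export
build_array <- function(layers = NULL, frequency_hz = 3e8,
                        min_radius_m = 0.105) {
  if (is.null(layers)) {
    layers <- data.frame(
      n = c(32L, 16L, 8L, 4L),
      radius_m = c(0.12, 0.115, 0.10, 0.06),
      z_m = c(-0.06, 0, 0.06, 0.10)
    )
  }
  pos <- do.call(rbind, lapply(seq_len(nrow(layers)), function(i) {
    n <- layers$n[i]
    ang <- 2 * pi * (seq_len(n) - 1) / n
    cbind(
      x = layers$radius_m[i] * cos(ang),
      y = layers$radius_m[i] * sin(ang),
      z = rep(layers$z_m[i], n),
      layer = rep(i, n)
    )
  }))
  d <- sqrt(rowSums(pos[, 1:3, drop = FALSE]^2))
  if (any(d < min_radius_m))
    abort(sprintf(
      "antenna %d at distance %.4f m from the domain centre lies inside the head region (min %.3f m)",
      which.min(d), min(d), min_radius_m
    ))
  structure(
    list(
      positions = pos[, 1:3, drop = FALSE],
      layer = as.integer(pos[, 4]),
      orientations = matrix(rep(c(0, 0, 1), each = nrow(pos)), ncol = 3,
                            dimnames = list(NULL, c("x", "y", "z"))),
      frequency_hz = frequency_hz
    ),
    class = "antenna_array"
  )
}

#' @export
print.antenna_array <- function(x, ...) {
  cat(sprintf(
    "<antenna_array> %d z-oriented dipole transceivers in %d layers at %.3g MHz\n",
    nrow(x$positions), length(unique(x$layer)), x$frequency_hz / 1e6
  ))
  invisible(x)
}

#' Tidy antenna positions
#'
#' @param x An `antenna_array`.
#' @param ... Unused.
#' @return Tibble of element index, layer, position and cylinder radius.
#' @method tidy antenna_array
#' @export
tidy.antenna_array <- function(x, ...) {
  pos <- x$positions
  tibble::tibble(
    element = seq_len(nrow(pos)),
    layer = x$layer,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius_m = sqrt(pos[, 1]^2 + pos[, 2]^2)
  )
}
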