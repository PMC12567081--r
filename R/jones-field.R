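# Per-pixel Jones matrix fields: the image-sized container shared by the
# phantom, the interferometric reconstruction and the theziography modules.

#' Construct a per-pixel Jones matrix field
#'
#' A `jones_field` holds the four complex element maps of a 2x2 Jones matrix
#' sampled on a pixel grid, plus a logical validity mask. Masked-out pixels
#' are excluded from every downstream statistic.
#'
#' @param w11,w12,w21,w22 Complex matrices of identical dimension.
#' @param mask Logical matrix of the same dimension (default: all `TRUE`).
#' @param recovered Logical flag marking fields that came out of holographic
#'   demodulation rather than forward simulation.
#' @return An object of class `jones_field`.
#' @export
jones_field <- function(w11, w12, w21, w22, mask = NULL, recovered = FALSE) {
  dims <- dim(w11)
  if (is.null(dims) || length(dims) != 2L) {
    .stop_jtez("jones_field components must be matrices", "jtez_shape_error")
  }
  for (m in list(w12, w21, w22)) {
    if (!identical(dim(m), dims)) {
      .stop_jtez("jones_field components must share one grid", "jtez_shape_error")
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (!identical(dim(mask), dims)) {
    .stop_jtez("mask must match the component grid", "jtez_shape_error")
  }
  structure(
    list(w11 = w11, w12 = w12, w21 = w21, w22 = w22, mask = mask),
    recovered = recovered,
    class = "jones_field"
  )
}

#' @export
dim.jones_field <- function(x) dim(x$w11)

#' @export
print.jones_field <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<jones_field> %d x %d pixels, %d valid (%.1f%%)%s\n",
              d[1], d[2], sum(x$mask), 100*mean(x$mask),
              if (isTRUE(attr(x, "recovered"))) ", recovered" else ""))
  invisible(x)
}

#' Identity Jones field
#'
#' @param grid Integer vector `c(rows, cols)`.
#' @return A `jones_field` whose every pixel is the identity matrix.
#' @export
jones_field_identity <- function(grid) {
  one <- matrix(1 + 0i, grid[1], grid[2])
  zero <- matrix(0 + 0i, grid[1], grid[2])
  jones_field(one, zero, zero, one)
}

#' Convert a Jones field to a tibble
#'
#' @param x A `jones_field`.
#' @param ... Unused.
#' @return A tibble with pixel indices `a`, `b` (row, column, 1-based), the
#'   four complex elements and the mask value.
#' @export
as_tibble.jones_field <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    a = rep(seq_len(d[1]), times = d[2]),
    b = rep(seq_len(d[2]), each = d[1]),
    w11 = as.vector(x$w11), w12 = as.vector(x$w12),
    w21 = as.vector(x$w21), w22 = as.vector(x$w22),
    mask = as.vector(x$mask)
  )
}

#' Pixelwise product of a stack of Jones fields
#'
#' Composes the layers of a thin multi-layer medium in beam order: the field
#' of layer 1 is applied first, so the result is `W_L ... W_2 W_1` at every
#' pixel. Validity masks are intersected.
#'
#' @param layers List of `jones_field` objects on one grid, ordered as the
#'   beam encounters them.
#' @return A single `jones_field`.
#' @export
stack_product <- function(layers) {
  if (!length(layers)) .stop_jtez("empty layer list", "jtez_invalid_argument")
  for (f in layers) {
    if (!inherits(f, "jones_field")) {
      .stop_jtez("layers must be jones_field objects", "jtez_invalid_argument")
    }
    if (!identical(dim(f), dim(layers[[1]]))) {
      .stop_jtez("all layers must share one grid", "jtez_shape_error")
    }
  }
  acc <- layers[[1]]
  for (f in layers[-1]) {
    acc <- jones_field(
      w11 = f$w11*acc$w11 + f$w12*acc$w21,
      w12 = f$w11*acc$w12 + f$w12*acc$w22,
      w21 = f$w21*acc$w11 + f$w22*acc$w21,
      w22 = f$w21*acc$w12 + f$w22*acc$w22,
      mask = acc$mask & f$mask
    )
  }
  acc
}

# apply a scalar complex phase map (or constant) to every component
.field_scale <- function(field, phase) {
  jones_field(field$w11*phase, field$w12*phase,
              field$w21*phase, field$w22*phase,
              mask = field$mask, recovered = attr(field, "recovered"))
}

#' Reduce a Jones field to unimodular form
#'
#' Divides each pixel matrix by the principal square root of its determinant,
#' choosing the root sign so that `Re(tr(W)) >= 0`. This strips any isotropic
#' (scalar) phase accumulated along the optical path and restores
#' `det(W) = 1`, the normalization assumed by both anisotropy inversions.
#'
#' @param field A `jones_field`.
#' @return A `jones_field` with unit determinant at every pixel.
#' @export
unimodular_reduce <- function(field) {
  det <- field$w11*field$w22 - field$w12*field$w21
  s <- sqrt(det)
  s[s == 0] <- 1   # degenerate pixels left untouched; masked downstream
  flip <- Re((field$w11 + field$w22)/s) < 0
  s[flip] <- -s[flip]
  .field_scale(field, 1/s)
}
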