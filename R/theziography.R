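# Pixelwise reconstruction of the four anisotropy maps (theziograms) from a
# recovered, possibly phase-sectioned, Jones-matrix field.

#' Reconstruct the four anisotropy maps of a field
#'
#' Every valid pixel matrix is first reduced to unimodular form (stripping the
#' isotropic path phase, see [unimodular_reduce()]) and then inverted with
#' [jones_invert()]: `method = "exact"` uses the principal matrix logarithm,
#' `method = "analytic"` the closed-form arccos reconstruction. Pixels where
#' the inversion is singular (arccos argument out of domain, retardance at the
#' `2*pi` branch) are dropped from the mask and counted; if more than half of
#' the valid pixels are singular the reconstruction aborts.
#'
#' @param field A `jones_field`, typically from [demodulate()] +
#'   [rephase()], possibly restricted by [layered_field()].
#' @param method `"exact"` (default) or `"analytic"`.
#' @param convention,clip_arccos Passed to [jones_invert()] for the analytic
#'   method.
#' @return A named list of four `theziogram` objects (`LB`, `CB`, `LD`,
#'   `CD`). Each carries the value matrix, the (possibly reduced) mask, the
#'   parameter name, the phase-plane tag of the input and the dropped-pixel
#'   fraction.
#' @export
theziogram_maps <- function(field, method = c("exact", "analytic"),
                            convention = c("phase_im", "phase_re"),
                            clip_arccos = FALSE) {
  stopifnot(inherits(field, "jones_field"))
  method <- match.arg(method)
  convention <- match.arg(convention)
  if (!any(field$mask)) .stop_jtez("empty validity mask", "jtez_empty_mask")
  grid <- dim(field)
  u <- unimodular_reduce(field)
  W <- tibble::tibble(w11 = as.vector(u$w11), w12 = as.vector(u$w12),
                      w21 = as.vector(u$w21), w22 = as.vector(u$w22))
  inv <- jones_invert(W,
                      method = if (method == "exact") "matrix_log" else "analytic",
                      convention = convention, clip_arccos = clip_arccos,
                      on_singular = "flag")
  singular <- matrix(inv$singular, grid[1], grid[2])
  ok_mask <- field$mask & !singular
  dropped <- sum(field$mask & singular)/max(1, sum(field$mask))
  if (dropped > 0.5) {
    .stop_jtez(sprintf("quality failure: %.0f%% of valid pixels singular", 100*dropped),
               "jtez_quality_failure")
  }
  plane <- attr(field, "phase_plane")
  if (is.null(plane)) plane <- "integral"
  mk <- function(values, parameter) {
    structure(
      list(values = matrix(values, grid[1], grid[2]),
           mask = ok_mask, parameter = parameter,
           phase_plane = plane, method = method,
           convention = if (method == "analytic") convention else NA_character_,
           dropped_fraction = dropped),
      class = "theziogram"
    )
  }
  list(LB = mk(inv$lb, "LB"), CB = mk(inv$cb, "CB"),
       LD = mk(inv$ld, "LD"), CD = mk(inv$cd, "CD"))
}

#' @export
print.theziogram <- function(x, ...) {
  plane <- if (identical(x$phase_plane, "integral")) "integral"
           else sprintf("phi_k = %.4g", x$phase_plane)
  cat(sprintf("<theziogram> %s (%s), %d x %d px, K = %d, dropped %.2f%%\n",
              x$parameter, plane, nrow(x$values), ncol(x$values),
              sum(x$mask), 100*x$dropped_fraction))
  invisible(x)
}

#' Valid values of a theziogram
#'
#' @param x A `theziogram`.
#' @return Numeric vector of the on-mask values.
#' @export
theziogram_values <- function(x) {
  stopifnot(inherits(x, "theziogram"))
  x$values[x$mask]
}

#' Convert a theziogram to a tibble
#'
#' @param x A `theziogram`.
#' @param ... Unused.
#' @return Tibble with pixel indices, `value`, `mask`, `parameter` and
#'   `phase_plane`.
#' @export
as_tibble.theziogram <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    a = rep(seq_len(d[1]), times = d[2]),
    b = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$values),
    mask = as.vector(x$mask),
    parameter = x$parameter,
    phase_plane = if (identical(x$phase_plane, "integral")) Inf else x$phase_plane
  )
}

#' Probability histogram of a theziogram
#'
#' Bins the on-mask values over their observed range into `n_bins` equal-width
#' bins and normalizes the counts to probabilities.
#'
#' @param x A `theziogram`.
#' @param n_bins Number of bins (default 50); must not exceed the number of
#'   valid pixels.
#' @return A tibble with `bin_lower`, `bin_upper`, `bin_mid`, `probability`.
#' @export
theziogram_histogram <- function(x, n_bins = 50) {
  v <- theziogram_values(x)
  if (!length(v)) .stop_jtez("empty validity mask", "jtez_empty_mask")
  if (length(v) < n_bins) {
    .stop_jtez("fewer valid pixels than bins", "jtez_invalid_argument")
  }
  rng <- range(v)
  if (rng[1] == rng[2]) {
    return(tibble::tibble(bin_lower = rng[1], bin_upper = rng[2],
                          bin_mid = rng[1], probability = 1))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  tibble::tibble(
    bin_lower = edges[-(n_bins + 1)],
    bin_upper = edges[-1],
    bin_mid = (edges[-(n_bins + 1)] + edges[-1])/2,
    probability = counts/length(v)
  )
}
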