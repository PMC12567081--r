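# Forward synthesis of the four off-axis interference channels and their
# Fourier-sideband demodulation back to the complex Jones-matrix field — the
# digital Mach-Zehnder. Irradiation with x- or y-polarized light selects the
# (w11, w21) or (w12, w22) column of the pixel Jones matrix (the object
# field); a tilted 45-degree-polarized reference plane wave beats against
# both analyzer projections, putting the object spectrum on a spatial
# carrier that a single 2D FFT can isolate.

.carrier_ramp <- function(grid, carrier, sign = +1) {
  A <- grid[1]; B <- grid[2]
  exp(sign*2i*pi*(outer((0:(A - 1))*carrier[1], rep(1, B)) +
                  outer(rep(1, A), (0:(B - 1))*carrier[2])))
}

.hann2 <- function(grid) {
  A <- grid[1]; B <- grid[2]
  outer(0.5 - 0.5*cos(2*pi*(0:(A - 1))/(A - 1)),
        0.5 - 0.5*cos(2*pi*(0:(B - 1))/(B - 1)))
}

.fft_freqs <- function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1))/n

.channel_names <- c("s0_A0", "s0_A90", "s90_A0", "s90_A90")

#' Construct an interferogram set
#'
#' Container for the four recorded intensity images, indexed by irradiation
#' polarization `s` (0 or 90 degrees) and analyzer orientation `A` (0 or 90
#' degrees), plus the recording metadata needed for demodulation.
#'
#' @param images Named list of four non-negative real matrices
#'   (`s0_A0`, `s0_A90`, `s90_A0`, `s90_A90`).
#' @param carrier Carrier frequency `c(u, v)` in cycles/pixel, components in
#'   (0, 0.5).
#' @param reference_amplitude Amplitude of the reference wave before the
#'   45-degree split.
#' @param bit_depth `8`, `16`, or `"float"`.
#' @param gain Intensity-to-count scale applied at quantization.
#' @param wavelength Light wavelength in micrometres (metadata only).
#' @return An object of class `interferogram_set`.
#' @export
interferogram_set <- function(images, carrier, reference_amplitude = 1,
                              bit_depth = "float", gain = 1,
                              wavelength = 0.6328) {
  if (!is.list(images) || !setequal(names(images), .channel_names)) {
    .stop_jtez("images must be a named list with channels s0_A0, s0_A90, s90_A0, s90_A90",
               "jtez_format_error")
  }
  images <- images[.channel_names]
  dims <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), dims)) {
      .stop_jtez("all four channels must share one grid", "jtez_shape_error")
    }
    if (any(im < 0)) .stop_jtez("intensities must be non-negative", "jtez_format_error")
  }
  if (any(carrier <= 0) || any(carrier >= 0.5)) {
    .stop_jtez("carrier components must lie in (0, 0.5) cycles/pixel",
               "jtez_aliasing_error")
  }
  structure(list(images = images, carrier = carrier,
                 reference_amplitude = reference_amplitude,
                 bit_depth = bit_depth, gain = gain,
                 wavelength = wavelength),
            class = "interferogram_set")
}

#' @export
print.interferogram_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<interferogram_set> 4 channels, %d x %d px, carrier (%.3f, %.3f) cyc/px, %s-bit\n",
              d[1], d[2], x$carrier[1], x$carrier[2], as.character(x$bit_depth)))
  invisible(x)
}

#' Synthesize the four off-axis interference channels
#'
#' For irradiation state `s` the object field is the corresponding column of
#' the pixel Jones matrix; the reference is a tilted plane wave linearly
#' polarized at 45 degrees with amplitude `reference_amplitude`, so each
#' analyzer channel receives `r/sqrt(2)` of it. The recorded intensity is
#' `|<E_s, analyzer> + (r/sqrt(2)) exp(2i*pi*(u*a + v*b))|^2`, optionally with
#' additive Gaussian detector noise (standard deviation `noise_sd` as a
#' fraction of the peak intensity) and quantization to `bit_depth` counts.
#'
#' @param field A `jones_field` (forward-simulated object).
#' @param carrier Carrier `c(u, v)` in cycles/pixel; both in (0, 0.5).
#' @param reference_amplitude Reference amplitude `r` (default 1).
#' @param noise_sd Additive Gaussian noise, as a fraction of the peak
#'   intensity (default 0 = off).
#' @param bit_depth `16` (default), `8`, or `"float"` for no quantization.
#' @param seed Seed for the noise draw (only used when `noise_sd > 0`).
#' @return An [interferogram_set()].
#' @export
synthesize <- function(field, carrier = c(0.27, 0.27),
                       reference_amplitude = 1, noise_sd = 0,
                       bit_depth = 16, seed = 1) {
  stopifnot(inherits(field, "jones_field"))
  if (any(carrier <= 0) || any(carrier >= 0.5)) {
    .stop_jtez("carrier at or beyond the Nyquist limit of 0.5 cycles/pixel",
               "jtez_aliasing_error")
  }
  grid <- dim(field)
  ramp <- .carrier_ramp(grid, carrier, +1)
  Rc <- reference_amplitude/sqrt(2)
  channels <- list(s0_A0 = field$w11, s0_A90 = field$w21,
                   s90_A0 = field$w12, s90_A90 = field$w22)
  images <- lapply(channels, function(E) Mod(E + Rc*ramp)^2)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    peak <- max(unlist(lapply(images, max)))
    images <- lapply(images, function(I) {
      pmax(I + matrix(rnorm(prod(grid), 0, noise_sd*peak), grid[1], grid[2]), 0)
    })
  }
  gain <- 1
  if (!identical(bit_depth, "float")) {
    bits <- as.integer(bit_depth)
    peak <- max(unlist(lapply(images, max)))
    gain <- (2^bits - 1)/peak
    images <- lapply(images, function(I) round(I*gain))
  }
  interferogram_set(images, carrier = carrier,
                    reference_amplitude = reference_amplitude,
                    bit_depth = bit_depth, gain = gain)
}

# locate the strongest non-DC spectral peak of one channel -> carrier estimate
.estimate_carrier <- function(img) {
  grid <- dim(img)
  F <- Mod(fft(img))
  fa <- .fft_freqs(grid[1]); fb <- .fft_freqs(grid[2])
  near_dc <- outer(abs(fa) < 0.05, abs(fb) < 0.05)
  F[near_dc] <- 0
  if (max(F) <= 10*stats::median(F) || max(F) == 0) {
    .stop_jtez("no detectable carrier peak in the interferogram spectrum",
               "jtez_demodulation_failure")
  }
  idx <- arrayInd(which.max(F), grid)
  c(abs(fa[idx[1]]), abs(fb[idx[2]]))
}

#' Demodulate an interferogram set to the recovered Jones field
#'
#' Standard off-axis sideband demodulation, per channel: the intensity image
#' is multiplied by the conjugate carrier ramp (shifting the object sideband
#' to baseband), optionally Hann-apodized, Fourier transformed, masked with a
#' square window of half-width `window_halfwidth` cycles/pixel about the
#' origin, inverse transformed, conjugated and divided by the per-channel
#' reference amplitude `r/sqrt(2)` (and the apodization window). Channel
#' `s0_A0` becomes `w11`, `s0_A90` becomes `w21`, `s90_A0` becomes `w12` and
#' `s90_A90` becomes `w22`. A border of `border` pixels is excluded from the
#' validity mask.
#'
#' @param igs An [interferogram_set()].
#' @param window_halfwidth Sideband window half-width, cycles/pixel.
#' @param apodize Apply a 2D Hann window before the FFT (default `TRUE`).
#' @param border Border width excluded from the validity mask (pixels).
#' @param carrier Optional carrier override; when the set's carrier metadata
#'   is missing it is estimated from the strongest non-DC spectral peak.
#' @return A `jones_field` with `recovered = TRUE`.
#' @export
demodulate <- function(igs, window_halfwidth = 0.18, apodize = TRUE,
                       border = 16, carrier = NULL) {
  stopifnot(inherits(igs, "interferogram_set"))
  grid <- dim(igs$images[[1]])
  if (is.null(carrier)) carrier <- igs$carrier
  if (is.null(carrier)) carrier <- .estimate_carrier(igs$images[[1]])
  if (max(unlist(lapply(igs$images, max))) == 0) {
    .stop_jtez("all-zero interferograms: nothing to demodulate",
               "jtez_demodulation_failure")
  }
  if (min(carrier) - window_halfwidth < 0.02) {
    warning("sideband window overlaps the DC term; expect leakage", call. = FALSE)
  }
  ramp <- .carrier_ramp(grid, carrier, -1)
  h <- if (apodize) .hann2(grid) else matrix(1, grid[1], grid[2])
  fa <- .fft_freqs(grid[1]); fb <- .fft_freqs(grid[2])
  win <- outer(abs(fa) <= window_halfwidth, abs(fb) <= window_halfwidth)
  Rc <- igs$reference_amplitude/sqrt(2)
  out <- lapply(igs$images, function(I) {
    F <- fft((I/igs$gain)*ramp*h)
    lp <- fft(F*win, inverse = TRUE)/prod(grid)
    (Conj(lp)/Rc)/pmax(h, 1e-6)
  })
  mask <- matrix(FALSE, grid[1], grid[2])
  if (grid[1] > 2*border && grid[2] > 2*border) {
    mask[(border + 1):(grid[1] - border), (border + 1):(grid[2] - border)] <- TRUE
  }
  jones_field(out$s0_A0, out$s90_A0, out$s0_A90, out$s90_A90,
              mask = mask, recovered = TRUE)
}

#' Remove the global piston phase of a recovered field
#'
#' The absolute phase of a holographic reconstruction is arbitrary (it depends
#' on the reference-arm path length). Because all four channels are recorded
#' against one shared reference arm, a single piston applies to the whole
#' field: `rephase()` fixes the convention by rotating all four components so
#' that the mean phase of `w11` over the validity mask is zero. The operation
#' is idempotent and leaves every relative (inter-component and inter-pixel)
#' phase untouched.
#'
#' @param field A recovered `jones_field`.
#' @return The field with the piston convention applied; the removed piston is
#'   stored in attribute `piston`.
#' @export
rephase <- function(field) {
  stopifnot(inherits(field, "jones_field"))
  if (!any(field$mask)) .stop_jtez("empty validity mask", "jtez_empty_mask")
  piston <- Arg(mean(field$w11[field$mask]))
  out <- .field_scale(field, exp(-1i*piston))
  attr(out, "piston") <- piston
  attr(out, "recovered") <- attr(field, "recovered")
  out
}
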