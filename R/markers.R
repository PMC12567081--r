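# Statistical-moment markers Z1-Z4 of theziograms: the scalar biomarkers the
# diagnostic stage classifies on.

#' First- to fourth-order statistical moments of a map
#'
#' Population moments of the on-mask values of a theziogram (or any numeric
#' vector): `z1` the mean, `z2` the spread, `z3` the standardized skewness and
#' `z4` the kurtosis. By default `z2` is the standard deviation (the root of
#' the second central moment) so that the `1/z2^3` and `1/z2^4`
#' standardizations of `z3` and `z4` are dimensionless, and `z4` is the excess
#' kurtosis, so a Gaussian map scores `z3 = z4 = 0`. Set `z2_is_variance =
#' TRUE` for the literal second central moment, and `raw_kurtosis = TRUE` for
#' the unshifted fourth moment. Normalization is `1/K`, not `1/(K-1)`.
#'
#' A constant map has `z2 = 0`; its `z3` and `z4` are then undefined and
#' returned as `NA` with `degenerate = TRUE` (never NaN).
#'
#' @param x A `theziogram`, or a numeric vector of values.
#' @param z2_is_variance Report the second central moment instead of its root.
#' @param raw_kurtosis Report raw instead of excess kurtosis.
#' @return A one-row tibble with `z1`, `z2`, `z3`, `z4`, the pixel count `k`,
#'   a `degenerate` flag, and (for theziogram input) `parameter` and
#'   `phase_plane` tags.
#' @examples
#' central_moments(c(0, 1, 0, 1)) # z1 = 0.5, z2 = 0.5, z3 = 0, z4 = -2
#' @export
central_moments <- function(x, z2_is_variance = FALSE, raw_kurtosis = FALSE) {
  tags <- NULL
  if (inherits(x, "theziogram")) {
    tags <- list(parameter = x$parameter,
                 phase_plane = if (identical(x$phase_plane, "integral")) Inf
                               else as.numeric(x$phase_plane))
    x <- theziogram_values(x)
  }
  x <- as.numeric(x)
  k <- length(x)
  if (k < 2) .stop_jtez("need at least 2 values", "jtez_invalid_argument")
  z1 <- mean(x)
  m2 <- mean((x - z1)^2)
  s <- sqrt(m2)
  degenerate <- s == 0
  if (degenerate) {
    z3 <- NA_real_; z4 <- NA_real_
  } else {
    z3 <- mean((x - z1)^3)/s^3
    z4 <- mean((x - z1)^4)/s^4
    if (!raw_kurtosis) z4 <- z4 - 3
  }
  out <- tibble::tibble(
    z1 = z1,
    z2 = if (z2_is_variance) m2 else s,
    z3 = z3, z4 = z4, k = k, degenerate = degenerate
  )
  if (!is.null(tags)) {
    out$parameter <- tags$parameter
    out$phase_plane <- tags$phase_plane
  }
  out
}

#' Marker table over samples, parameters and phase planes
#'
#' Runs the full reconstruction chain per sample (synthesis, demodulation,
#' piston removal, phase sectioning, theziogram maps, moments) and collects
#' one record per (sample, parameter, phase plane) in long format — the shape
#' the diagnostic stage consumes.
#'
#' @param samples A cohort tibble from [make_cohort()] (with rendered
#'   `sample` column), or a list of `phantom_sample` objects.
#' @param phase_planes Numeric vector of phase planes `phi_k`; `Inf` denotes
#'   the integral (unsectioned) field. Default `c(Inf, pi/2, pi/4, pi/8)`.
#' @param parameters Which of `"LB"`, `"CB"`, `"LD"`, `"CD"` to keep.
#' @param method,functional Inversion method and phase functional, passed
#'   through.
#' @param carrier,window_halfwidth,bit_depth Recording settings passed to
#'   [synthesize()]/[demodulate()].
#' @param z2_is_variance,raw_kurtosis Moment conventions, see
#'   [central_moments()].
#' @return A tibble with columns `sample_id`, `group`, `parameter`,
#'   `phase_plane` (`Inf` = integral), `z1`..`z4`, `k`; rows ordered by
#'   sample, then parameter, then descending phase plane.
#' @export
marker_table <- function(samples,
                         phase_planes = c(Inf, pi/2, pi/4, pi/8),
                         parameters = c("LB", "CB", "LD", "CD"),
                         method = c("exact", "analytic"),
                         functional = "path",
                         carrier = c(0.27, 0.27),
                         window_halfwidth = 0.18,
                         bit_depth = 16,
                         z2_is_variance = FALSE,
                         raw_kurtosis = FALSE) {
  method <- match.arg(method)
  parameters <- match.arg(parameters, several.ok = TRUE)
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample_id", "group", "sample") %in% names(samples)))
    ids <- samples$sample_id; groups <- samples$group; objs <- samples$sample
  } else {
    objs <- samples
    ids <- sprintf("s_%02d", seq_along(objs))
    groups <- rep(NA_character_, length(objs))
  }
  rows <- vector("list", length(objs))
  for (i in seq_along(objs)) {
    rec <- rephase(demodulate(synthesize(objs[[i]]$field, carrier = carrier,
                                         bit_depth = bit_depth),
                              window_halfwidth = window_halfwidth))
    per_plane <- lapply(phase_planes, function(pk) {
      fld <- if (is.infinite(pk)) layered_field(rec, NULL)
             else layered_field(rec, phase_section(pk), functional = functional)
      maps <- theziogram_maps(fld, method = method)
      dplyr::bind_rows(lapply(maps[parameters], central_moments,
                              z2_is_variance = z2_is_variance,
                              raw_kurtosis = raw_kurtosis))
    })
    tab <- dplyr::bind_rows(per_plane)
    tab$sample_id <- ids[i]
    tab$group <- groups[i]
    rows[[i]] <- tab
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("sample_id", "group", "parameter", "phase_plane",
                 "z1", "z2", "z3", "z4", "k")]
  dplyr::arrange(out, .data$sample_id, .data$parameter,
                 dplyr::desc(.data$phase_plane))
}

#' Write / read a marker table as CSV
#'
#' Plain-text round trip with a fixed significant-digit representation (17
#' digits, enough to restore doubles bit-identically).
#'
#' @param markers Marker tibble from [marker_table()].
#' @param path File path.
#' @return `write_marker_csv` returns `path` invisibly; `read_marker_csv`
#'   returns the tibble.
#' @export
write_marker_csv <- function(markers, path) {
  need <- c("sample_id", "group", "parameter", "phase_plane",
            "z1", "z2", "z3", "z4", "k")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    .stop_jtez(paste("marker table missing column(s):", paste(miss, collapse = ", ")),
               "jtez_schema_error")
  }
  df <- as.data.frame(markers[need])
  for (cc in c("phase_plane", "z1", "z2", "z3", "z4")) {
    df[[cc]] <- sprintf("%.17g", df[[cc]])
  }
  tmp <- paste0(path, ".tmp")
  write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "parameter", "phase_plane",
            "z1", "z2", "z3", "z4", "k")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    .stop_jtez(paste("marker CSV missing column(s):", paste(miss, collapse = ", ")),
               "jtez_schema_error")
  }
  for (cc in c("phase_plane", "z1", "z2", "z3", "z4")) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  tibble::as_tibble(df)
}
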