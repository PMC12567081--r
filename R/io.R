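# Plain I/O: TIFF images for interferograms and maps, YAML run configs,
# JSON reports. All writes go through a temp file + rename so readers never
# see a partial file.

.atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read a real-valued map as 32-bit float TIFF
#'
#' TIFF stores samples in `[0, 1]`, so the map is affinely normalized to that
#' range and the original `(min, max)` recorded in a plain-text `.range`
#' sidecar next to the image; reading restores the original values (to 32-bit
#' float precision).
#'
#' @param map Numeric matrix.
#' @param path Output path.
#' @return `write_map_tiff` returns `path` invisibly; `read_map_tiff` the
#'   matrix.
#' @export
write_map_tiff <- function(map, path) {
  if (!is.matrix(map) || !is.numeric(map)) {
    .stop_jtez("map must be a numeric matrix", "jtez_format_error")
  }
  lo <- min(map); hi <- max(map)
  norm <- if (hi > lo) (map - lo)/(hi - lo) else map*0
  .atomic_write(path, function(tmp) {
    tiff::writeTIFF(norm, tmp, bits.per.sample = 32L, reduce = FALSE)
  })
  .atomic_write(paste0(path, ".range"), function(tmp) {
    writeLines(sprintf("%.17g %.17g", lo, hi), tmp)
  })
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  if (!file.exists(path)) {
    .stop_jtez(paste("no such file:", path), "jtez_format_error")
  }
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) != 2L) {
    .stop_jtez(paste(path, "is not a single-channel image"), "jtez_format_error")
  }
  img <- .as_plain_matrix(img)
  range_path <- paste0(path, ".range")
  if (file.exists(range_path)) {
    rg <- as.numeric(strsplit(trimws(readLines(range_path)[1]), "\\s+")[[1]])
    img <- rg[1] + img*(rg[2] - rg[1])
  }
  img
}

.as_plain_matrix <- function(m) {
  out <- as.vector(m)
  dim(out) <- dim(m)
  out
}

#' Write / read an interferogram set as 16-bit grayscale TIFF files
#'
#' One file per channel, named `<prefix>_s{0|90}_A{0|90}.tif`, plus a YAML
#' sidecar `<prefix>_meta.yaml` holding carrier, reference amplitude, gain
#' and bit depth. Only 16-bit sets can be written in this format.
#'
#' @param igs An [interferogram_set()].
#' @param prefix Path prefix for the four files.
#' @return `write_interferograms` returns the sidecar path invisibly;
#'   `read_interferograms` the reconstructed [interferogram_set()].
#' @export
write_interferograms <- function(igs, prefix) {
  stopifnot(inherits(igs, "interferogram_set"))
  bits <- if (identical(igs$bit_depth, "float")) NA_integer_ else as.integer(igs$bit_depth)
  if (!identical(bits, 16L)) {
    .stop_jtez("only 16-bit interferogram sets are written as TIFF", "jtez_format_error")
  }
  files <- c(s0_A0 = "_s0_A0.tif", s0_A90 = "_s0_A90.tif",
             s90_A0 = "_s90_A0.tif", s90_A90 = "_s90_A90.tif")
  for (ch in names(files)) {
    img <- igs$images[[ch]]/65535           # writeTIFF expects [0, 1]
    .atomic_write(paste0(prefix, files[[ch]]), function(tmp) {
      tiff::writeTIFF(img, tmp, bits.per.sample = 16L, reduce = FALSE)
    })
  }
  meta <- list(carrier = as.numeric(igs$carrier),
               reference_amplitude = igs$reference_amplitude,
               gain = igs$gain, bit_depth = 16L,
               wavelength = igs$wavelength)
  .atomic_write(paste0(prefix, "_meta.yaml"), function(tmp) {
    yaml::write_yaml(meta, tmp, precision = 15)
  })
}

#' @rdname write_interferograms
#' @export
read_interferograms <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.yaml")
  if (!file.exists(meta_path)) {
    .stop_jtez(paste("missing metadata sidecar:", meta_path), "jtez_format_error")
  }
  meta <- yaml::read_yaml(meta_path)
  files <- c(s0_A0 = "_s0_A0.tif", s0_A90 = "_s0_A90.tif",
             s90_A0 = "_s90_A0.tif", s90_A90 = "_s90_A90.tif")
  images <- lapply(names(files), function(ch) {
    p <- paste0(prefix, files[[ch]])
    if (!file.exists(p)) .stop_jtez(paste("missing channel file:", p), "jtez_format_error")
    raw <- tiff::readTIFF(p, as.is = TRUE, info = TRUE)
    if (length(dim(raw)) != 2L) {
      .stop_jtez(paste(p, "is not single-channel grayscale"), "jtez_format_error")
    }
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && !identical(as.integer(bits), 16L)) {
      .stop_jtez(paste(p, "is not 16-bit as required"), "jtez_format_error")
    }
    .as_plain_matrix(raw)
  })
  names(images) <- names(files)
  interferogram_set(images, carrier = unlist(meta$carrier),
                    reference_amplitude = meta$reference_amplitude,
                    bit_depth = 16L, gain = meta$gain,
                    wavelength = meta$wavelength)
}

#' Write a theziogram as float TIFF with a JSON sidecar
#'
#' The value map goes to `<prefix>.tif` (32-bit float), the mask to
#' `<prefix>_mask.tif`, and parameter, phase plane, pixel count and dropped
#' fraction to `<prefix>.json`.
#'
#' @param x A `theziogram`.
#' @param prefix Path prefix.
#' @return The JSON sidecar path, invisibly.
#' @export
write_theziogram <- function(x, prefix) {
  stopifnot(inherits(x, "theziogram"))
  write_map_tiff(x$values, paste0(prefix, ".tif"))
  write_map_tiff(x$mask + 0, paste0(prefix, "_mask.tif"))
  meta <- list(parameter = x$parameter,
               phase_plane = if (identical(x$phase_plane, "integral")) "integral"
                             else as.numeric(x$phase_plane),
               k = sum(x$mask),
               dropped_fraction = x$dropped_fraction,
               method = x$method)
  .atomic_write(paste0(prefix, ".json"), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA)
  })
}

#' Load / save a run configuration
#'
#' Run configurations are YAML files mirroring the arguments of
#' [run_pipeline()]. Saving and re-loading a config reproduces it exactly.
#'
#' @param path YAML file path.
#' @param config Named list of settings.
#' @return `read_run_config` returns the config list; `write_run_config` the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    .stop_jtez(paste("no such config file:", path), "jtez_format_error")
  }
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  .atomic_write(path, function(tmp) yaml::write_yaml(config, tmp, precision = 15))
}
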