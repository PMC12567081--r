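# Synthetic facies phantom: seeded per-pixel anisotropy fields emulating the
# zonal structure of a dried biological-fluid film. Needle-shaped crystals of
# the marginal (albumin-like) zone carry linear birefringence/dichroism with
# orientation-disordered optical axes; spherulite domains of the central zone
# carry circular birefringence/dichroism. Each structure also deposits an
# isotropic path phase proportional to its material thickness, which is what
# the layer-by-layer phase scan gates on.

#' Specification of one synthetic facies phantom
#'
#' Collects every tunable of the generator. Structure counts default to fixed
#' densities per pixel so that phantoms rendered on different grids are
#' statistically comparable; geometric scales (needle length, skirt width,
#' disc radius) are in pixels. Each rasterized structure has a flat core and a
#' Gaussian skirt of scale `skirt_sigma`, which keeps the object spectrum
#' compact enough for off-axis holographic recording (see the methods
#' vignette).
#'
#' @param grid Integer vector `c(rows, cols)`; default `c(1120, 960)`, the
#'   camera format; tests and examples use `c(128, 128)`.
#' @param zones Three increasing radius fractions splitting the drop into
#'   central / transitional / edge zones. Needles populate the annulus outside
#'   `zones[1]`; spherulites the disc inside `zones[2]`.
#' @param n_needles,n_discs Structure counts per layer; `NULL` means the
#'   default density (needles: 5, discs: 8 per 128^2 pixels; `disc_density`
#'   scales the latter).
#' @param needle_length Length range (pixels).
#' @param needle_core Flat half-width of a needle (pixels).
#' @param skirt_sigma Gaussian skirt scale shared by needles and discs
#'   (pixels).
#' @param gamma_range Orientation range `c(min, max)` of needle optical axes,
#'   radians in `[0, 2*pi)`.
#' @param gamma_kappa Optional concentration parameter; when given, needle
#'   orientations are drawn from a wrapped normal with standard deviation
#'   `1/sqrt(gamma_kappa)` about the centre of `gamma_range` instead of
#'   uniformly.
#' @param delta_meanlog,delta_sdlog Log-normal law of needle retardance
#'   (radians); draws are capped at `delta_cap`.
#' @param delta_cap Upper cap on needle retardance.
#' @param dichroism_fraction Linear dichroism as a fraction of linear
#'   birefringence.
#' @param disc_core Disc flat-core radius range (pixels).
#' @param cb_meanlog,cb_sdlog Log-normal law of spherulite circular
#'   birefringence amplitude; capped at `4*exp(cb_meanlog)`.
#' @param cd_fraction Circular dichroism as a fraction of circular
#'   birefringence.
#' @param disc_density Multiplier on the default disc density.
#' @param thickness_range Uniform range of the per-structure isotropic path
#'   phase (radians per unit coverage).
#' @param disc_phase_coupling Additional path phase per unit of disc circular
#'   birefringence (thicker spherulites rotate more and retard more).
#' @param n_layers Number of stacked layers (`>= 1`).
#' @param seed Integer seed; every per-layer draw derives from it
#'   deterministically.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(1120, 960),
                         zones = c(0.4, 0.7, 1.0),
                         n_needles = NULL,
                         n_discs = NULL,
                         needle_length = c(12, 26),
                         needle_core = 2,
                         skirt_sigma = 4.5,
                         gamma_range = c(0, 2*pi),
                         gamma_kappa = NULL,
                         delta_meanlog = log(0.3),
                         delta_sdlog = 0.45,
                         delta_cap = 1.5,
                         dichroism_fraction = 0.25,
                         disc_core = c(2.5, 4.5),
                         cb_meanlog = log(0.13),
                         cb_sdlog = 0.4,
                         cd_fraction = 0.25,
                         disc_density = 1,
                         thickness_range = c(0.05, 1.15),
                         disc_phase_coupling = 0.8,
                         n_layers = 3,
                         seed = 1) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 8L)) {
    .stop_jtez("grid must be two integers >= 8", "jtez_shape_error")
  }
  if (length(zones) != 3L || any(diff(zones) <= 0) || zones[1] <= 0 || zones[3] > 1) {
    .stop_jtez("zones must be three strictly increasing fractions in (0, 1]",
               "jtez_invalid_argument")
  }
  if (gamma_range[1] >= gamma_range[2]) {
    .stop_jtez("gamma_range must satisfy min < max", "jtez_invalid_argument")
  }
  if (n_layers < 1) .stop_jtez("n_layers must be >= 1", "jtez_invalid_argument")
  area <- prod(grid)
  if (is.null(n_needles)) n_needles <- max(0L, round(5 * area / 128^2))
  if (is.null(n_discs)) n_discs <- max(0L, round(8 * disc_density * area / 128^2))
  spec <- list(
    grid = grid, zones = zones,
    n_needles = as.integer(n_needles), n_discs = as.integer(n_discs),
    needle_length = needle_length, needle_core = needle_core,
    skirt_sigma = skirt_sigma,
    gamma_range = gamma_range, gamma_kappa = gamma_kappa,
    delta_meanlog = delta_meanlog, delta_sdlog = delta_sdlog,
    delta_cap = delta_cap,
    dichroism_fraction = dichroism_fraction,
    disc_core = disc_core,
    cb_meanlog = cb_meanlog, cb_sdlog = cb_sdlog,
    cd_fraction = cd_fraction,
    thickness_range = thickness_range,
    disc_phase_coupling = disc_phase_coupling,
    n_layers = as.integer(n_layers),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px, %d layer(s), %d needles + %d discs per layer, seed %d\n",
              x$grid[1], x$grid[2], x$n_layers, x$n_needles, x$n_discs, x$seed))
  invisible(x)
}

# deterministic per-(seed, layer) stream seed, kept below 2^31
.layer_seed <- function(seed, layer_index) {
  as.integer((abs(as.numeric(seed)) * 131 + layer_index * 7919) %% 2147483647)
}

.draw_gamma <- function(n, spec) {
  if (is.null(spec$gamma_kappa)) {
    runif(n, spec$gamma_range[1], spec$gamma_range[2])
  } else {
    mid <- mean(spec$gamma_range)
    (rnorm(n, mid, 1/sqrt(spec$gamma_kappa))) %% (2*pi)
  }
}

#' Render one phantom layer as per-pixel anisotropy maps
#'
#' Rasterizes the needles and spherulite discs of one layer into seven maps:
#' the six anisotropy parameters plus the isotropic path phase `iso`. A needle
#' with axis angle `gamma` and retardance `delta` contributes
#' `delta*cos(2*gamma)` to `lb_0_90` and `delta*sin(2*gamma)` to `lb_45_135`
#' (standard retarder decomposition), scaled by its coverage profile;
#' dichroism maps are a fixed fraction of the birefringence maps.
#' Overlapping structures add their parameters (thin-element approximation).
#' Rendering is bit-reproducible for a fixed `(seed, layer_index)`.
#'
#' @param spec A [phantom_spec()].
#' @param layer_index Which layer to render (1-based; must not exceed
#'   `spec$n_layers`).
#' @param seed Optional override of `spec$seed`.
#' @return A list of class `aniso_field`: matrices `lb_0_90`, `lb_45_135`,
#'   `cb`, `ld_0_90`, `ld_45_135`, `cd`, `iso`.
#' @export
render_layer <- function(spec, layer_index = 1, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (layer_index < 1 || layer_index > spec$n_layers) {
    .stop_jtez("layer_index must be in 1..n_layers", "jtez_invalid_argument")
  }
  if (is.null(seed)) seed <- spec$seed
  set.seed(.layer_seed(seed, layer_index))
  A <- spec$grid[1]; B <- spec$grid[2]
  nm <- c("lb_0_90", "lb_45_135", "cb", "ld_0_90", "ld_45_135", "cd", "iso")
  maps <- setNames(lapply(nm, function(i) matrix(0, A, B)), nm)
  cx <- (A + 1)/2; cy <- (B + 1)/2
  rmax <- min(A, B)/2
  sk <- spec$skirt_sigma

  # needles: edge + transitional annulus
  if (spec$n_needles > 0) {
    for (i in seq_len(spec$n_needles)) {
      rf <- sqrt(runif(1, spec$zones[1]^2, spec$zones[3]^2))
      th <- runif(1, 0, 2*pi)
      x0 <- cx + rf*rmax*cos(th); y0 <- cy + rf*rmax*sin(th)
      g <- .draw_gamma(1, spec)
      L <- runif(1, spec$needle_length[1], spec$needle_length[2])
      d <- min(rlnorm(1, spec$delta_meanlog, spec$delta_sdlog), spec$delta_cap)
      tt <- runif(1, spec$thickness_range[1], spec$thickness_range[2])
      ux <- cos(g); uy <- sin(g)
      ext <- L/2 + spec$needle_core + 4*sk
      xs <- max(1, floor(x0 - ext)); xe <- min(A, ceiling(x0 + ext))
      ys <- max(1, floor(y0 - ext)); ye <- min(B, ceiling(y0 + ext))
      if (xs > xe || ys > ye) next
      ii <- xs:xe; jj <- ys:ye
      px <- outer(ii - x0, rep(1, length(jj)))
      py <- outer(rep(1, length(ii)), jj - y0)
      t <- pmin(pmax(px*ux + py*uy, -L/2), L/2)
      dist <- sqrt((px - t*ux)^2 + (py - t*uy)^2)
      cov <- ifelse(dist <= spec$needle_core, 1,
                    exp(-(dist - spec$needle_core)^2/(2*sk^2)))
      maps$lb_0_90[ii, jj] <- maps$lb_0_90[ii, jj] + d*cos(2*g)*cov
      maps$lb_45_135[ii, jj] <- maps$lb_45_135[ii, jj] + d*sin(2*g)*cov
      maps$iso[ii, jj] <- maps$iso[ii, jj] + tt*cov
    }
    maps$ld_0_90 <- spec$dichroism_fraction*maps$lb_0_90
    maps$ld_45_135 <- spec$dichroism_fraction*maps$lb_45_135
  }

  # spherulites: central + transitional disc
  if (spec$n_discs > 0) {
    for (i in seq_len(spec$n_discs)) {
      rf <- sqrt(runif(1, 0, spec$zones[2]^2))
      th <- runif(1, 0, 2*pi)
      x0 <- cx + rf*rmax*cos(th); y0 <- cy + rf*rmax*sin(th)
      r <- runif(1, spec$disc_core[1], spec$disc_core[2])
      amp <- min(rlnorm(1, spec$cb_meanlog, spec$cb_sdlog), 4*exp(spec$cb_meanlog))
      tt <- runif(1, spec$thickness_range[1], spec$thickness_range[2])
      ext <- r + 4*sk
      xs <- max(1, floor(x0 - ext)); xe <- min(A, ceiling(x0 + ext))
      ys <- max(1, floor(y0 - ext)); ye <- min(B, ceiling(y0 + ext))
      ii <- xs:xe; jj <- ys:ye
      dist <- sqrt(outer((ii - x0)^2, (jj - y0)^2, `+`))
      cov <- ifelse(dist <= r, 1, exp(-(dist - r)^2/(2*sk^2)))
      maps$cb[ii, jj] <- maps$cb[ii, jj] + amp*cov
      maps$iso[ii, jj] <- maps$iso[ii, jj] +
        (spec$disc_phase_coupling*amp + tt)*cov
    }
    maps$cd <- spec$cd_fraction*maps$cb
  }

  class(maps) <- "aniso_field"
  maps
}

#' @export
print.aniso_field <- function(x, ...) {
  cat(sprintf("<aniso_field> %d x %d px, max |lb| = %.3f, max |cb| = %.3f\n",
              nrow(x$lb_0_90), ncol(x$lb_0_90),
              max(sqrt(x$lb_0_90^2 + x$lb_45_135^2)), max(abs(x$cb))))
  invisible(x)
}

#' Convert an anisotropy field to a tibble of states
#'
#' @param x An `aniso_field` from [render_layer()].
#' @param ... Unused.
#' @return A tibble with pixel indices, the six anisotropy columns and `iso`.
#' @export
as_tibble.aniso_field <- function(x, ...) {
  d <- dim(x$lb_0_90)
  tibble::tibble(
    a = rep(seq_len(d[1]), times = d[2]),
    b = rep(seq_len(d[2]), each = d[1]),
    lb_0_90 = as.vector(x$lb_0_90), lb_45_135 = as.vector(x$lb_45_135),
    cb = as.vector(x$cb),
    ld_0_90 = as.vector(x$ld_0_90), ld_45_135 = as.vector(x$ld_45_135),
    cd = as.vector(x$cd), iso = as.vector(x$iso)
  )
}

# forward Jones field of one aniso_field layer (includes the isotropic phase)
.layer_jones <- function(layer) {
  b090 <- complex(real = as.vector(layer$lb_0_90), imaginary = -as.vector(layer$ld_0_90))
  b45 <- complex(real = as.vector(layer$lb_45_135), imaginary = -as.vector(layer$ld_45_135))
  a <- complex(real = as.vector(layer$cb), imaginary = -as.vector(layer$cd))
  w <- .jones_forward_core(b090, b45, a)
  d <- dim(layer$lb_0_90)
  ph <- exp(1i*as.vector(layer$iso))
  jones_field(
    matrix(w$w11*ph, d[1], d[2]), matrix(w$w12*ph, d[1], d[2]),
    matrix(w$w21*ph, d[1], d[2]), matrix(w$w22*ph, d[1], d[2])
  )
}

#' Render the full multi-layer Jones field of a phantom
#'
#' Renders every layer of the spec, converts each to its Jones field (the
#' anisotropy matrix times the layer's isotropic phase factor) and composes
#' them with [stack_product()]. The per-layer ground-truth parameter maps are
#' retained for recovery tests.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A list of class `phantom_sample` with elements `field` (the
#'   composed `jones_field`), `layers` (list of ground-truth `aniso_field`s)
#'   and `spec`.
#' @export
render_jones_field <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  layers <- lapply(seq_len(spec$n_layers), function(l) render_layer(spec, l, seed = seed))
  field <- stack_product(lapply(layers, .layer_jones))
  structure(list(field = field, layers = layers, spec = spec, seed = seed),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> seed %d, %d layer(s), %d x %d px\n",
              x$seed, length(x$layers), dim(x$field)[1], dim(x$field)[2]))
  invisible(x)
}

#' Specification of a two-group synthetic cohort
#'
#' Pairs a healthy-like phantom spec with a pathology-like variant. The
#' default pathology deltas follow the qualitative disease picture for
#' facies of thyroid-cancer patients: the needle orientation range narrows
#' (increased crystallization order) and the spherulite circular anisotropy
#' rises in amplitude and concentration (more globulin and formed elements).
#'
#' @param n_per_group Samples per group (default 26).
#' @param healthy A [phantom_spec()] for the control group.
#' @param pathology A [phantom_spec()] for the disease group; the default
#'   narrows `gamma_range` to `c(0, pi/3)`, raises `cb_meanlog` to
#'   `log(0.32)` and multiplies the disc density by 1.5.
#' @param seed Cohort seed; per-sample seeds derive from it deterministically.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 26,
                        healthy = phantom_spec(grid = c(128, 128)),
                        pathology = NULL,
                        seed = 1) {
  if (n_per_group < 2) .stop_jtez("n_per_group must be >= 2", "jtez_invalid_argument")
  stopifnot(inherits(healthy, "phantom_spec"))
  if (is.null(pathology)) {
    pathology <- healthy
    pathology$gamma_range <- c(0, pi/3)
    pathology$cb_meanlog <- log(0.32)
    pathology$n_discs <- as.integer(round(1.5 * healthy$n_discs))
  }
  stopifnot(inherits(pathology, "phantom_spec"))
  if (pathology$gamma_range[1] < healthy$gamma_range[1] ||
      pathology$gamma_range[2] > healthy$gamma_range[2]) {
    .stop_jtez("pathology orientation range must lie within the healthy range",
               "jtez_invalid_argument")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 healthy = healthy, pathology = pathology,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# deterministic per-sample seed from (cohort seed, group index, sample index)
.sample_seed <- function(seed, group, i) {
  as.integer((abs(as.numeric(seed)) * 69621 + group * 1000003 + i * 30011) %% 2147483647)
}

#' Generate a two-group cohort of phantom samples
#'
#' @param cohort A [cohort_spec()].
#' @param render If `TRUE` (default) the Jones field and ground truth of every
#'   sample are rendered eagerly into the `sample` list-column; with `FALSE`
#'   only group labels and per-sample seeds are returned, and samples can be
#'   rendered on demand with [render_jones_field()].
#' @return A tibble with columns `group` (`"healthy"`/`"pathology"`),
#'   `sample_id`, `seed` and (if `render`) a list-column `sample` of
#'   `phantom_sample` objects.
#' @export
make_cohort <- function(cohort, render = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  grid <- expand.grid(i = seq_len(cohort$n_per_group), g = 1:2)
  out <- tibble::tibble(
    group = c("healthy", "pathology")[grid$g],
    sample_id = sprintf("%s_%02d", c("h", "p")[grid$g], grid$i),
    seed = mapply(function(g, i) .sample_seed(cohort$seed, g, i), grid$g, grid$i)
  )
  if (render) {
    specs <- list(cohort$healthy, cohort$pathology)
    out$sample <- mapply(function(g, s) render_jones_field(specs[[g]], seed = s),
                         grid$g, out$seed, SIMPLIFY = FALSE)
  }
  out
}
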