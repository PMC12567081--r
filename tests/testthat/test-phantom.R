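# Synthetic facies phantom: rasterization, determinism, cohort statistics.

test_that("empty spec renders an all-zero field and identity Jones field", {
  spec <- test_spec(grid = c(64, 64), n_needles = 0, n_discs = 0)
  layer <- render_layer(spec)
  for (nm in c("lb_0_90", "lb_45_135", "cb", "ld_0_90", "ld_45_135", "cd", "iso")) {
    expect_equal(max(abs(layer[[nm]])), 0)
  }
  ph <- render_jones_field(phantom_spec(grid = c(64, 64), n_needles = 0,
                                        n_discs = 0, n_layers = 1))
  expect_lt(max(Mod(ph$field$w11 - 1)), 1e-14)
  expect_lt(max(Mod(ph$field$w12)), 1e-14)
})

test_that("a horizontal needle puts its retardance into the 0-90 channel", {
  # gamma fixed at 0 via a degenerate orientation range
  spec <- phantom_spec(grid = c(64, 64), n_needles = 1, n_discs = 0,
                       gamma_range = c(0, 1e-9),
                       delta_meanlog = log(0.4), delta_sdlog = 0,
                       needle_length = c(20, 20), seed = 8)
  layer <- render_layer(spec)
  core <- abs(layer$lb_0_90 - 0.4) < 1e-6
  expect_gt(sum(core), 10)                      # flat core pixels hit exactly delta
  expect_lt(max(abs(layer$lb_45_135)), 1e-6)    # sin(2*gamma) = 0
  expect_equal(layer$ld_0_90, 0.25*layer$lb_0_90, tolerance = 1e-12)
})

test_that("rendering is bit-reproducible and layers differ", {
  spec <- test_spec(grid = c(64, 64), seed = 21)
  a <- render_layer(spec, 1)
  b <- render_layer(spec, 1)
  expect_identical(a, b)
  c2 <- render_layer(spec, 2)
  expect_gt(max(abs(a$lb_0_90 - c2$lb_0_90)), 1e-6)
  ph1 <- render_jones_field(spec)
  ph2 <- render_jones_field(spec)
  expect_identical(ph1$field$w11, ph2$field$w11)
})

test_that("fields stay finite and respect the overlap amplitude bound", {
  spec <- test_spec(grid = c(96, 96), seed = 4)
  ph <- render_jones_field(spec)
  for (k in c("w11", "w12", "w21", "w22")) {
    expect_true(all(is.finite(Re(ph$field[[k]]))))
  }
  lb <- sqrt(ph$layers[[1]]$lb_0_90^2 + ph$layers[[1]]$lb_45_135^2)
  expect_lt(max(lb), spec$n_needles * spec$delta_cap)
})

test_that("single-layer ground truth round-trips through the exact inversion", {
  spec <- phantom_spec(grid = c(64, 64), n_layers = 1, seed = 13)
  ph <- render_jones_field(spec)
  u <- unimodular_reduce(ph$field)
  inv <- jones_invert(
    tibble::tibble(w11 = as.vector(u$w11), w12 = as.vector(u$w12),
                   w21 = as.vector(u$w21), w22 = as.vector(u$w22)),
    method = "matrix_log")
  truth <- ph$layers[[1]]
  expect_lt(max(abs(inv$lb_0_90 - as.vector(truth$lb_0_90))), 1e-8)
  expect_lt(max(abs(inv$cb - as.vector(truth$cb))), 1e-8)
  expect_lt(max(abs(inv$cd - as.vector(truth$cd))), 1e-8)
})

test_that("stacked pure-rotation layers compose to one rotation", {
  # three identical spherulite-only layers act as a single rotation by 3x
  spec <- phantom_spec(grid = c(48, 48), n_needles = 0, n_discs = 1,
                       disc_core = c(6, 6), cb_meanlog = log(0.2), cb_sdlog = 0,
                       cd_fraction = 0, thickness_range = c(1e-9, 2e-9),
                       disc_phase_coupling = 0, n_layers = 3, seed = 2)
  one <- render_layer(spec, 1)
  same <- list(one, one, one)
  triple <- stack_product(lapply(same, jtez:::.layer_jones))
  tripled <- one
  tripled$cb <- 3*one$cb
  tripled$cd <- 3*one$cd
  tripled$iso <- 3*one$iso
  ref <- jtez:::.layer_jones(tripled)
  for (k in c("w11", "w12", "w21", "w22")) {
    expect_lt(max(Mod(triple[[k]] - ref[[k]])), 1e-10)
  }
})

test_that("cohort generation is deterministic with distinct per-sample seeds", {
  co <- cohort_spec(n_per_group = 2, healthy = test_spec(grid = c(48, 48)), seed = 9)
  tab <- make_cohort(co, render = FALSE)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$group == "healthy"), 2)
  expect_equal(length(unique(tab$seed)), 4)
  tab2 <- make_cohort(co, render = FALSE)
  expect_identical(tab$seed, tab2$seed)
})

test_that("needle orientation statistics follow their stated laws", {
  # uniform orientations on [0, 2*pi): tiny resultant at >= 500 needles
  set.seed(77)
  spec_u <- phantom_spec(grid = c(256, 256), n_needles = 600, n_discs = 0, seed = 5)
  set.seed(jtez:::.layer_seed(spec_u$seed, 1))
  g_u <- jtez:::.draw_gamma(600, spec_u)
  expect_lt(resultant_length(g_u), 0.1)
  # narrowed pathology-like range concentrates them
  spec_n <- phantom_spec(grid = c(256, 256), n_needles = 600, n_discs = 0,
                         gamma_range = c(0, pi/4), seed = 5)
  set.seed(jtez:::.layer_seed(spec_n$seed, 1))
  g_n <- jtez:::.draw_gamma(600, spec_n)
  expect_gt(resultant_length(g_n), 0.8)
})

test_that("pathology cohort narrows orientation and raises circular anisotropy", {
  co <- cohort_spec(n_per_group = 2, healthy = test_spec(grid = c(48, 48)))
  expect_lt(diff(co$pathology$gamma_range), diff(co$healthy$gamma_range))
  expect_gt(co$pathology$cb_meanlog, co$healthy$cb_meanlog)
  expect_gt(co$pathology$n_discs, co$healthy$n_discs)
  # invalid: pathology range outside healthy range
  bad <- test_spec(grid = c(48, 48), gamma_range = c(0, 3*pi))
  expect_error(
    cohort_spec(healthy = test_spec(grid = c(48, 48), gamma_range = c(0, pi)),
                pathology = bad),
    class = "jtez_invalid_argument")
})
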