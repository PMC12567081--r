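# The anisotropy algebra: vector modulus, forward Jones matrix, inversions.

test_that("q_modulus reduces to known values", {
  expect_equal(q_modulus(anisotropy_state()), 0)
  expect_equal(q_modulus(anisotropy_state(lb_0_90 = 0.6)), 0.6)
  expect_equal(q_modulus(anisotropy_state(lb_0_90 = 0.3, lb_45_135 = 0.4)), 0.5)
  s <- random_states(200, seed = 3)
  brute <- sqrt(s$lb_0_90^2 + s$lb_45_135^2 + s$cb^2 +
                  s$ld_0_90^2 + s$ld_45_135^2 + s$cd^2)
  expect_equal(q_modulus(s), brute, tolerance = 1e-14)
})

test_that("q_modulus vanishes only for the zero state and rejects bad input", {
  expect_gt(q_modulus(anisotropy_state(cd = 1e-8)), 0)
  expect_error(q_modulus(anisotropy_state(lb_0_90 = NA)), class = "jtez_invalid_argument")
  expect_error(q_modulus(data.frame(x = 1)), class = "jtez_invalid_argument")
})

test_that("generalized vector is real for phase-only states, principal branch", {
  s <- random_states(100, seed = 11)
  s$ld_0_90 <- s$ld_45_135 <- s$cd <- 0
  gv <- generalized_vector(s)
  expect_true(all(abs(Im(gv$q_complex)) < 1e-12))
  expect_equal(Re(gv$q_complex), gv$q_abs, tolerance = 1e-12)
  gv2 <- generalized_vector(random_states(100, seed = 12))
  expect_true(all(Re(gv2$q_complex) >= 0))
})

test_that("jones_forward matches its defining special cases", {
  I2 <- jones_forward(anisotropy_state())
  expect_equal(c(I2$w11, I2$w22), c(1 + 0i, 1 + 0i))
  expect_equal(c(I2$w12, I2$w21), c(0i, 0i))
  # pure optical activity is a rotation by cb/2
  th <- 0.8
  W <- jones_forward(anisotropy_state(cb = th))
  expect_equal(W$w11, complex(real = cos(th/2)), tolerance = 1e-12)
  expect_equal(W$w12, complex(real = sin(th/2)), tolerance = 1e-12)
  expect_equal(W$w21, complex(real = -sin(th/2)), tolerance = 1e-12)
  # pure linear retardance along 0-90
  d <- 0.5
  W <- jones_forward(anisotropy_state(lb_0_90 = d))
  expect_equal(W$w11, exp(-1i*d/2), tolerance = 1e-12)
  expect_equal(W$w22, exp(1i*d/2), tolerance = 1e-12)
})

test_that("jones_forward equals the matrix exponential of half the generator", {
  s <- random_states(1000, qmax = 3, seed = 42)
  W <- jones_forward(s)
  for (i in seq(1, 1000, by = 7)) {   # spot-check a systematic subsample
    E <- expm_2x2(0.5*state_generator(s[i, ]))
    expect_lt(max(Mod(c(W$w11[i] - E[1, 1], W$w12[i] - E[1, 2],
                        W$w21[i] - E[2, 1], W$w22[i] - E[2, 2]))), 1e-10)
  }
})

test_that("jones_forward is unimodular always, unitary iff phase-only", {
  s <- random_states(1000, qmax = 5, seed = 7)
  W <- jones_forward(s)
  det <- W$w11*W$w22 - W$w12*W$w21
  expect_lt(max(Mod(det - 1)), 1e-10)
  sp <- s
  sp$ld_0_90 <- sp$ld_45_135 <- sp$cd <- 0
  Wp <- jones_forward(sp)
  # unitarity: W^H W = I
  u11 <- Mod(Wp$w11)^2 + Mod(Wp$w21)^2
  u12 <- Conj(Wp$w11)*Wp$w12 + Conj(Wp$w21)*Wp$w22
  expect_lt(max(abs(u11 - 1)), 1e-10)
  expect_lt(max(Mod(u12)), 1e-10)
  # with dichroism present unitarity must fail
  Wd <- jones_forward(anisotropy_state(ld_0_90 = 0.3))
  expect_gt(abs(Mod(Wd$w11)^2 + Mod(Wd$w21)^2 - 1), 1e-3)
})

test_that("analytic inversion round-trips phase-only states", {
  expect_equal(
    as.numeric(jones_invert(jones_forward(anisotropy_state()))[1, c("q", "lb", "cb", "ld", "cd")]),
    c(0, 0, 0, 0, 0), tolerance = 1e-9)
  s <- random_states(400, qmax = 2*pi - 1e-2, seed = 20)
  s$ld_0_90 <- s$ld_45_135 <- s$cd <- 0
  inv <- jones_invert(jones_forward(s), method = "analytic")
  expect_equal(inv$lb, sqrt(s$lb_0_90^2 + s$lb_45_135^2), tolerance = 1e-8)
  expect_equal(inv$cb, s$cb, tolerance = 1e-8)
  expect_lt(max(abs(inv$ld)), 1e-8)
  expect_lt(max(abs(inv$cd)), 1e-8)
})

test_that("analytic inversion approximates weak-dichroism states within 5%", {
  s <- random_states(200, qmax = 1, seed = 31)
  s <- s[q_modulus(s) > 0.5, ]                      # q_abs of order 1
  scale <- 1/q_modulus(s)
  for (p in names(s)) s[[p]] <- s[[p]]*scale        # q_abs = 1 exactly
  shrink <- 0.05/pmax(abs(s$ld_0_90), abs(s$ld_45_135), abs(s$cd), 0.05)
  s$ld_0_90 <- s$ld_0_90*shrink
  s$ld_45_135 <- s$ld_45_135*shrink
  s$cd <- s$cd*shrink
  W <- jones_forward(s)
  approx <- jones_invert(W, method = "analytic", clip_arccos = TRUE)
  exact <- jones_invert(W, method = "matrix_log")
  # the closed form is first-order accurate in dichroism: birefringence
  # channels come back essentially exact, dichroism channels to ~10%
  for (p in c("lb", "cb")) {
    denom <- pmax(abs(exact[[p]]), 0.05)
    expect_lt(max(abs(approx[[p]] - exact[[p]])/denom), 0.005)
  }
  for (p in c("ld", "cd")) {
    denom <- pmax(abs(exact[[p]]), 0.05)
    expect_lt(max(abs(approx[[p]] - exact[[p]])/denom), 0.10)
  }
})

test_that("matrix-log inversion is an exact inverse below the branch limit", {
  s <- random_states(1000, qmax = 6, seed = 99)
  gv <- generalized_vector(s)
  ok <- Mod(gv$q_complex) < 2*pi - 0.05
  s <- s[ok, ]
  inv <- jones_invert(jones_forward(s), method = "matrix_log")
  for (p in c("lb_0_90", "lb_45_135", "cb", "ld_0_90", "ld_45_135", "cd")) {
    expect_lt(max(abs(inv[[p]] - s[[p]])), 1e-8)
  }
  # pure linear dichroism
  inv2 <- jones_invert(jones_forward(anisotropy_state(ld_0_90 = 0.3)),
                       method = "matrix_log")
  expect_equal(inv2$ld, 0.3, tolerance = 1e-10)
  expect_lt(abs(inv2$lb) + abs(inv2$cb) + abs(inv2$cd), 1e-10)
})

test_that("analytic birefringence error shrinks quadratically as dichroism vanishes", {
  base <- anisotropy_state(lb_0_90 = 0.5, lb_45_135 = 0.4, cb = 0.6)
  err_at <- function(ld) {
    s <- base
    s$ld_0_90 <- ld
    W <- jones_forward(s)
    a <- jones_invert(W, method = "analytic", clip_arccos = TRUE)
    e <- jones_invert(W, method = "matrix_log")
    c(biref = abs(a$lb - e$lb) + abs(a$cb - e$cb),
      dichro = abs(a$ld - e$ld) + abs(a$cd - e$cd))
  }
  e1 <- err_at(0.1); e2 <- err_at(0.05)
  # birefringence channels converge quadratically ...
  expect_gt(e1["biref"]/e2["biref"], 3)
  expect_lt(e1["biref"]/e2["biref"], 5)
  # ... dichroism channels linearly (their relative error is constant)
  expect_gt(e1["dichro"]/e2["dichro"], 1.7)
  expect_lt(e1["dichro"]/e2["dichro"], 2.3)
})

test_that("inversion error signalling and convention switch behave", {
  # strongly dichroic matrix pushes arccos out of domain
  W <- jones_forward(anisotropy_state(ld_0_90 = 1.5))
  expect_error(jones_invert(W, method = "analytic"), class = "jtez_out_of_domain")
  expect_silent(jones_invert(W, method = "analytic", clip_arccos = TRUE))
  # the alternative convention swaps the phase/amplitude channels
  s <- anisotropy_state(lb_0_90 = 0.4, cb = 0.3)
  W <- jones_forward(s)
  flip <- jones_invert(W, method = "analytic", convention = "phase_re")
  expect_equal(flip$ld, 0.4, tolerance = 1e-8)
  expect_equal(flip$cd, 0.3, tolerance = 1e-8)
  # beyond the branch limit the retardance aliases into the principal sheet
  # (the matrices coincide); exactly at 2*pi the inversion is singular
  far <- jones_invert(jones_forward(anisotropy_state(cb = 2*pi + 0.5)),
                      method = "matrix_log")
  expect_equal(far$q, 2*pi - 0.5, tolerance = 1e-9)
  at_branch <- jones_invert(jones_forward(anisotropy_state(cb = 2*pi)),
                            method = "matrix_log", on_singular = "flag")
  expect_true(at_branch$singular[1])
})
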