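# Generalized Jones matrix algebra: forward construction from the six
# anisotropy parameters and the two inverse reconstructions (closed-form
# arccos inversion and the exact principal matrix logarithm).

# sin(q/2)/q with a series fallback below |q| = 1e-6 (avoids 0/0; complex-safe)
.sinc_half <- function(q) {
  small <- abs(q) < 1e-6
  out <- q
  out[small] <- 0.5 - q[small]^2/48
  out[!small] <- sin(q[!small]/2)/q[!small]
  out
}

# q / (2 sin(q/2)), the inverse prefactor, with the matching series fallback
.inv_sinc_half <- function(q) {
  small <- abs(q) < 1e-6
  out <- q
  out[small] <- 1 + q[small]^2/48
  out[!small] <- q[!small]/(2*sin(q[!small]/2))
  out
}

.jones_forward_core <- function(b090, b45, a) {
  qc <- sqrt(b090^2 + b45^2 + a^2 + 0i)
  co <- cos(qc/2)
  s <- .sinc_half(qc)
  list(
    w11 = co - 1i*b090*s,
    w12 = (a - 1i*b45)*s,
    w21 = (-a - 1i*b45)*s,
    w22 = co + 1i*b090*s
  )
}

#' Generalized Jones matrix of an anisotropic layer
#'
#' Builds the 2x2 complex amplitude-transmission matrix of a homogeneous layer
#' with the six-parameter complex anisotropy of [anisotropy_state()]. With the
#' complex generator components `b_0_90`, `b_45_135`, `a_circ` of
#' [generalized_vector()] and `q` their complex modulus, the matrix is
#' `W = cos(q/2) I + sin(q/2)/q * G`, where `G` has `-1i*b_0_90` and
#' `+1i*b_0_90` on the diagonal and `+/-a_circ - 1i*b_45_135` off it. `W`
#' equals the matrix exponential of `G/2` (since `G^2 = -q^2 I`), is always
#' unimodular (`det W = 1`), and is unitary exactly when all dichroisms
#' vanish.
#'
#' @inheritParams q_modulus
#' @return A tibble with complex columns `w11`, `w12`, `w21`, `w22`, one row
#'   per input state.
#' @examples
#' jones_forward(anisotropy_state(cb = pi/2)) # rotation by pi/4
#' @export
jones_forward <- function(states) {
  gv <- generalized_vector(states)
  tibble::as_tibble(.jones_forward_core(gv$b_0_90, gv$b_45_135, gv$a_circ))
}

.check_jones <- function(W) {
  need <- c("w11", "w12", "w21", "w22")
  if (!is.data.frame(W) || !all(need %in% names(W))) {
    .stop_jtez("expected a data frame with columns w11, w12, w21, w22",
               "jtez_invalid_argument")
  }
  invisible(W)
}

# closed-form inversion of a unimodular Jones matrix into the four aggregate
# anisotropy parameters; returns also singular/out-of-domain flags
.invert_analytic_core <- function(w11, w12, w21, w22,
                                  convention = "phase_im", clip_arccos = FALSE) {
  x <- 0.5*(Re(w11) + Re(w22))
  out_of_domain <- abs(x) > 1 + 1e-12
  if (clip_arccos) {
    x <- pmin(pmax(x, -1), 1)
    out_of_domain <- rep(FALSE, length(x))
  }
  xs <- pmin(pmax(x, -1), 1)
  q <- 2*acos(xs)
  singular <- !out_of_domain & (abs(sin(q/2)) < 1e-12) & (q > 1)  # q ~ 2*pi branch
  f <- .inv_sinc_half(q)
  lin_im <- f*sqrt((Im(w22) - Im(w11))^2 + (Im(w12) + Im(w21))^2)
  lin_re <- f*sqrt((Re(w22) - Re(w11))^2 + (Re(w12) + Re(w21))^2)
  circ_re <- f*(Re(w12) - Re(w21))
  circ_im <- f*(Im(w21) - Im(w12))
  if (convention == "phase_im") {
    lb <- lin_im; ld <- lin_re; cb <- circ_re; cd <- circ_im
  } else {
    lb <- lin_re; ld <- lin_im; cb <- circ_im; cd <- circ_re
  }
  list(q = q, lb = lb, cb = cb, ld = ld, cd = cd,
       out_of_domain = out_of_domain, singular = singular)
}

# exact inversion by the principal matrix logarithm of a (unimodular) 2x2
# complex matrix; returns the six components plus the complex retardance
.invert_exact_core <- function(w11, w12, w21, w22) {
  tr2 <- (w11 + w22)/2
  qc <- 2*acos(tr2 + 0i)
  # acos is ill-conditioned near tr2 = +/-1; refine with the analytically
  # equivalent sine form sin^2(q/2) = det(W - tr2 I), which is well behaved
  # there, picking the solution branch nearest the acos estimate
  s2 <- sqrt((w11 - tr2)*(w22 - tr2) - w12*w21 + 0i)
  a2 <- 2*asin(s2)
  cand <- rbind(a2, 2*pi - a2, -a2, 2*pi + a2)
  pick <- apply(Mod(sweep(cand, 2, qc, `-`)), 2, which.min)
  qc <- cand[cbind(pick, seq_along(qc))]
  f <- 2*.inv_sinc_half(qc)   # G = q/sin(q/2) * (W - cos(q/2) I)
  co <- cos(qc/2)
  g11 <- f*(w11 - co)
  g12 <- f*w12
  g21 <- f*w21
  b090 <- 1i*g11
  b45 <- 1i*(g12 + g21)/2
  a <- (g12 - g21)/2
  out_of_range <- Re(qc) >= 2*pi - 1e-9
  list(
    lb_0_90 = Re(b090), ld_0_90 = -Im(b090),
    lb_45_135 = Re(b45), ld_45_135 = -Im(b45),
    cb = Re(a), cd = -Im(a),
    q_complex = qc, out_of_range = out_of_range
  )
}

#' Reconstruct anisotropy parameters from a Jones matrix
#'
#' Two inversions of [jones_forward()] are provided. `method = "analytic"` is
#' the closed-form reconstruction used in theziography: the retardance is
#' `q = 2*acos(0.5*(Re(w11) + Re(w22)))` and the four aggregate parameters
#' follow from real and imaginary parts of the matrix elements with the
#' prefactor `q/(2*sin(q/2))`. It is exact for purely refractive (phase-only)
#' anisotropy and a weak-dichroism approximation otherwise. `method =
#' "matrix_log"` computes the principal matrix logarithm in closed form and is
#' an exact inverse for any state with retardance below `2*pi`; it returns all
#' six basis components in addition to the aggregates.
#'
#' The `convention` switch controls which of the real/imaginary parts are read
#' as birefringence versus dichroism in the analytic method; `"phase_im"`
#' (default) takes the diagonal imaginary parts as linear birefringence,
#' `"phase_re"` swaps the roles of the phase and amplitude channels.
#'
#' @param W Data frame with complex columns `w11`, `w12`, `w21`, `w22`.
#' @param method `"analytic"` or `"matrix_log"`.
#' @param convention `"phase_im"` or `"phase_re"` (analytic method only).
#' @param clip_arccos If `TRUE`, the arccos argument is clipped into
#'   `[-1, 1]` instead of signalling an out-of-domain error (useful when
#'   demodulation noise pushes it slightly outside).
#' @param on_singular `"error"` (default) or `"flag"`: whether singular or
#'   out-of-domain rows abort or are returned flagged with `NA` parameters.
#' @return A tibble with columns `q`, `lb`, `cb`, `ld`, `cd` (plus the six
#'   basis components for `method = "matrix_log"`) and a logical `singular`
#'   column when `on_singular = "flag"`.
#' @examples
#' W <- jones_forward(anisotropy_state(lb_0_90 = 0.4, cb = 0.2))
#' jones_invert(W) # recovers lb = 0.4, cb = 0.2
#' @export
jones_invert <- function(W, method = c("analytic", "matrix_log"),
                         convention = c("phase_im", "phase_re"),
                         clip_arccos = FALSE,
                         on_singular = c("error", "flag")) {
  .check_jones(W)
  method <- match.arg(method)
  convention <- match.arg(convention)
  on_singular <- match.arg(on_singular)
  if (method == "analytic") {
    res <- .invert_analytic_core(W$w11, W$w12, W$w21, W$w22,
                                 convention = convention,
                                 clip_arccos = clip_arccos)
    bad_dom <- res$out_of_domain
    bad_sing <- res$singular
    if (on_singular == "error") {
      if (any(bad_dom)) {
        .stop_jtez("arccos argument outside [-1, 1]; strongly dichroic matrix (set clip_arccos = TRUE to clip)",
                   "jtez_out_of_domain")
      }
      if (any(bad_sing)) {
        .stop_jtez("retardance at the 2*pi branch point (sin(q/2) = 0)",
                   "jtez_singular_branch")
      }
    }
    bad <- bad_dom | bad_sing
    out <- tibble::tibble(q = res$q, lb = res$lb, cb = res$cb,
                          ld = res$ld, cd = res$cd)
    out[bad, ] <- NA_real_
    if (on_singular == "flag") out$singular <- bad
    out
  } else {
    res <- .invert_exact_core(W$w11, W$w12, W$w21, W$w22)
    bad <- res$out_of_range
    if (on_singular == "error" && any(bad)) {
      .stop_jtez("complex retardance at or beyond the 2*pi branch limit",
                 "jtez_out_of_range")
    }
    out <- tibble::tibble(
      q = abs(Re(res$q_complex)),
      lb = sqrt(res$lb_0_90^2 + res$lb_45_135^2),
      cb = res$cb,
      ld = sqrt(res$ld_0_90^2 + res$ld_45_135^2),
      cd = res$cd,
      lb_0_90 = res$lb_0_90, lb_45_135 = res$lb_45_135,
      ld_0_90 = res$ld_0_90, ld_45_135 = res$ld_45_135
    )
    out[bad, ] <- NA_real_
    if (on_singular == "flag") out$singular <- bad
    out
  }
}
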