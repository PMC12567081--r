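#' Construct a table of anisotropy states
#'
#' An anisotropy state collects the six parameters that describe the complex
#' optical anisotropy of one homogeneous domain (or pixel) of a polycrystalline
#' layer: linear birefringence in the 0-90 and 45-135 degree bases, circular
#' birefringence, and the corresponding dichroisms (radian-equivalent
#' attenuation). All arguments are recycled to a common length, so the
#' constructor builds one row per domain.
#'
#' @param lb_0_90,lb_45_135 Linear birefringence in the two linear bases
#'   (radians).
#' @param cb Circular birefringence (optical activity), radians.
#' @param ld_0_90,ld_45_135 Linear dichroism in the two linear bases
#'   (dimensionless, radian-equivalent).
#' @param cd Circular dichroism.
#' @return A tibble with the six columns above, one row per state.
#' @examples
#' anisotropy_state(lb_0_90 = 0.3, lb_45_135 = 0.4)
#' @export
anisotropy_state <- function(lb_0_90 = 0, lb_45_135 = 0, cb = 0,
                             ld_0_90 = 0, ld_45_135 = 0, cd = 0) {
  out <- tibble::tibble(
    lb_0_90 = as.numeric(lb_0_90), lb_45_135 = as.numeric(lb_45_135),
    cb = as.numeric(cb),
    ld_0_90 = as.numeric(ld_0_90), ld_45_135 = as.numeric(ld_45_135),
    cd = as.numeric(cd)
  )
  .check_states(out)
  out
}

.state_cols <- c("lb_0_90", "lb_45_135", "cb", "ld_0_90", "ld_45_135", "cd")

.check_states <- function(states) {
  if (!is.data.frame(states) || !all(.state_cols %in% names(states))) {
    .stop_jtez(
      paste("expected a data frame with columns", paste(.state_cols, collapse = ", ")),
      "jtez_invalid_argument"
    )
  }
  vals <- as.matrix(states[.state_cols])
  if (!all(is.finite(vals))) {
    .stop_jtez("anisotropy parameters must all be finite", "jtez_invalid_argument")
  }
  invisible(states)
}

#' Modulus of the generalized anisotropy vector
#'
#' The six anisotropy parameters form a generalized vector whose modulus is the
#' root sum of squares of all six components. It equals
#' `sqrt(lb^2 + cb^2 + ld^2 + cd^2)` with the aggregates
#' `lb = sqrt(lb_0_90^2 + lb_45_135^2)` and `ld = sqrt(ld_0_90^2 + ld_45_135^2)`,
#' and vanishes only for the fully isotropic state.
#'
#' @param states Data frame of anisotropy states (see [anisotropy_state()]).
#' @return Numeric vector of moduli, one per row.
#' @examples
#' q_modulus(anisotropy_state(lb_0_90 = 0.3, lb_45_135 = 0.4)) # 0.5
#' @export
q_modulus <- function(states) {
  .check_states(states)
  vals <- as.matrix(states[.state_cols])
  sqrt(rowSums(vals^2))
}

#' Complex form of the generalized anisotropy vector
#'
#' Packs each anisotropy state into the three complex components that generate
#' the Jones matrix: `b_0_90 = lb_0_90 - 1i*ld_0_90`,
#' `b_45_135 = lb_45_135 - 1i*ld_45_135` and `a_circ = cb - 1i*cd`, together
#' with the complex modulus `q_complex = sqrt(b_0_90^2 + b_45_135^2 + a_circ^2)`
#' (principal square root, so `Re(q_complex) >= 0`) and the real modulus
#' `q_abs` of [q_modulus()]. For a purely refractive state (all dichroisms
#' zero) `q_complex` is real and equals `q_abs`.
#'
#' @inheritParams q_modulus
#' @return A tibble with complex columns `b_0_90`, `b_45_135`, `a_circ`,
#'   `q_complex` and numeric `q_abs`.
#' @export
generalized_vector <- function(states) {
  .check_states(states)
  b090 <- complex(real = states$lb_0_90, imaginary = -states$ld_0_90)
  b45  <- complex(real = states$lb_45_135, imaginary = -states$ld_45_135)
  a    <- complex(real = states$cb, imaginary = -states$cd)
  tibble::tibble(
    b_0_90 = b090, b_45_135 = b45, a_circ = a,
    q_complex = sqrt(b090^2 + b45^2 + a^2 + 0i),
    q_abs = q_modulus(states)
  )
}
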