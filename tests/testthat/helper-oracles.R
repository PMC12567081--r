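# Independent numerical oracles used across the suite.

# matrix exponential of a complex 2x2 by scaling-and-squaring on the
# truncated series (independent of the closed form under test)
expm_2x2 <- function(M) {
  nrm <- max(Mod(M))
  k <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 4L)
  A <- M/2^k
  S <- diag(2) + 0i
  term <- diag(2) + 0i
  for (n in 1:20) {
    term <- term %*% A/n
    S <- S + term
  }
  for (i in seq_len(k)) S <- S %*% S
  S
}

# generator matrix G of a six-parameter state (for the exponential oracle)
state_generator <- function(s) {
  b090 <- complex(real = s$lb_0_90, imaginary = -s$ld_0_90)
  b45 <- complex(real = s$lb_45_135, imaginary = -s$ld_45_135)
  a <- complex(real = s$cb, imaginary = -s$cd)
  matrix(c(-1i*b090, -a - 1i*b45, a - 1i*b45, 1i*b090), 2, 2)
}

# brute-force two-pass central moments (population, sd spread, excess z4)
brute_moments <- function(x) {
  k <- length(x)
  z1 <- sum(x)/k
  d <- x - z1
  m2 <- sum(d^2)/k
  s <- sqrt(m2)
  c(z1 = z1, z2 = s, z3 = sum(d^3)/k/s^3, z4 = sum(d^4)/k/s^4 - 3)
}

# circular mean resultant length of axis angles
resultant_length <- function(theta) Mod(mean(exp(1i*theta)))

# random anisotropy states with q_abs roughly uniform in (0, qmax)
random_states <- function(n, qmax = 3, seed = 1) {
  set.seed(seed)
  raw <- matrix(rnorm(6*n), n, 6)
  raw <- raw/sqrt(rowSums(raw^2))
  scale <- runif(n, 1e-3, qmax)
  out <- tibble::as_tibble(as.data.frame(raw*scale))
  names(out) <- c("lb_0_90", "lb_45_135", "cb", "ld_0_90", "ld_45_135", "cd")
  out
}

# aggregate relative RMSE between two jones fields over a mask
field_rel_rmse <- function(x, y, mask) {
  num <- 0; den <- 0
  for (k in c("w11", "w12", "w21", "w22")) {
    num <- num + sum(Mod(x[[k]] - y[[k]])[mask]^2)
    den <- den + sum(Mod(y[[k]])[mask]^2)
  }
  sqrt(num/den)
}

map_rel_rmse <- function(x, y, mask) {
  sqrt(mean((x[mask] - y[mask])^2))/sqrt(mean(y[mask]^2))
}

# small phantom spec used throughout the tests
test_spec <- function(grid = c(128, 128), ...) {
  phantom_spec(grid = grid, ...)
}
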