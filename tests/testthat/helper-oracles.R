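# Independent analytic oracles used by the forward-model tests.

# Closed-form surface potential of a current dipole inside a homogeneous
# conducting sphere with insulating boundary, derived from the generating
# functions of the Legendre series (independent of the package's truncated
# per-harmonic linear-system solution).
#
# dipole at position p (|p| < R), unit moment m, electrode at r (|r| = R).
homogeneous_sphere_potential <- function(p, m, r, R, sigma) {
  b <- sqrt(sum(p^2))
  stopifnot(b > 1e-9, b < R)
  ez <- p / b
  m_r <- sum(m * ez)
  tvec <- m - m_r * ez
  m_t <- sqrt(sum(tvec^2))
  ex <- if (m_t > 1e-12) tvec / m_t else c(0, 0, 0)
  u <- r / R
  tt <- sum(u * ez)            # cos(gamma)
  cp <- sum(u * ex)            # sin(gamma) cos(phi)
  f <- b / R
  h <- sqrt(1 - 2 * f * tt + f^2)
  S1 <- 2 * (tt - f) / h^3 + (1 / h - 1) / f
  S2 <- 2 / h^3 + (h + 1) / (h * (1 - f * tt + h))
  (m_r * S1 + m_t * cp * S2) / (4 * pi * sigma * R^2)
}

# quasi-uniform unit-sphere grid (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

# Laplace-distributed sample (used by ICA and negentropy oracles)
rlaplace <- function(n, scale = 1) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}
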