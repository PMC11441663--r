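# Small fixtures built in code, shared across test files.

# Four-observation dataset used in the IPW hand checks.
ipw_fixture <- function() {
  list(y = c(2, 4, 1, 3), t = c(1, 1, 0, 0), pi = c(0.25, 0.75, 0.25, 0.75))
}

# Tiny positional-layout table: (y, t, x1, z1).
tiny_table <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(y = rnorm(n), t = rep(c(0, 1), length.out = n),
             x1 = rnorm(n), z1 = rnorm(n))
}

# Independent closed-form threshold oracles (published formulas, v = 1),
# kept separate from the package's candidate-enumeration implementation.
soft_threshold <- function(z, lam) sign(z) * pmax(abs(z) - lam, 0)

scad_threshold <- function(z, lam, a = 3.7) {
  az <- abs(z)
  if (az <= 2 * lam) {
    soft_threshold(z, lam)
  } else if (az <= a * lam) {
    ((a - 1) * z - sign(z) * a * lam) / (a - 2)
  } else {
    z
  }
}

mcp_threshold <- function(z, lam, a = 3) {
  az <- abs(z)
  if (az <= a * lam) {
    soft_threshold(z, lam) / (1 - 1 / a)
  } else {
    z
  }
}

# Brute-force 1-D grid minimizer of v/2 (g - z)^2 + rho_lambda(|g|).
grid_threshold <- function(z, lam, penalty, a = NULL, alpha = 1, v = 1,
                           step = 5e-5) {
  g <- seq(-abs(z) - 2 * lam - 1, abs(z) + 2 * lam + 1, by = step)
  obj <- v / 2 * (g - z)^2 +
    penalty_value(abs(g), lam, penalty, a = a, alpha = alpha)
  g[which.min(obj)]
}

# Fast benchmark control for smoke-level end-to-end runs.
quick_control <- function(seed = 1, k = 5, m = 5, extrapolant = "quadratic") {
  simex_control(psi = seq(0, 1, length.out = m), k = k,
                extrapolant = extrapolant, seed = seed)
}
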