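# Internal helpers shared across modules.

# Clamp probabilities away from 0/1 so downstream weights stay finite.
clamp_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

# Deterministic substream seed for the (k, psi_index) pair (k-major order),
# optionally offset by a bootstrap replicate index. Keeps every derived seed
# strictly below 2^31 - 1 so set.seed() accepts it on all platforms.
substream_seed <- function(seed, k, m, offset = 0L) {
  base <- (as.numeric(seed) %% 1000003) * 2039
  s <- (base + as.numeric(k) * 16141 + as.numeric(m) * 127 +
          as.numeric(offset) * 524287) %% 2147483629
  as.integer(s) + 1L
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number.", name), call. = FALSE)
  }
  invisible(x)
}

assert_binary <- function(t, name = "treatment") {
  bad <- which(!(t %in% c(0, 1)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "`%s` must be coded 0/1; offending rows: %s.",
      name, paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(t)
}

assert_no_missing <- function(x, what) {
  if (anyNA(x)) {
    stop(sprintf("Missing values in %s are not supported; remove or impute upstream.", what),
         call. = FALSE)
  }
  invisible(x)
}

is_symmetric_matrix <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
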