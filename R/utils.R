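# Internal validation and seeding helpers shared across the generators and
# analysis functions.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (integer && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(lower),
                  format(upper)))
  }
  invisible(x)
}

assert_probability <- function(x, name) {
  assert_scalar_number(x, name, lower = 0, upper = 1)
}

# Deterministic expansion of one master seed into per-unit child seeds.
# Rule: child(master, i) = (1009 * master + 7919 * i) mod (2^31 - 1), +1 if 0.
# Documented so that externally regenerated datasets match exactly.
child_seed <- function(master, i) {
  s <- (1009 * as.double(master) + 7919 * as.double(i)) %% 2147483647
  s <- as.integer(s)
  if (s == 0L) 1L else s
}

# Binary symmetric adjacency check used by the cascade simulator.
assert_adjacency <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    abort("`adjacency` must be a square matrix.")
  }
  if (!all(adjacency %in% c(0, 1))) {
    abort("`adjacency` must be binary (0/1).")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    abort("`adjacency` must be symmetric.")
  }
  if (any(diag(adjacency) != 0)) {
    abort("`adjacency` must have a zero diagonal.")
  }
  invisible(adjacency)
}

# Edge-truncated centered moving average (windows shrink at the borders).
moving_average <- function(x, width) {
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
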