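# internal helpers shared across modules

# Deterministic child seed: fold a base seed and a sequence of labels into
# a 31-bit integer so stages/subjects/sessions can be (re)drawn in isolation
# without consuming a single global RNG stream.
child_seed <- function(seed, ...) {
  tokens <- paste(c(seed, ...), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(tokens)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(max(h, 1))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, upper))
  }
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# row variances of a matrix (trials projected through filters)
row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

is_session_recording <- function(x) inherits(x, "session_recording")
is_epoch_set <- function(x) inherits(x, "epoch_set")
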