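# Internal validation helpers shared across modules.

stop_dim <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Dimensions of a vector-or-matrix activation block: vectors are treated as a
# single-sample row.
act_dim <- function(x) {
  if (is.matrix(x)) dim(x) else c(1L, length(x))
}

as_act <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

check_same_shape <- function(a, b, what_a, what_b) {
  da <- act_dim(a)
  db <- act_dim(b)
  if (!identical(da, db)) {
    stop_dim("%s has shape %s but %s has shape %s",
             what_a, paste(da, collapse = "x"),
             what_b, paste(db, collapse = "x"))
  }
  invisible(TRUE)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic sub-seed derivation. Streams separate the independent sources
# of randomness (weights, feedback, per-epoch shuffles) while keeping every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  base <- (as.double(seed) %% 1e6) * 2017 + stream * 97003 + index * 131
  as.integer(base %% .Machine$integer.max)
}
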