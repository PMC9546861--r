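# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(expr))
}

# Derive a distinct but reproducible child seed from a base seed.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1009L * as.integer(k)) %% .Machine$integer.max
}

stop_multikin <- function(..., class = "multikin_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_multikin(name, " must be strictly positive and finite")
  }
  invisible(x)
}

assert_non_negative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_multikin(name, " must be non-negative and finite")
  }
  invisible(x)
}

M_PER_NM <- 1e-9

nM_to_M <- function(x) x * M_PER_NM
M_to_nM <- function(x) x / M_PER_NM
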