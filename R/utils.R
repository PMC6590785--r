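# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed plus integer
# tags (stage, group, repetition, ...).  A multiplicative-congruential mix
# keeps every derived value a valid 32-bit seed so the same master seed
# reproduces every sub-stream regardless of evaluation order.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.numeric(t) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.  Keeps library functions
# from perturbing user-level random streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
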