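# Internal helpers shared across modules.

# Deterministic derived seeds: one RNG stream per (stage, index) so pipeline
# stages and simulated weeks are independently reproducible from one master
# seed. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, stage, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(master) * 2654435 + h * 97 + as.numeric(index) * 10007) %% 2147483647)
}

# Run expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library internals never perturb user-visible RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
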