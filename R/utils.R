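#' @keywords internal
"_PACKAGE"

## Deterministic seed derivation: every stochastic stage draws its own
## sub-seed from the run seed plus a small integer key path, so that the
## output of one stage never depends on how many random numbers another
## stage consumed.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in keys) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## First-index argmax (deterministic tie-break to the lowest class index).
argmax1 <- function(x) which.max(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
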