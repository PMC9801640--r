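#' @keywords internal
"_PACKAGE"

## Seed plumbing. One user-facing seed; every stochastic component draws from
## its own derived stream so adding a stage never perturbs another stage's
## draws. Derived seeds stay below 2^31 - 1.

derive_seed <- function(seed, component) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(component) * seq_len(nchar(component)))
  as.integer(((as.numeric(seed) %% 65011) * 31013 + (h %% 104729)) %% 2147483647)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG state is restored afterwards. `seed = NULL` leaves the global stream
## untouched (draws come from wherever the user's RNG happens to be).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
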