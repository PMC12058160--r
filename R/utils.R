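# Internal helpers shared across modules.

# Locale-independent lexicographic sort: every downstream stochastic step is
# reproducible only if orderings do not depend on the session locale.
sort_c <- function(x) sort(x, method = "radix")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package calls never disturb user code.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

md_inform <- function(msg) {
  rlang::inform(msg, class = "methdriver_note")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
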