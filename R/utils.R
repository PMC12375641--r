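`%||%` <- function(a, b) if (is.null(a)) b else a

# A private seeded RNG stream that never disturbs the caller's global RNG
# state: every draw swaps the saved stream in, draws, and swaps the caller's
# state back. All stochastic generator/statistics code uses this, so
# cohorts are reproducible regardless of what the session RNG is doing.
local_rng <- function(seed) {
  genv <- globalenv()
  keep <- new.env()
  outer <- get0(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed))
  keep$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(outer)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", outer, envir = genv)
  }
  with_state <- function(fn) {
    force(fn)
    function(...) {
      outer <- get0(".Random.seed", envir = genv, inherits = FALSE)
      assign(".Random.seed", keep$state, envir = genv)
      on.exit({
        keep$state <- get(".Random.seed", envir = genv, inherits = FALSE)
        if (is.null(outer)) {
          if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
        } else {
          assign(".Random.seed", outer, envir = genv)
        }
      })
      fn(...)
    }
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample = with_state(base::sample))
}
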