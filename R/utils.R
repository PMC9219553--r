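`%||%` <- function(x, y) if (is.null(x)) y else x

## Run code with a temporary RNG state so that seeded draws inside the
## package never disturb the caller's random number stream.
with_preserved_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_hpt <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "hpt_error")))
}
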