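#' @keywords internal
"_PACKAGE"

#' @useDynLib tjstorm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois rgeom pnorm pchisq p.adjust sd qnorm
#' @importFrom utils read.csv write.csv
NULL

stop_tj <- function(..., class) {
  stop(structure(
    class = c(class, "tjstorm_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's
# RNG state afterwards so scene generation has no side effects.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
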