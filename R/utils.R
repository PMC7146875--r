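#' @importFrom stats rnorm rexp runif rbinom quantile pchisq pt var median
#'   density cor prcomp p.adjust phyper rlnorm sd lm coef setNames
#' @importFrom utils read.delim write.csv read.csv packageVersion
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs on the ambient stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                               strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) stop(sprintf("'%s' must be a single number in %s%s, %s%s",
                        name, if (strict) "(" else "[", lower, upper,
                        if (strict) ")" else "]"), call. = FALSE)
  invisible(x)
}
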