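#' @import methods
#' @importFrom stats approx median optim pnorm quantile rbinom rlnorm rnorm
#'   runif setNames
#' @importFrom utils head tail modifyList read.table write.table
#'   packageVersion
NULL

# Run expr with a local RNG state seeded at `seed`; the caller's RNG stream
# is untouched, so simulations are reproducible without global side effects.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

.packMismatches <- function(pos, ref, obs) {
  if (length(pos) == 0L) return(".")
  paste(sprintf("%d:%s>%s", pos, ref, obs), collapse = ";")
}

.unpackMismatches <- function(s) {
  if (is.na(s) || s == "." || s == "") {
    return(data.frame(pos = integer(), ref = character(),
                      obs = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[:>]")
  data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
             ref = vapply(parts, `[`, "", 2L),
             obs = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
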