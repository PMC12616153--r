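#' Z-transform a numeric vector
#'
#' Centers and scales to sample mean 0 and sample standard deviation 1
#' (denominator n - 1). Behavioral measures and mediation inputs are
#' z-transformed so path coefficients are standardized.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Numeric vector of the same length with mean 0 and SD 1.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  v <- values[is.finite(values)]
  if (length(v) < 2L || length(unique(v)) < 2L) {
    stop("cannot z-transform a constant or near-empty vector", call. = FALSE)
  }
  (values - mean(values, na.rm = TRUE)) / stats::sd(values, na.rm = TRUE)
}

# clip proportions into the open unit interval used by the bias-corrected
# bootstrap: [1/(B+1), B/(B+1)]
clip_prop <- function(p, B) {
  pmin(pmax(p, 1 / (B + 1)), B / (B + 1))
}

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic stream splitting: each generator / ROI gets its own seed so
#' that adding or removing one component does not shift the random draws of
#' the others. Uses a Lehmer-style modular hash; the result always lies in
#' [1, 2^31 - 2] and so is a valid `set.seed()` argument.
#'
#' @param master Integer master seed.
#' @param key Character scalar naming the stream (e.g. an ROI name).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  s <- ((abs(master) %% m) * 48271) %% m
  s <- (s + h) %% m
  as.integer(max(1, s))
}

# run an expression with a temporary RNG state; restores .Random.seed after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
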