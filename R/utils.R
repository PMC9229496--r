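# internal helpers shared across modules

stopf <- function(fmt, ..., class = "gaitstager_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "gaitstager_error")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so simulation calls do not perturb it.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Half-up decimal rounding (R's round() is banker's rounding); used when
# comparing full-precision metrics against printed 2-decimal tables.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_uniform_grid <- function(times, rtol = 1e-6) {
  if (length(times) < 3L) return(TRUE)
  d <- diff(times)
  max(d) - min(d) <= rtol * mean(d)
}
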