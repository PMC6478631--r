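# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

## Speed of sound in warm air, cm/s (uniform-tube formant model).
SPEED_OF_SOUND <- 35400

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so library calls never clobber user randomness.
## seed = NULL leaves the RNG stream alone (still reproducible if the caller
## seeded it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## dB <-> linear amplitude
db_to_lin <- function(db) 10 ^ (db / 20)
lin_to_db <- function(a) 20 * log10(pmax(a, .Machine$double.xmin))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## moving-average smoother with edge padding; width in points
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(round(width)))
  if (width <= 1L || length(x) < 2L) return(x)
  kernel <- rep(1 / width, width)
  n <- length(x)
  xp <- c(rep(x[1L], width), x, rep(x[n], width))
  out <- stats::filter(xp, kernel, sides = 2)
  as.numeric(out[(width + 1L):(width + n)])
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}
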