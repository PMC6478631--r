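## Sparse anchor contours: every time-varying control parameter (f0,
## amplitude, mouth opening, formant frequency ...) is specified as a handful
## of [time, value] anchors on a normalized time axis and densified on demand.

#' Create a contour specification from sparse anchors
#'
#' A contour is a set of `[time, value]` anchors with `time` normalized to
#' `[0, 1]` over the segment it controls.  Densification (see
#' [sample_contour()]) draws a shape-preserving monotone cubic through the
#' anchors, on the log scale for strictly positive parameters such as
#' fundamental or formant frequencies, so that pitch interpolation is
#' perceptually uniform and never overshoots between anchors.
#'
#' @param anchors one of: a single number (flat contour); a numeric vector of
#'   values (placed at equidistant times from 0 to 1); a 2-column matrix or
#'   data.frame of `(time, value)` rows; or a list of `c(time, value)` pairs
#'   as read from a YAML configuration.
#' @param scale `"linear"` or `"log"`: the domain in which interpolation is
#'   performed.  `"log"` is only valid for strictly positive values.
#' @param parameter optional name of the controlled parameter (used in error
#'   messages and by [wiggle_contour()] to pick a perturbation scale).
#' @param range optional length-2 numeric vector of legal values; anchors are
#'   validated against it and perturbed values clamped to it.
#' @return an object of class `contour_spec`.
#' @examples
#' cs <- contour_spec(rbind(c(0, 100), c(0.5, 200), c(1, 100)), scale = "log")
#' sample_contour(cs, duration = 1, rate = 100)$values[c(1, 51, 100)]
#' @export
contour_spec <- function(anchors, scale = c("linear", "log"),
                         parameter = NULL, range = NULL) {
  scale <- match.arg(scale)
  if (inherits(anchors, "contour_spec")) return(anchors)
  if (is.null(anchors) || (is.atomic(anchors) && length(anchors) == 0L))
    stop("contour needs at least one anchor", call. = FALSE)
  if (is.list(anchors) && !is.data.frame(anchors))
    anchors <- do.call(rbind, lapply(anchors, function(p) {
      if (length(p) != 2L) stop("each anchor must be a [time, value] pair",
                                call. = FALSE)
      as.numeric(p)
    }))
  if (is.data.frame(anchors)) anchors <- as.matrix(anchors)
  if (is.matrix(anchors)) {
    tab <- data.frame(time = anchors[, 1L], value = anchors[, 2L])
  } else if (is.numeric(anchors)) {
    n <- length(anchors)
    tms <- if (n == 1L) 0 else seq(0, 1, length.out = n)
    tab <- data.frame(time = tms, value = as.numeric(anchors))
  } else stop("unsupported anchor specification", call. = FALSE)
  if (anyNA(tab)) stop("anchors contain missing values", call. = FALSE)
  if (any(tab$time < 0 | tab$time > 1))
    stop("anchor times must lie in [0, 1]", call. = FALSE)
  tab <- tab[order(tab$time), , drop = FALSE]
  if (anyDuplicated(tab$time))
    stop("anchor times must be distinct", call. = FALSE)
  if (scale == "log" && any(tab$value <= 0))
    stop(sprintf("logarithmic contour '%s' requires strictly positive values",
                 parameter %||% "?"), call. = FALSE)
  if (!is.null(range)) {
    if (any(tab$value < range[1L] | tab$value > range[2L]))
      stop(sprintf("anchor value out of range [%g, %g] for '%s'",
                   range[1L], range[2L], parameter %||% "?"), call. = FALSE)
  }
  structure(list(anchors = tab, scale = scale, parameter = parameter,
                 range = range),
            class = "contour_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## shape-preserving monotone cubic interpolation (PCHIP); linear for two
## points, constant for one; queries are clamped to the anchored range
interp_monotone <- function(x, y, xout) {
  xq <- clamp(xout, min(x), max(x))
  if (length(x) == 1L) rep(y, length(xout))
  else if (length(x) == 2L) stats::approx(x, y, xout = xq)$y
  else pracma::pchip(x, y, xq)
}

#' @export
print.contour_spec <- function(x, ...) {
  cat(sprintf("<contour_spec%s: %d anchor(s), %s scale>\n",
              if (is.null(x$parameter)) "" else paste0(" ", x$parameter),
              nrow(x$anchors), x$scale))
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Densify an anchor contour
#'
#' Evaluates the contour on a regular grid of `round(duration * rate)` points
#' spanning the segment.  Interpolation is monotone piecewise-cubic
#' (Fritsch-Carlson, via [stats::splinefun()] `method = "monoH.FC"`): the
#' curve passes exactly through every anchor and never overshoots between
#' anchors whose values are monotone.  A single anchor yields a flat contour.
#'
#' @param spec a [contour_spec()] (or anything it accepts).
#' @param duration segment duration in seconds.
#' @param rate points per second (a sampling rate or an STFT frame rate).
#' @return an object of class `sampled_contour`: list with `values` (numeric
#'   vector), `rate`, and `duration`.
#' @export
sample_contour <- function(spec, duration, rate) {
  spec <- contour_spec(spec)
  stopifnot_scalar(duration, "duration", lo = 1e-9)
  stopifnot_scalar(rate, "rate", lo = 1e-9)
  n <- max(1L, as.integer(round(duration * rate)))
  tt <- if (n == 1L) 0 else seq(0, 1, length.out = n)
  a <- spec$anchors
  if (nrow(a) == 1L) {
    vals <- rep(a$value, n)
  } else {
    y <- if (spec$scale == "log") log(a$value) else a$value
    vals <- interp_monotone(a$time, y, tt)
    if (spec$scale == "log") vals <- exp(vals)
  }
  if (!is.null(spec$range)) vals <- clamp(vals, spec$range[1L], spec$range[2L])
  structure(list(values = vals, rate = rate, duration = duration),
            class = "sampled_contour")
}

#' @export
print.sampled_contour <- function(x, ...) {
  cat(sprintf("<sampled_contour: %d points @ %g/s, range [%g, %g]>\n",
              length(x$values), x$rate, min(x$values), max(x$values)))
  invisible(x)
}

## Default per-parameter perturbation scales used by wiggle_contour(): the SD
## of the anchor perturbation is temperature * scale.  Relative scales are
## fractions of the anchor value; absolute scales are in the parameter's
## units.
WIGGLE_SCALES <- list(
  f0        = list(type = "relative", scale = 0.05),  # 5% of value
  formant   = list(type = "relative", scale = 0.05),
  ampl      = list(type = "absolute", scale = 2),     # dB
  noise_env = list(type = "absolute", scale = 2),     # dB
  syl_len   = list(type = "relative", scale = 0.10),  # 10% of value
  pause_len = list(type = "relative", scale = 0.10),
  mouth     = list(type = "absolute", scale = 0.05)
)

#' Stochastic perturbation of contour anchors
#'
#' Adds a seeded Gaussian perturbation to every anchor value, with standard
#' deviation `temperature * scale`, where the per-parameter `scale` comes
#' from a fixed table (relative 5% for frequencies, 2 dB for amplitudes, 10%
#' for segment lengths, 0.05 for mouth opening).  Perturbed values are
#' clamped to the contour's legal range.  `temperature = 0` returns the spec
#' unchanged; the same seed always yields the same perturbation.
#'
#' @param spec a [contour_spec()].
#' @param temperature non-negative hyperparameter scaling all stochasticity.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return a perturbed `contour_spec`.
#' @export
wiggle_contour <- function(spec, temperature, seed = NULL) {
  spec <- contour_spec(spec)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature < 0)
    stop("`temperature` must be a single non-negative number", call. = FALSE)
  if (temperature == 0) return(spec)
  par <- spec$parameter %||% "f0"
  ws <- WIGGLE_SCALES[[par]] %||% WIGGLE_SCALES[["f0"]]
  with_seed(seed, {
    v <- spec$anchors$value
    sd_abs <- if (ws$type == "relative") temperature * ws$scale * abs(v)
              else rep(temperature * ws$scale, length(v))
    v2 <- v + stats::rnorm(length(v), 0, sd_abs)
    if (spec$scale == "log") v2 <- pmax(v2, v * 0.1)  # keep log-legal
    if (!is.null(spec$range)) v2 <- clamp(v2, spec$range[1L], spec$range[2L])
    spec$anchors$value <- v2
    spec
  })
}
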