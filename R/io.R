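## Configuration documents (YAML), WAV output, and the preset library.
## A config document mirrors the synth_config structure; every key is
## optional (defaults fill the gaps), unknown keys are rejected with their
## full path, and parse -> serialize -> parse is the identity.

## the full default document (plain nested list)
config_template <- function() {
  list(
    bout = list(n_syllables = 1L, syllable_len = 300, pause_len = 100,
                repeat_bout = 1L),
    source = list(f0 = 120, ampl = 0, rolloff = 12,
                  vibrato_freq = 5, vibrato_depth = 0,
                  jitter_depth = 0, jitter_period = 0.02,
                  shimmer_depth = 0, attack_len = 0.01,
                  am_depth = 0, am_freq = 30, am_shape = 1,
                  sub_ratio = 1L, sub_depth = 12,
                  chaos_jitter = 1.5, chaos_shimmer = 0.25),
    noise = list(envelope = -Inf, rolloff_noise = -4, flat_ceiling = 1200,
                 own_filter = NULL),
    formants = list(),
    antiformants = list(),
    tract = list(vtl = NULL, mouth = 0.5, lip_radiation = 6,
                 nose_radiation = 0),
    voiced = TRUE,
    nonlinear_balance = 0,
    regime_thresholds = c(0.5, 0.8),
    walk_smoothness = 10,
    regime_frame_rate = 100,
    temperature = 0.025,
    male_female = 0,
    sampling_rate = 22050,
    seed = NULL)
}

## top-level convenience aliases accepted in config files
CONFIG_ALIASES <- c(f0_anchors = "source.f0", f0 = "source.f0",
                    rolloff = "source.rolloff", mouth = "tract.mouth",
                    vtl = "tract.vtl", noise_envelope = "noise.envelope")

## recursive merge of a user document into the template, rejecting unknown
## keys with their dotted path
merge_document <- function(tmpl, doc, path = character()) {
  if (is.list(doc) && !length(doc)) return(tmpl)
  if (!is.list(doc) || is.null(names(doc))) return(doc)
  out <- tmpl
  for (key in names(doc)) {
    p <- paste(c(path, key), collapse = ".")
    if (!length(path) && key %in% names(CONFIG_ALIASES)) {
      parts <- strsplit(CONFIG_ALIASES[[key]], ".", fixed = TRUE)[[1L]]
      out[[parts[1L]]][[parts[2L]]] <- doc[[key]]
      next
    }
    if (!key %in% names(tmpl))
      stop(sprintf("unknown configuration key: %s", p), call. = FALSE)
    ## formant blocks and anchor lists are free-form below their key
    free <- p %in% c("formants", "antiformants", "noise.own_filter") ||
      !is.list(tmpl[[key]]) || is.null(names(tmpl[[key]]))
    out[[key]] <- if (free) doc[[key]]
                  else merge_document(tmpl[[key]], doc[[key]], c(path, key))
  }
  out
}

## -Inf round-trips through YAML as -.inf; NULLs stay null
doc_to_config <- function(doc) {
  err_at <- function(path, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s (at key '%s')", conditionMessage(e), path),
           call. = FALSE))
  }
  src <- doc$source
  source <- err_at("source", do.call(source_params, src))
  nz <- doc$noise
  noise <- err_at("noise", noise_params(
    envelope = nz$envelope, rolloff_noise = nz$rolloff_noise,
    flat_ceiling = nz$flat_ceiling,
    own_filter = if (!is.null(nz$own_filter))
      formant_table(nz$own_filter)))
  formants <- err_at("formants",
                     formant_table(doc$formants %||% list(),
                                   doc$antiformants %||% list()))
  tr <- doc$tract
  tract <- err_at("mouth", tract_params(
    vtl = tr$vtl, mouth = tr$mouth, lip_radiation = tr$lip_radiation,
    nose_radiation = tr$nose_radiation))
  err_at("", synth_config(
    n_syllables = doc$bout$n_syllables,
    syllable_len = doc$bout$syllable_len,
    pause_len = doc$bout$pause_len,
    repeat_bout = doc$bout$repeat_bout,
    source = source, noise = noise, formants = formants, tract = tract,
    voiced = doc$voiced,
    nonlinear_balance = doc$nonlinear_balance,
    regime_thresholds = as.numeric(doc$regime_thresholds),
    walk_smoothness = doc$walk_smoothness,
    regime_frame_rate = doc$regime_frame_rate,
    temperature = doc$temperature, male_female = doc$male_female,
    sampling_rate = doc$sampling_rate, seed = doc$seed))
}

#' Read a synthesis configuration from a YAML file
#'
#' Omitted keys take their documented defaults (an empty document is a valid
#' config: a flat 120-Hz voiced sound at 22050 Hz with no filtering).
#' Unknown keys and out-of-range values are rejected with the offending key
#' named in the error.
#'
#' @param path YAML file.
#' @return a [synth_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  parse_config(doc)
}

#' @rdname load_config
#' @param doc a nested list as produced by [yaml::read_yaml()]; NULL or an
#'   empty list gives the default configuration.
#' @export
parse_config <- function(doc = NULL) {
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("config document must be a mapping", call. = FALSE)
  doc_to_config(merge_document(config_template(), doc))
}

## ---- serialization ------------------------------------------------------

contour_to_doc <- function(spec) {
  a <- spec$anchors
  if (nrow(a) == 1L && a$time[1L] == 0) return(a$value[1L])
  lapply(seq_len(nrow(a)), function(i) c(a$time[i], a$value[i]))
}

formants_to_doc <- function(group) {
  lapply(group, function(f) {
    out <- list(freq = contour_to_doc(f$freq))
    if (f$amp != 0) out$amp <- f$amp
    if (!is.null(f$width)) out$width <- f$width
    if (f$strength != 1) out$strength <- f$strength
    out
  })
}

#' Serialize a configuration back to a document / YAML file
#'
#' Inverse of [load_config()]: `parse -> serialize -> parse` is the
#' identity.
#'
#' @param config a [synth_config()].
#' @param path YAML file to write; NULL returns the document (nested list).
#' @return the document, invisibly when written to a file.
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  s <- config$source
  doc <- list(
    bout = list(n_syllables = config$bout$n_syllables,
                syllable_len = contour_to_doc(config$bout$syllable_len),
                pause_len = contour_to_doc(config$bout$pause_len),
                repeat_bout = config$bout$repeat_bout),
    source = list(f0 = contour_to_doc(s$f0), ampl = contour_to_doc(s$ampl),
                  rolloff = s$rolloff, vibrato_freq = s$vibrato_freq,
                  vibrato_depth = s$vibrato_depth,
                  jitter_depth = s$jitter_depth,
                  jitter_period = s$jitter_period,
                  shimmer_depth = s$shimmer_depth,
                  attack_len = s$attack_len, am_depth = s$am_depth,
                  am_freq = s$am_freq, am_shape = s$am_shape,
                  sub_ratio = s$sub_ratio, sub_depth = s$sub_depth,
                  chaos_jitter = s$chaos_jitter,
                  chaos_shimmer = s$chaos_shimmer),
    noise = list(envelope = contour_to_doc(config$noise$envelope),
                 rolloff_noise = config$noise$rolloff_noise,
                 flat_ceiling = config$noise$flat_ceiling,
                 own_filter = if (!is.null(config$noise$own_filter))
                   formants_to_doc(config$noise$own_filter$formants)),
    formants = formants_to_doc(config$formants$formants),
    antiformants = formants_to_doc(config$formants$antiformants),
    tract = list(vtl = config$tract$vtl,
                 mouth = contour_to_doc(config$tract$mouth),
                 lip_radiation = config$tract$lip_radiation,
                 nose_radiation = config$tract$nose_radiation),
    voiced = config$voiced,
    nonlinear_balance = config$nonlinear_balance,
    regime_thresholds = config$regime_thresholds,
    walk_smoothness = config$walk_smoothness,
    regime_frame_rate = config$regime_frame_rate,
    temperature = config$temperature,
    male_female = config$male_female,
    sampling_rate = config$sampling_rate,
    seed = config$seed)
  if (is.null(path)) return(doc)
  yaml::write_yaml(doc, path)
  invisible(doc)
}

## ---- WAV I/O ------------------------------------------------------------
## Minimal RIFF/WAVE PCM-16 reader and writer (mono output; the reader also
## accepts stereo and averages channels).

#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' Samples are clamped to `[-1, 1]` and quantized to 16 bits.  The file is
#' written to a temporary name and atomically renamed, so a failed write
#' never leaves a partial file.
#'
#' @param sound a [waveform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sound, path) {
  stopifnot(inherits(sound, "waveform"))
  sr <- as.integer(round(sound$sampling_rate))
  pcm <- as.integer(round(clamp(sound$samples, -1, 1) * 32767))
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  con <- file(tmp, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (ok) file.rename(tmp, path) else unlink(tmp)
  })
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  ok <- TRUE
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Minimal RIFF parser for the files this package writes (PCM 16-bit; a
#' stereo file is mixed down by channel averaging).
#'
#' @param path WAV file.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  sr <- NULL; n_chan <- NULL; bits <- NULL; samples <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV is supported", call. = FALSE)
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV is supported", call. = FALSE)
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (tag == "data") {
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples) || is.null(sr))
    stop("malformed WAV file", call. = FALSE)
  x <- samples / 32767
  if (n_chan > 1L) {
    x <- matrix(x, nrow = n_chan)
    x <- colMeans(x)
  }
  waveform(x, sr)
}

## ---- presets ------------------------------------------------------------

#' Preset vocalizations
#'
#' The package ships reference configurations for a few call types (moan,
#' scream, laugh syllables, roar, and an animal-like growl) as plain YAML
#' under `inst/extdata/presets`.
#'
#' @return `preset_names()`: character vector of available presets.
#' @export
preset_names <- function() {
  dir <- system.file("extdata", "presets", package = "vocsynth")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' @rdname preset_names
#' @param name preset name, one of `preset_names()`.
#' @return `load_preset()`: a [synth_config()].
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "vocsynth")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(preset_names(), collapse = ", ")), call. = FALSE)
  load_config(path)
}
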