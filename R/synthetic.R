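#' Spike shape parameters
#'
#' Parametric description of one class's action-potential shape. The
#' waveform model is a half-Gaussian rise and half-Gaussian fall (widths in
#' the ratio `rise_fall_ratio`, jointly calibrated so the realized full
#' width at half amplitude equals `apd_ms`) followed by an
#' alpha-function afterhyperpolarization whose depth is calibrated to
#' `ahp_mv`. Every parameter maps one-to-one onto a measured shape
#' feature, so generated data can be verified in closed loop with
#' [ap_shape_features()].
#'
#' @param apt_mv threshold (baseline) voltage, mV.
#' @param amplitude_mv peak height above threshold, mV (> 0).
#' @param apd_ms full width at half amplitude, ms (> 0).
#' @param rise_fall_ratio ratio of rise-side to fall-side half-widths.
#' @param ahp_mv afterhyperpolarization depth below threshold, mV (>= 0).
#' @param ahp_tau_ms afterhyperpolarization time constant, ms; the trough
#'   sits near `ahp_tau_ms` after the peak and must fall inside the
#'   post-peak window.
#' @param jitter_cv per-spike multiplicative jitter (coefficient of
#'   variation) applied to amplitude, duration and AHP depth.
#' @return An object of class `spike_shape`.
#' @export
spike_shape <- function(apt_mv = -40, amplitude_mv = 65, apd_ms = 0.70,
                        rise_fall_ratio = 0.8, ahp_mv = 12.45,
                        ahp_tau_ms = 0.6, jitter_cv = 0.05) {
  stopifnot(amplitude_mv > 0, apd_ms > 0, ahp_mv >= 0, ahp_tau_ms > 0,
            rise_fall_ratio > 0, jitter_cv >= 0)
  structure(list(apt_mv = apt_mv, amplitude_mv = amplitude_mv,
                 apd_ms = apd_ms, rise_fall_ratio = rise_fall_ratio,
                 ahp_mv = ahp_mv, ahp_tau_ms = ahp_tau_ms,
                 jitter_cv = jitter_cv),
            class = "spike_shape")
}

#' Class specification for trace generation
#'
#' @param label class name (e.g. `"PV"`).
#' @param shape a [spike_shape()].
#' @param n_neurons number of neurons (traces) to generate.
#' @param spikes_per_neuron spikes per trace.
#' @param rest_mv resting (baseline) membrane potential, mV.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, shape = spike_shape(), n_neurons = 5L,
                       spikes_per_neuron = 100L, rest_mv = -65) {
  stopifnot(inherits(shape, "spike_shape"), n_neurons >= 1L,
            spikes_per_neuron >= 1L)
  structure(list(label = label, shape = shape,
                 n_neurons = as.integer(n_neurons),
                 spikes_per_neuron = as.integer(spikes_per_neuron),
                 rest_mv = rest_mv),
            class = "class_spec")
}

# Deviation-from-threshold waveform on a [-pre, +post) ms grid, with the
# peak at sample n_pre + 1. The half-Gaussian widths and the AHP depth are
# calibrated by fixed-point iteration against the package's own shape
# measurement (ap_shape_one), so the APD and AHP that the feature
# extractor reads off the generated spike match the requested values: the
# dV/dt-defined threshold sits above the nominal baseline and the AHP
# component superposes on the Gaussian fall, and both would otherwise bias
# the realized morphometry.
ap_waveform <- function(shape, fs, pre_ms = 1, post_ms = 2, tail_ms = 0,
                        apd_ms = shape$apd_ms, amplitude_mv = shape$amplitude_mv,
                        ahp_mv = shape$ahp_mv) {
  if (apd_ms >= pre_ms + post_ms)
    stop("apd_ms must be shorter than the epoch window", call. = FALSE)
  n_pre <- round(pre_ms * fs / 1000)
  n_post <- round((post_ms + tail_ms) * fs / 1000)
  s <- (seq_len(n_pre + n_post) - (n_pre + 1L)) * 1000 / fs   # ms from peak
  n_win <- n_pre + round(post_ms * fs / 1000)                 # epoch extent
  A <- amplitude_mv
  ratio <- shape$rise_fall_ratio
  tau <- shape$ahp_tau_ms
  sig_total <- apd_ms / sqrt(2 * log(2))   # sigma_r + sigma_f, first guess
  h <- ahp_mv
  alpha_fn <- ifelse(s > 0, (s / tau) * exp(1 - s / tau), 0)
  dev <- NULL
  for (it in 1:8) {
    sig_f <- sig_total / (1 + ratio)
    sig_r <- sig_total - sig_f
    g <- ifelse(s <= 0, exp(-s^2 / (2 * sig_r^2)), exp(-s^2 / (2 * sig_f^2)))
    dev <- A * g - h * alpha_fn
    meas <- ap_shape_one(dev[seq_len(n_win)], n_pre + 1L, fs, 10)
    if (anyNA(meas[c("apd_ms")])) break
    err_apd <- abs(meas[["apd_ms"]] / apd_ms - 1)
    sig_total <- sig_total * apd_ms / meas[["apd_ms"]]
    err_ahp <- 0
    if (ahp_mv > 0) {
      if (meas[["ahp_mv"]] > 0) {
        err_ahp <- abs(meas[["ahp_mv"]] / ahp_mv - 1)
        h <- h * ahp_mv / meas[["ahp_mv"]]
      } else h <- h + ahp_mv        # AHP not yet expressed: deepen
    }
    if (err_apd < 1e-4 && err_ahp < 1e-4) break
  }
  dev
}

# Draw one jittered parameter set from the current RNG stream.
jitter_shape <- function(shape) {
  cv <- shape$jitter_cv
  if (cv <= 0) return(shape[c("apd_ms", "amplitude_mv", "ahp_mv")])
  f <- function() max(0.5, min(1.5, 1 + cv * stats::rnorm(1)))
  list(apd_ms = shape$apd_ms * f(),
       amplitude_mv = shape$amplitude_mv * f(),
       ahp_mv = shape$ahp_mv * f())
}

#' Generate one spike waveform
#'
#' Produces a single action-potential epoch spanning 1 ms before to 2 ms
#' after the peak, on the threshold baseline `apt_mv`, with per-spike
#' parameter jitter of `shape$jitter_cv`.
#'
#' @param shape a [spike_shape()].
#' @param fs sampling rate, Hz (>= 10 kHz).
#' @param seed optional integer seed for the jitter draw.
#' @return Numeric voltage vector (mV) with attributes `fs` and
#'   `peak_offset` (zero-based, `round(fs / 1000)`).
#' @export
make_spike <- function(shape, fs = 20000, seed = NULL) {
  stopifnot(inherits(shape, "spike_shape"))
  if (fs < 10000) stop("make_spike needs fs >= 10 kHz", call. = FALSE)
  pars <- with_seed(seed, jitter_shape(shape))
  dev <- ap_waveform(shape, fs, pre_ms = 1, post_ms = 2,
                     apd_ms = pars$apd_ms, amplitude_mv = pars$amplitude_mv,
                     ahp_mv = pars$ahp_mv)
  structure(shape$apt_mv + dev, fs = fs, peak_offset = round(fs / 1000))
}

#' Generate one neuron's trace with ground-truth markers
#'
#' Places `spec$spikes_per_neuron` spikes by exponential inter-spike
#' intervals with a 10 ms refractory floor on a resting baseline, and adds
#' Gaussian noise plus a line-frequency sinusoid (random phase). Spike
#' waveforms ride on the baseline as deviations from threshold level; each
#' spike carries independent parameter jitter. The true peak sample
#' indices are returned as ground truth.
#'
#' @param spec a [class_spec()].
#' @param duration_s trace duration, s; must leave room for the requested
#'   spike count above the refractory floor.
#' @param noise_sd_mv Gaussian noise standard deviation, mV.
#' @param line_amp_mv line-interference amplitude, mV.
#' @param line_hz line frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed.
#' @param neuron_id identifier stored on the trace.
#' @return List with `trace` (an [ap_trace()] labeled with the class) and
#'   `markers` (integer peak sample indices).
#' @export
make_trace <- function(spec, duration_s, noise_sd_mv = 0.5,
                       line_amp_mv = 1.0, line_hz = 50, fs = 20000,
                       seed = NULL, neuron_id = spec$label) {
  stopifnot(inherits(spec, "class_spec"))
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  n_spk <- spec$spikes_per_neuron
  refr <- 0.010
  margin_lo <- 0.0015
  margin_hi <- 0.0035
  avail <- duration_s - margin_lo - margin_hi - n_spk * refr
  if (avail <= 0)
    stop(sprintf("duration %g s cannot hold %d spikes at the 10 ms refractory floor",
                 duration_s, n_spk), call. = FALSE)
  with_seed(seed, {
    rate <- n_spk / avail * 1.4
    peaks_t <- NULL
    for (try in 1:50) {
      gaps <- stats::rexp(n_spk, rate)
      pt <- margin_lo + cumsum(c(gaps[1L], refr + gaps[-1L]))
      if (pt[n_spk] <= duration_s - margin_hi) { peaks_t <- pt; break }
    }
    if (is.null(peaks_t))
      stop("could not place ", n_spk, " spikes in ", duration_s,
           " s; increase the duration", call. = FALSE)
    n <- round(duration_s * fs)
    x <- rep(spec$rest_mv, n)
    if (noise_sd_mv > 0) x <- x + stats::rnorm(n, 0, noise_sd_mv)
    if (line_amp_mv > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + line_amp_mv * sin(2 * pi * line_hz * seq_len(n) / fs + phase)
    }
    n_pre <- round(fs / 1000)
    markers <- integer(n_spk)
    for (i in seq_len(n_spk)) {
      pars <- jitter_shape(spec$shape)
      dev <- ap_waveform(spec$shape, fs, pre_ms = 1, post_ms = 2,
                         tail_ms = 6,
                         apd_ms = pars$apd_ms,
                         amplitude_mv = pars$amplitude_mv,
                         ahp_mv = pars$ahp_mv)
      pk <- round(peaks_t[i] * fs) + 1L
      idx <- (pk - n_pre):(pk - n_pre + length(dev) - 1L)
      keep <- idx >= 1L & idx <= n
      x[idx[keep]] <- x[idx[keep]] + dev[keep]
      markers[i] <- pk
    }
    list(trace = ap_trace(x, fs = fs, neuron_id = neuron_id,
                          class_label = spec$label),
         markers = markers)
  })
}

#' Built-in class presets
#'
#' `"paper3"` holds the three cortical classes with their reported mean
#' spike durations and afterhyperpolarization depths (PV: APD 0.70 ms, AHP
#' 12.45 mV; SST: 1.18 ms, 7.23 mV; Pyr: 1.41 ms, 3.06 mV). `"allen5"`
#' adds VIP and 5HT3a interneurons with interpolated shape parameters;
#' these two are synthetic stand-ins, not measurements. Parameters without
#' a reported value (resting potential -65 mV, amplitude 65 mV, per-class
#' thresholds, rise/fall asymmetry, jitter) are generator conventions.
#'
#' @param preset `"paper3"` or `"allen5"`.
#' @param n_neurons,spikes_per_neuron per-class counts.
#' @return A list of [class_spec()] objects.
#' @export
preset_specs <- function(preset = c("paper3", "allen5"), n_neurons = 5L,
                         spikes_per_neuron = 100L) {
  preset <- match.arg(preset)
  mk <- function(label, apt, apd, ratio, ahp, tau)
    class_spec(label,
               spike_shape(apt_mv = apt, amplitude_mv = 65, apd_ms = apd,
                           rise_fall_ratio = ratio, ahp_mv = ahp,
                           ahp_tau_ms = tau, jitter_cv = 0.05),
               n_neurons = n_neurons,
               spikes_per_neuron = spikes_per_neuron, rest_mv = -65)
  specs <- list(
    mk("PV",  -40, 0.70, 0.8, 12.45, 0.6),
    mk("SST", -44, 1.18, 0.6, 7.23, 0.9),
    mk("Pyr", -42, 1.41, 0.5, 3.06, 1.2))
  if (preset == "allen5")
    specs <- c(specs, list(
      mk("VIP",   -42, 0.95, 0.7, 9.50, 0.8),
      mk("5HT3a", -43, 1.05, 0.65, 8.30, 0.85)))
  specs
}

#' Generate a labeled synthetic dataset
#'
#' Generates all traces for a list of class specifications (or a built-in
#' preset), with per-trace ground-truth markers and a manifest from which
#' the dataset can be regenerated bit-identically.
#'
#' @param specs list of [class_spec()]; at least 2 classes with distinct
#'   labels. Defaults to `preset_specs(preset, ...)`.
#' @param preset preset name used when `specs` is `NULL`.
#' @param n_neurons,spikes_per_neuron per-class counts for the preset.
#' @param duration_s trace duration; defaults to
#'   `0.05 + spikes_per_neuron * 0.03` seconds.
#' @param noise_sd_mv,line_amp_mv,line_hz noise model, see [make_trace()].
#' @param fs sampling rate, Hz.
#' @param seed integer master seed; per-trace seeds are derived from it.
#' @return An object of class `synthetic_dataset`: list with `traces`
#'   (list of [ap_trace()]), `markers` (list of integer vectors), `labels`,
#'   `neuron_ids`, `manifest`.
#' @seealso [regenerate_dataset()], [extract_dataset()]
#' @export
make_dataset <- function(specs = NULL, preset = c("paper3", "allen5"),
                         n_neurons = 5L, spikes_per_neuron = 100L,
                         duration_s = NULL, noise_sd_mv = 0.5,
                         line_amp_mv = 1.0, line_hz = 50, fs = 20000,
                         seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(specs))
    specs <- preset_specs(preset, n_neurons, spikes_per_neuron)
  stopifnot(all(vapply(specs, inherits, TRUE, "class_spec")))
  labels <- vapply(specs, `[[`, "", "label")
  if (length(specs) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate class labels", call. = FALSE)

  n_traces <- sum(vapply(specs, `[[`, 1L, "n_neurons"))
  trace_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            n_traces))
  traces <- vector("list", n_traces)
  markers <- vector("list", n_traces)
  trace_labels <- character(n_traces)
  neuron_ids <- character(n_traces)
  k <- 0L
  for (sp in specs) {
    dur <- if (is.null(duration_s)) 0.05 + sp$spikes_per_neuron * 0.03
           else duration_s
    for (j in seq_len(sp$n_neurons)) {
      k <- k + 1L
      nid <- sprintf("%s_%02d", sp$label, j)
      out <- make_trace(sp, duration_s = dur, noise_sd_mv = noise_sd_mv,
                        line_amp_mv = line_amp_mv, line_hz = line_hz,
                        fs = fs, seed = trace_seeds[k], neuron_id = nid)
      traces[[k]] <- out$trace
      markers[[k]] <- out$markers
      trace_labels[k] <- sp$label
      neuron_ids[k] <- nid
    }
  }
  manifest <- list(
    seed = seed, fs = fs, duration_s = duration_s,
    noise_sd_mv = noise_sd_mv, line_amp_mv = line_amp_mv,
    line_hz = line_hz,
    classes = lapply(specs, function(sp)
      c(list(label = sp$label, n_neurons = sp$n_neurons,
             spikes_per_neuron = sp$spikes_per_neuron,
             rest_mv = sp$rest_mv), unclass(sp$shape))),
    note = paste("synthetic data; rest/amplitude/threshold/jitter/noise",
                 "defaults are generator conventions, not measured values"))
  structure(list(traces = traces, markers = markers, labels = trace_labels,
                 neuron_ids = neuron_ids, manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d traces, %d spikes, classes: %s (seed %d)\n",
              length(x$traces), sum(lengths(x$markers)),
              paste(unique(x$labels), collapse = ", "), x$manifest$seed))
  invisible(x)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest the `manifest` element of a [make_dataset()] result.
#' @return A `synthetic_dataset` bit-identical to the original.
#' @export
regenerate_dataset <- function(manifest) {
  specs <- lapply(manifest$classes, function(cl)
    class_spec(cl$label,
               spike_shape(apt_mv = cl$apt_mv, amplitude_mv = cl$amplitude_mv,
                           apd_ms = cl$apd_ms,
                           rise_fall_ratio = cl$rise_fall_ratio,
                           ahp_mv = cl$ahp_mv, ahp_tau_ms = cl$ahp_tau_ms,
                           jitter_cv = cl$jitter_cv),
               n_neurons = cl$n_neurons,
               spikes_per_neuron = cl$spikes_per_neuron,
               rest_mv = cl$rest_mv))
  make_dataset(specs, duration_s = manifest$duration_s,
               noise_sd_mv = manifest$noise_sd_mv,
               line_amp_mv = manifest$line_amp_mv,
               line_hz = manifest$line_hz, fs = manifest$fs,
               seed = manifest$seed)
}

#' Run a dataset through denoising, detection and epoch extraction
#'
#' Convenience wrapper applying [preprocess_trace()], [detect_peaks()] and
#' [extract_spikes()] to every trace of a dataset and pooling the results.
#'
#' @param ds a `synthetic_dataset` (or list with `traces`).
#' @param notch,smooth denoising switches, see [preprocess_trace()].
#' @param threshold_mv,min_isi_ms detection parameters.
#' @param pre_ms,post_ms epoch window.
#' @return A pooled labeled [spike_set()].
#' @export
extract_dataset <- function(ds, notch = TRUE, smooth = TRUE,
                            threshold_mv = -20, min_isi_ms = 2.0,
                            pre_ms = 1.0, post_ms = 2.0) {
  sets <- lapply(ds$traces, function(tr) {
    den <- preprocess_trace(tr, notch = notch, smooth = smooth)
    mk <- detect_peaks(den, threshold_mv = threshold_mv,
                       min_isi_ms = min_isi_ms)
    extract_spikes(den, mk, pre_ms = pre_ms, post_ms = post_ms)
  })
  combine_spikes(sets)
}
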