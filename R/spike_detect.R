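#' Detect action-potential peaks by thresholding
#'
#' Finds every contiguous supra-threshold excursion of the trace and places
#' one marker at its maximum sample (plateau ties resolve to the earliest
#' sample). Peaks closer together than `min_isi_ms` are pruned, keeping the
#' larger peak.
#'
#' @param trace a (preferably denoised) [ap_trace()].
#' @param threshold_mv detection threshold in mV; action-potential peaks
#'   overshoot far above subthreshold activity, so an absolute value such
#'   as -20 mV works for typical resting potentials near -65 mV.
#' @param min_isi_ms minimum separation between retained peaks (ms).
#' @return An object of class `spike_markers`: list with `peak_indices`
#'   (1-based sample indices, strictly increasing), `threshold_mv`, `fs`.
#'   An empty marker set is a valid result.
#' @export
detect_peaks <- function(trace, threshold_mv = -20, min_isi_ms = 2.0) {
  stopifnot(inherits(trace, "ap_trace"))
  x <- trace$samples
  above <- x >= threshold_mv
  peaks <- integer(0)
  if (any(above)) {
    d <- diff(c(FALSE, above, FALSE))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    peaks <- vapply(seq_along(starts), function(i) {
      seg <- starts[i]:ends[i]
      seg[which.max(x[seg])]        # which.max -> earliest on plateaus
    }, 0L)
    # enforce the refractory separation, keeping the larger peak
    min_gap <- round(min_isi_ms * trace$fs / 1000)
    if (length(peaks) > 1L && min_gap > 0L) {
      keep <- rep(TRUE, length(peaks))
      last <- 1L
      for (i in 2L:length(peaks)) {
        if (peaks[i] - peaks[last] < min_gap) {
          if (x[peaks[i]] > x[peaks[last]]) {
            keep[last] <- FALSE; last <- i
          } else keep[i] <- FALSE
        } else last <- i
      }
      peaks <- peaks[keep]
    }
  }
  structure(list(peak_indices = as.integer(peaks),
                 threshold_mv = threshold_mv, fs = trace$fs),
            class = "spike_markers")
}

#' @export
print.spike_markers <- function(x, ...) {
  cat(sprintf("<spike_markers> %d peaks (threshold %g mV @ %g Hz)\n",
              length(x$peak_indices), x$threshold_mv, x$fs))
  invisible(x)
}

#' Cut fixed-length spike epochs around markers
#'
#' For each marker at sample `t` the half-open window
#' `[t - round(pre_ms * fs / 1000), t + round(post_ms * fs / 1000))` becomes
#' one epoch row; samples are exact copies of the trace (no re-filtering).
#' With the default 1 ms before / 2 ms after window at 20 kHz each epoch
#' has exactly 60 samples with the peak at zero-based offset 20. Markers
#' whose window would run past either end of the trace are skipped and
#' counted in the result's `n_skipped`.
#'
#' @param trace the [ap_trace()] the markers refer to.
#' @param markers a `spike_markers` object from [detect_peaks()].
#' @param pre_ms,post_ms window extent before/after the peak (ms).
#' @return A [spike_set()]; `source_ids` and `labels` are filled from the
#'   trace's `neuron_id` / `class_label` when present.
#' @export
extract_spikes <- function(trace, markers, pre_ms = 1.0, post_ms = 2.0) {
  stopifnot(inherits(trace, "ap_trace"), inherits(markers, "spike_markers"))
  if (!isTRUE(all.equal(markers$fs, trace$fs)))
    stop("markers were detected at a different sampling rate", call. = FALSE)
  fs <- trace$fs
  npre <- round(pre_ms * fs / 1000)
  npost <- round(post_ms * fs / 1000)
  w <- npre + npost
  n <- length(trace$samples)
  ok <- markers$peak_indices - npre >= 1L &
        markers$peak_indices + npost - 1L <= n
  kept <- markers$peak_indices[ok]
  wav <- matrix(0, nrow = length(kept), ncol = w)
  for (i in seq_along(kept))
    wav[i, ] <- trace$samples[(kept[i] - npre):(kept[i] + npost - 1L)]
  n_skip <- sum(!ok)
  if (length(kept) == 0L)
    warning("no extractable markers (", n_skip, " skipped at edges)",
            call. = FALSE)
  spike_set(wav, fs = fs, pre_ms = pre_ms, post_ms = post_ms,
            peak_offset = npre,
            source_ids = if (!is.null(trace$neuron_id))
              rep(trace$neuron_id, length(kept)),
            labels = if (!is.null(trace$class_label))
              rep(trace$class_label, length(kept)),
            n_skipped = n_skip)
}
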