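#' Membrane-potential trace
#'
#' Container for one neuron's intracellular membrane-potential time series.
#' Voltages are in millivolts; the sampling rate must be known (the reference
#' acquisition setting for this pipeline is 20 kHz).
#'
#' @param samples numeric vector of membrane potentials (mV), all finite,
#'   length at least 2.
#' @param fs sampling rate in Hz, positive.
#' @param units voltage unit tag; only `"mV"` is supported.
#' @param neuron_id optional free-text neuron identifier.
#' @param class_label optional class label (e.g. `"PV"`, `"SST"`, `"Pyr"`).
#' @return An object of class `ap_trace`: a list with elements `samples`,
#'   `fs`, `units`, `neuron_id`, `class_label`.
#' @examples
#' tr <- ap_trace(rep(-65, 100), fs = 20000, neuron_id = "n1")
#' length(tr$samples)
#' @export
ap_trace <- function(samples, fs, units = "mV", neuron_id = NULL,
                     class_label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("trace samples must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  if (!identical(units, "mV"))
    stop("only millivolt ('mV') traces are supported", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs), units = "mV",
         neuron_id = neuron_id, class_label = class_label),
    class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.null(x$neuron_id)) cat("  neuron_id:  ", x$neuron_id, "\n")
  if (!is.null(x$class_label)) cat("  class_label:", x$class_label, "\n")
  cat(sprintf("  range: [%.3f, %.3f] mV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Spike epoch set
#'
#' A set of fixed-length spike epochs cut around detected action-potential
#' peaks. With the reference window (1 ms before to 2 ms after the peak) at
#' 20 kHz every row has exactly 60 samples and the peak sits at zero-based
#' offset 20.
#'
#' @param waveforms numeric matrix, one spike per row (mV).
#' @param fs sampling rate in Hz.
#' @param pre_ms,post_ms window extent before/after the peak (ms).
#' @param peak_offset zero-based sample offset of the peak within each row;
#'   defaults to `round(pre_ms * fs / 1000)`.
#' @param source_ids optional per-row neuron identifier.
#' @param labels optional per-row class label (must cover all rows).
#' @param n_skipped number of markers skipped because their window ran off
#'   an edge of the trace.
#' @return An object of class `spike_set`.
#' @export
spike_set <- function(waveforms, fs, pre_ms, post_ms,
                      peak_offset = round(pre_ms * fs / 1000),
                      source_ids = NULL, labels = NULL, n_skipped = 0L) {
  waveforms <- as.matrix(waveforms)
  w <- round((pre_ms + post_ms) * fs / 1000)
  if (nrow(waveforms) > 0L && ncol(waveforms) != w)
    stop(sprintf("spike rows have %d samples; window implies %d",
                 ncol(waveforms), w), call. = FALSE)
  if (peak_offset < 0 || (nrow(waveforms) > 0L && peak_offset >= w))
    stop("peak_offset must lie inside the window", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(waveforms))
    stop("labels must cover every spike row", call. = FALSE)
  if (!is.null(source_ids) && length(source_ids) != nrow(waveforms))
    stop("source_ids must cover every spike row", call. = FALSE)
  structure(
    list(waveforms = waveforms, peak_offset = as.integer(peak_offset),
         fs = fs, pre_ms = pre_ms, post_ms = post_ms,
         source_ids = source_ids, labels = labels,
         n_skipped = as.integer(n_skipped)),
    class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("<spike_set> %d spikes x %d samples @ %g Hz (-%g/+%g ms, peak offset %d)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$fs,
              x$pre_ms, x$post_ms, x$peak_offset))
  if (!is.null(x$labels))
    print(table(x$labels))
  if (x$n_skipped > 0L)
    cat("  markers skipped at edges:", x$n_skipped, "\n")
  invisible(x)
}

#' @export
dim.spike_set <- function(x) dim(x$waveforms)

#' Combine several spike sets
#'
#' Row-binds spike sets that share the same window geometry and sampling
#' rate, concatenating labels and source ids.
#'
#' @param sets a list of `spike_set` objects.
#' @return A single `spike_set`.
#' @export
combine_spikes <- function(sets) {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "spike_set")))
  ref <- sets[[1L]]
  for (s in sets[-1L])
    if (s$fs != ref$fs || s$pre_ms != ref$pre_ms || s$post_ms != ref$post_ms)
      stop("spike sets have incompatible windows or sampling rates",
           call. = FALSE)
  has_lab <- !vapply(sets, function(s) is.null(s$labels), TRUE)
  has_src <- !vapply(sets, function(s) is.null(s$source_ids), TRUE)
  spike_set(
    do.call(rbind, lapply(sets, `[[`, "waveforms")),
    fs = ref$fs, pre_ms = ref$pre_ms, post_ms = ref$post_ms,
    peak_offset = ref$peak_offset,
    source_ids = if (all(has_src)) unlist(lapply(sets, `[[`, "source_ids")),
    labels = if (all(has_lab)) unlist(lapply(sets, `[[`, "labels")),
    n_skipped = sum(vapply(sets, `[[`, 1L, "n_skipped")))
}

#' Feature matrix
#'
#' Per-spike feature vectors: DCT coefficients (`kind = "dct"`, 100 columns),
#' action-potential shape variables (`kind = "ap_shape"`, 7 columns), raw
#' epoch samples (`kind = "raw"`) or principal-component scores
#' (`kind = "pc_scores"`).
#'
#' @param values numeric matrix, one spike per row; all finite.
#' @param kind one of `"dct"`, `"ap_shape"`, `"pc_scores"`, `"raw"`.
#' @param labels,source_ids optional per-row annotations carried from the
#'   originating [spike_set()].
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kind = c("dct", "ap_shape", "pc_scores", "raw"),
                           labels = NULL, source_ids = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop("feature values must all be finite", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("labels must cover every row", call. = FALSE)
  if (!is.null(source_ids) && length(source_ids) != nrow(values))
    stop("source_ids must cover every row", call. = FALSE)
  structure(
    list(values = values, kind = kind,
         column_names = colnames(values),
         labels = labels, source_ids = source_ids),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d, kind '%s'%s\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Accept either a bare matrix or a feature_matrix; return the matrix and
# annotations in one normal form.
fm_parts <- function(x, labels = NULL) {
  if (inherits(x, "feature_matrix")) {
    list(values = x$values,
         labels = if (is.null(labels)) x$labels else labels,
         source_ids = x$source_ids, kind = x$kind)
  } else {
    list(values = as.matrix(x), labels = labels, source_ids = NULL,
         kind = "raw")
  }
}

# Subset rows keeping annotations aligned.
fm_subset <- function(x, idx) {
  feature_matrix(x$values[idx, , drop = FALSE], kind = x$kind,
                 labels = if (!is.null(x$labels)) x$labels[idx],
                 source_ids = if (!is.null(x$source_ids)) x$source_ids[idx])
}
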