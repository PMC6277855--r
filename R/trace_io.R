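#' Read a voltage trace from delimited text
#'
#' The trace format is plain text: lines starting with `#` hold `key=value`
#' metadata (the key `fs_hz` is required; `units`, `neuron_id` and
#' `class_label` are recognized), every following non-empty line holds one
#' voltage sample in mV, or two whitespace/comma-separated columns
#' `time,voltage` of which the time column is ignored (spacing is assumed
#' uniform at `fs_hz`).
#'
#' @param path path to an existing trace file.
#' @return An [ap_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    stop("trace file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grepl("^\\s*#", lines)
  meta <- parse_header(lines[hdr_idx], path)
  if (is.null(meta$fs_hz))
    stop("trace file ", path, " has no 'fs_hz' header line", call. = FALSE)
  fs <- suppressWarnings(as.numeric(meta$fs_hz))
  if (!is.finite(fs) || fs <= 0)
    stop("invalid fs_hz value in ", path, ": ", meta$fs_hz, call. = FALSE)

  data_lines <- which(!hdr_idx & !grepl("^\\s*$", lines))
  if (length(data_lines) == 0L)
    stop("trace file ", path, " contains no samples", call. = FALSE)
  fields <- strsplit(trimws(lines[data_lines]), "[,;\t ]+")
  nf <- lengths(fields)
  if (any(nf > 2L))
    stop(sprintf("line %d of %s: expected 1 or 2 columns, got %d",
                 data_lines[which(nf > 2L)[1L]], path, max(nf)), call. = FALSE)
  vals <- vapply(fields, function(f) f[[length(f)]], "")
  samples <- suppressWarnings(as.numeric(vals))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L]
    stop(sprintf("line %d of %s: non-numeric sample '%s'",
                 data_lines[bad], path, vals[bad]), call. = FALSE)
  }
  ap_trace(samples, fs = fs,
           units = if (is.null(meta$units)) "mV" else meta$units,
           neuron_id = meta$neuron_id, class_label = meta$class_label)
}

#' Write a voltage trace
#'
#' Writes a trace in the format read by [read_trace()], preserving sample
#' values to at least 15 significant digits.
#'
#' @param trace an [ap_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ap_trace"))
  hdr <- c(sprintf("# fs_hz=%s", format(trace$fs, digits = 15)),
           "# units=mV")
  if (!is.null(trace$neuron_id))
    hdr <- c(hdr, paste0("# neuron_id=", trace$neuron_id))
  if (!is.null(trace$class_label))
    hdr <- c(hdr, paste0("# class_label=", trace$class_label))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(hdr, sprintf("%.15g", trace$samples)), con)
  invisible(path)
}

#' Read a spike epoch set
#'
#' Spike-set files are tab-separated: `#` header lines record `fs_hz`,
#' `pre_ms`, `post_ms`, `peak_offset` and whether rows carry annotations;
#' each data row is `label <TAB> source_id <TAB> v1 <TAB> ... <TAB> vw`
#' (label and source_id may be `NA`).
#'
#' @param path path to a spike-set file.
#' @return A [spike_set()].
#' @export
read_spikes <- function(path) {
  if (!file.exists(path))
    stop("spike file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grepl("^\\s*#", lines)
  meta <- parse_header(lines[hdr_idx], path)
  for (k in c("fs_hz", "pre_ms", "post_ms"))
    if (is.null(meta[[k]]))
      stop("spike file ", path, " lacks required header '", k, "'",
           call. = FALSE)
  rows <- strsplit(lines[!hdr_idx & !grepl("^\\s*$", lines)], "\t", fixed = TRUE)
  if (length(rows) == 0L)
    stop("spike file ", path, " contains no rows", call. = FALSE)
  labs <- vapply(rows, `[[`, "", 1L)
  srcs <- vapply(rows, `[[`, "", 2L)
  wav <- t(vapply(rows, function(r) as.numeric(r[-(1:2)]),
                  numeric(length(rows[[1L]]) - 2L)))
  if (anyNA(wav))
    stop("non-numeric waveform value in ", path, call. = FALSE)
  fs <- as.numeric(meta$fs_hz)
  spike_set(wav, fs = fs,
            pre_ms = as.numeric(meta$pre_ms),
            post_ms = as.numeric(meta$post_ms),
            peak_offset = if (!is.null(meta$peak_offset))
              as.integer(meta$peak_offset) else round(as.numeric(meta$pre_ms) * fs / 1000),
            labels = if (!all(labs == "NA")) labs,
            source_ids = if (!all(srcs == "NA")) srcs)
}

#' Write a spike epoch set
#'
#' @param spikes a [spike_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_set"))
  hdr <- c(sprintf("# fs_hz=%s", format(spikes$fs, digits = 15)),
           sprintf("# pre_ms=%s", format(spikes$pre_ms, digits = 15)),
           sprintf("# post_ms=%s", format(spikes$post_ms, digits = 15)),
           sprintf("# peak_offset=%d", spikes$peak_offset))
  labs <- if (is.null(spikes$labels)) rep("NA", nrow(spikes$waveforms))
          else as.character(spikes$labels)
  srcs <- if (is.null(spikes$source_ids)) rep("NA", nrow(spikes$waveforms))
          else as.character(spikes$source_ids)
  body <- vapply(seq_len(nrow(spikes$waveforms)), function(i)
    paste(c(labs[i], srcs[i], sprintf("%.15g", spikes$waveforms[i, ])),
          collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

MODEL_FORMAT_VERSION <- "1"

#' Save a trained classifier model
#'
#' Serializes the trained repository of labeled cluster centers — the
#' standardization and PCA parameters, the per-class fuzzy c-means centers
#' and their class labels, and the feature configuration — as versioned
#' JSON. Readers reject files with an unknown format version.
#'
#' @param model a [spiketype()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "spiketype"))
  obj <- list(
    format = "spiketype-model",
    version = MODEL_FORMAT_VERSION,
    feature_config = model$feature_config,
    pca = list(center = model$pca$center, scale = model$pca$scale,
               components = model$pca$components,
               explained_ratio = model$pca$explained_ratio,
               eigenvalues = model$pca$eigenvalues,
               q = model$pca$q, cpv = model$pca$cpv),
    centers = model$centers,
    center_labels = model$center_labels,
    training_summary = as.list(model$training_summary))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a trained classifier model
#'
#' @param path path to a file written by [save_model()].
#' @return A [spiketype()] model.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("model file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (!identical(obj$format, "spiketype-model"))
    stop(path, " is not a spiketype model file", call. = FALSE)
  if (!identical(as.character(obj$version), MODEL_FORMAT_VERSION))
    stop("unsupported model format version '", obj$version,
         "' (supported: ", MODEL_FORMAT_VERSION, ")", call. = FALSE)
  pca <- structure(list(
    center = as.numeric(obj$pca$center), scale = as.numeric(obj$pca$scale),
    components = as.matrix(obj$pca$components),
    explained_ratio = as.numeric(obj$pca$explained_ratio),
    eigenvalues = as.numeric(obj$pca$eigenvalues),
    q = as.integer(obj$pca$q), cpv = as.numeric(obj$pca$cpv)),
    class = "ap_pca")
  ts <- unlist(obj$training_summary)
  structure(list(
    pca = pca,
    centers = as.matrix(obj$centers),
    center_labels = as.character(obj$center_labels),
    feature_config = obj$feature_config,
    training_summary = ts,
    call = NULL),
    class = "spiketype")
}

parse_header <- function(hdr_lines, path) {
  meta <- list()
  for (ln in hdr_lines) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (!grepl("=", body, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", body))
    val <- trimws(sub("^[^=]*=", "", body))
    meta[[key]] <- val
  }
  meta
}
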