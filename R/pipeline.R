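#' Run the full classification pipeline
#'
#' Wires the stages denoise -> detect -> extract -> features ->
#' (train | predict | evaluate) from a single configuration list, logging
#' per-stage record counts. This is the programmatic core behind the
#' command-line interface.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{mode}{`"train"`, `"predict"` or `"evaluate"`.}
#'     \item{traces}{list of [ap_trace()] objects, or `dataset` holding a
#'       [make_dataset()] result.}
#'     \item{model}{(predict mode) a [spiketype()] model or a model file
#'       path.}
#'     \item{feature_kind}{`"dct"` (default), `"ap_shape"` or `"raw"`.}
#'     \item{n_coeff, dct_alpha, dvdt_threshold_v_per_s}{feature options.}
#'     \item{notch, smooth, threshold_mv, min_isi_ms, pre_ms, post_ms}{
#'       stage parameters with the module defaults.}
#'     \item{clusters_per_class, cpv, n_components, fcm_m, fcm_tol,
#'       fcm_max_iter, folds, group_by_neuron, pca_global}{training and
#'       evaluation parameters.}
#'     \item{seed}{integer seed (default 1).}
#'   }
#' @param quiet suppress per-stage log messages?
#' @return Mode `"train"`: a [spiketype()] model. Mode `"predict"`: a data
#'   frame with one row per neuron (`neuron_id`, `label`, `n_spikes`).
#'   Mode `"evaluate"`: an `evaluation_report`. All results carry the
#'   resolved configuration as attribute `config` and the stage counts as
#'   attribute `counts`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- utils::modifyList(list(
    mode = "evaluate", feature_kind = "dct", n_coeff = 100,
    dct_alpha = "ortho", dvdt_threshold_v_per_s = 10,
    notch = TRUE, smooth = TRUE, threshold_mv = -20, min_isi_ms = 2.0,
    pre_ms = 1.0, post_ms = 2.0, clusters_per_class = 2L, cpv = 0.90,
    n_components = NULL, fcm_m = 2.0, fcm_tol = 1e-5, fcm_max_iter = 300L,
    folds = 10L, group_by_neuron = FALSE, pca_global = FALSE, seed = 1L),
    config)
  say <- function(...) if (!quiet) message("[spiketype] ", sprintf(...))

  traces <- if (!is.null(cfg$dataset)) cfg$dataset$traces else cfg$traces
  if (is.null(traces) || length(traces) == 0L)
    stop("pipeline: no input traces", call. = FALSE)
  say("traces read: %d", length(traces))

  sets <- lapply(traces, function(tr) {
    den <- preprocess_trace(tr, notch = cfg$notch, smooth = cfg$smooth)
    mk <- detect_peaks(den, threshold_mv = cfg$threshold_mv,
                       min_isi_ms = cfg$min_isi_ms)
    extract_spikes(den, mk, pre_ms = cfg$pre_ms, post_ms = cfg$post_ms)
  })
  spikes <- combine_spikes(sets)
  n_detected <- nrow(spikes$waveforms) + spikes$n_skipped
  say("spikes detected: %d, extracted: %d, skipped at edges: %d",
      n_detected, nrow(spikes$waveforms), spikes$n_skipped)
  counts <- c(traces = length(traces), spikes_detected = n_detected,
              spikes_extracted = nrow(spikes$waveforms),
              spikes_skipped_at_edges = spikes$n_skipped)

  feats <- switch(cfg$feature_kind,
    dct = dct_features(spikes, n_coeff = cfg$n_coeff, alpha = cfg$dct_alpha),
    ap_shape = ap_shape_features(spikes,
      dvdt_threshold_v_per_s = cfg$dvdt_threshold_v_per_s),
    raw = raw_features(spikes),
    stop("unknown feature_kind '", cfg$feature_kind, "'", call. = FALSE))
  say("feature matrix: %d x %d (%s)", nrow(feats$values),
      ncol(feats$values), feats$kind)

  fc <- list(kind = cfg$feature_kind, n_coeff = cfg$n_coeff,
             alpha = cfg$dct_alpha,
             dvdt_threshold_v_per_s = cfg$dvdt_threshold_v_per_s)
  out <- switch(cfg$mode,
    train = spiketype(feats, clusters_per_class = cfg$clusters_per_class,
                      cpv = cfg$cpv, n_components = cfg$n_components,
                      m = cfg$fcm_m, tol = cfg$fcm_tol,
                      max_iter = cfg$fcm_max_iter, seed = cfg$seed,
                      feature_config = fc),
    predict = {
      model <- cfg$model
      if (is.null(model))
        stop("predict mode needs a 'model' (object or file path)",
             call. = FALSE)
      if (is.character(model)) model <- load_model(model)
      ids <- spikes$source_ids %||% rep("neuron", nrow(spikes$waveforms))
      per <- lapply(unique(ids), function(id) {
        sub <- fm_subset(feats, ids == id)
        lab <- classify_neuron(model, sub)
        data.frame(neuron_id = id, label = as.character(lab),
                   n_spikes = attr(lab, "n_spikes"))
      })
      do.call(rbind, per)
    },
    evaluate = cross_validate(feats, k = cfg$folds,
                              clusters_per_class = cfg$clusters_per_class,
                              cpv = cfg$cpv, n_components = cfg$n_components,
                              m = cfg$fcm_m, tol = cfg$fcm_tol,
                              max_iter = cfg$fcm_max_iter, seed = cfg$seed,
                              group_by = if (cfg$group_by_neuron)
                                spikes$source_ids,
                              pca_global = cfg$pca_global),
    stop("unknown mode '", cfg$mode, "'", call. = FALSE))
  attr(out, "config") <- cfg
  attr(out, "counts") <- counts
  out
}
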