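#' Train a minimum-distance neuron-type classifier
#'
#' Fits the semi-supervised waveform classifier: feature columns are
#' standardized and reduced by correlation-matrix PCA (components retained
#' up to the cumulative-variance threshold `cpv`), fuzzy c-means is then
#' run separately within each labeled class's PC scores, and every
#' resulting cluster center is stored in the model's repository tagged
#' with its class. Prediction assigns each spike the class of the nearest
#' center in Euclidean distance.
#'
#' Running FCM inside each class (rather than globally) keeps the labeling
#' of centers deterministic; `clusters_per_class = 2` accommodates classes
#' whose feature cloud splits into two visible modes, as SST interneurons
#' tend to.
#'
#' @param x a labeled [feature_matrix()], or a numeric matrix with `labels`
#'   supplied.
#' @param labels per-spike class labels (overrides labels stored in `x`).
#' @param clusters_per_class number of FCM centers per class.
#' @param cpv PCA cumulative-variance retention threshold.
#' @param n_components optional fixed PCA dimension overriding `cpv`.
#' @param m,tol,max_iter FCM hyperparameters, see [fcm()].
#' @param seed integer seed for the FCM initializations.
#' @param feature_config optional list recording how the features were
#'   computed (kind, n_coeff, dct alpha, dV/dt threshold); stored verbatim
#'   in the model and used by [save_model()].
#' @return An object of class `spiketype`: list with `pca` ([fit_pca()]
#'   model), `centers` (matrix in PC space), `center_labels`,
#'   `feature_config`, `training_summary` (per-class spike counts), `call`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 5), ncol = 2))
#' fit <- spiketype(x, labels = rep(c("A", "B"), each = 30),
#'                  clusters_per_class = 1, n_components = 2)
#' predict(fit, x[1:3, ])
#' @seealso [predict.spiketype()], [classify_neuron()], [cross_validate()]
#' @export
spiketype <- function(x, labels = NULL, clusters_per_class = 2L,
                      cpv = 0.90, n_components = NULL,
                      m = 2.0, tol = 1e-5, max_iter = 300L, seed = 1L,
                      feature_config = NULL) {
  p <- fm_parts(x, labels)
  if (is.null(p$labels))
    stop("training features must be labeled", call. = FALSE)
  labels <- as.character(p$labels)
  counts <- table(labels)
  short <- counts < clusters_per_class
  if (any(short))
    stop("class '", names(counts)[short][1L], "' has ", counts[short][1L],
         " spikes but clusters_per_class = ", clusters_per_class,
         call. = FALSE)
  if (is.null(feature_config) && !is.null(p$kind))
    feature_config <- list(kind = p$kind)

  pca <- fit_pca(p$values, cpv = cpv, n_components = n_components)
  scores <- apply_pca(pca, p$values)$values

  classes <- sort(unique(labels))
  centers <- NULL
  center_labels <- character(0)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    pts <- scores[labels == cl, , drop = FALSE]
    f <- fcm(pts, c = clusters_per_class, m = m, tol = tol,
             max_iter = max_iter, seed = seed + ci)
    centers <- rbind(centers, f$centers)
    center_labels <- c(center_labels, rep(cl, clusters_per_class))
  }
  structure(list(pca = pca, centers = centers,
                 center_labels = center_labels,
                 feature_config = feature_config,
                 training_summary = c(counts),
                 call = match.call()),
            class = "spiketype")
}

#' @export
print.spiketype <- function(x, ...) {
  cat("Minimum-distance spike-waveform classifier\n")
  cat(sprintf("  classes: %s\n",
              paste(unique(x$center_labels), collapse = ", ")))
  cat(sprintf("  %d centers in %d PC dimensions (CPV %.1f%%)\n",
              nrow(x$centers), ncol(x$centers),
              100 * sum(x$pca$explained_ratio)))
  invisible(x)
}

#' @export
summary.spiketype <- function(object, ...) {
  structure(list(model = object), class = "summary.spiketype")
}

#' @export
print.summary.spiketype <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nTraining spikes per class:\n")
  print(m$training_summary)
  cat("\nPCA explained variance ratio (retained):\n")
  print(round(m$pca$explained_ratio, 4))
  cat("\nCluster centers (PC space):\n")
  ctr <- m$centers
  rownames(ctr) <- make.unique(m$center_labels)
  print(round(ctr, 4))
  invisible(x)
}

#' Classify spikes with a trained model
#'
#' Each spike is standardized and projected with the model's stored PCA
#' (no re-fitting), then assigned the class label of the Euclidean-nearest
#' stored cluster center. Exact distance ties resolve to the
#' earliest-stored center.
#'
#' @param object a [spiketype()] model.
#' @param newdata a [feature_matrix()] or numeric matrix in the model's
#'   original feature space, a `pc_scores` feature matrix already in the
#'   model's PC space, or a [spike_set()] (features are computed according
#'   to the model's `feature_config`).
#' @param type `"class"` for a label vector (with the winning distances as
#'   attribute `distance`), or `"response"` for a data frame with columns
#'   `label` and `distance`.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.spiketype <- function(object, newdata,
                              type = c("class", "response"), ...) {
  type <- match.arg(type)
  scores <- model_scores(object, newdata)
  # squared distances to every center; which.min takes the earliest tie
  d2 <- outer(rowSums(scores^2), rep(1, nrow(object$centers))) +
    outer(rep(1, nrow(scores)), rowSums(object$centers^2)) -
    2 * scores %*% t(object$centers)
  d2 <- pmax(d2, 0)
  win <- apply(d2, 1L, which.min)
  labels <- object$center_labels[win]
  dist <- sqrt(d2[cbind(seq_along(win), win)])
  if (type == "response")
    data.frame(label = labels, distance = dist)
  else
    structure(labels, distance = dist)
}

# Bring any supported input into the model's PC-score space.
model_scores <- function(model, newdata) {
  if (inherits(newdata, "spike_set")) {
    cfg <- model$feature_config
    kind <- if (is.null(cfg$kind)) "dct" else cfg$kind
    newdata <- switch(kind,
      dct = dct_features(newdata,
              n_coeff = cfg$n_coeff %||% 100,
              alpha = cfg$alpha %||% "ortho"),
      ap_shape = ap_shape_features(newdata,
              dvdt_threshold_v_per_s = cfg$dvdt_threshold_v_per_s %||% 10),
      raw = raw_features(newdata),
      stop("model has unknown feature kind '", kind, "'", call. = FALSE))
  }
  p <- fm_parts(newdata)
  if (identical(p$kind, "pc_scores")) {
    if (ncol(p$values) != ncol(model$centers))
      stop("PC-score dimension does not match the model", call. = FALSE)
    return(p$values)
  }
  apply_pca(model$pca, p$values)$values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-spike calls to one label per neuron
#'
#' Majority vote over a neuron's per-spike predictions; vote ties resolve
#' to the tied class with the smaller mean winning distance.
#'
#' @param model a [spiketype()] model.
#' @param spikes a [spike_set()] or [feature_matrix()] holding the spikes
#'   of one neuron (at least one spike).
#' @return A single class label (character), with attributes `votes`
#'   (the per-class vote table) and `n_spikes`.
#' @export
classify_neuron <- function(model, spikes) {
  pred <- predict(model, spikes, type = "response")
  if (nrow(pred) == 0L) stop("no spikes to classify", call. = FALSE)
  votes <- table(pred$label)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    mean_d <- vapply(top, function(cl)
      mean(pred$distance[pred$label == cl]), 0)
    top <- top[which.min(mean_d)]
  }
  structure(top, votes = votes, n_spikes = nrow(pred))
}

#' Plot a trained classifier
#'
#' Scatter of the stored cluster centers in the first two PC dimensions,
#' optionally overlaid on projected spike features.
#'
#' @param x a [spiketype()] model.
#' @param newdata optional features to project and draw behind the centers.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spiketype <- function(x, newdata = NULL, ...) {
  if (ncol(x$centers) < 2L)
    stop("plotting needs at least 2 PC dimensions", call. = FALSE)
  classes <- unique(x$center_labels)
  pal <- grDevices::hcl.colors(max(3L, length(classes)), "Dark 3")
  if (!is.null(newdata)) {
    s <- model_scores(x, newdata)
    lab <- fm_parts(newdata)$labels
    col <- if (!is.null(lab)) pal[match(lab, classes)] else "grey70"
    graphics::plot(s[, 1L], s[, 2L], col = col, pch = 16, cex = 0.4,
                   xlab = "PC1", ylab = "PC2", ...)
  } else {
    graphics::plot(x$centers[, 1L], x$centers[, 2L], type = "n",
                   xlab = "PC1", ylab = "PC2", ...)
  }
  graphics::points(x$centers[, 1L], x$centers[, 2L],
                   pch = 21, cex = 1.6, lwd = 2,
                   bg = pal[match(x$center_labels, classes)])
  graphics::legend("topright", legend = classes, pt.bg = pal[seq_along(classes)],
                   pch = 21, bty = "n")
  invisible(x)
}
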