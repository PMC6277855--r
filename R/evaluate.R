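#' Scatter-matrix class-separability index J3
#'
#' Computes the within-class scatter trace
#' `trace(Sw) = sum_i sum_j ||x_ij - m_i||^2`, the class-size-weighted
#' between-class scatter trace `trace(Sb) = sum_i n_i ||m_i - m||^2`, and
#' `J3 = trace(Sb + Sw) / trace(Sw)`. J3 is at least 1, unbounded above,
#' and invariant under rotation, translation and uniform scaling of the
#' feature space; larger values mean better class separability.
#'
#' Because an orthonormal transform (such as the default DCT) cannot change
#' J3 of the raw values, comparisons between feature representations are
#' only informative after per-column standardization — the form in which
#' the pipeline actually consumes features (correlation-matrix PCA). Set
#' `scale = TRUE` for that comparison.
#'
#' @param x a labeled [feature_matrix()] or numeric matrix.
#' @param labels per-row class labels (overrides labels in `x`).
#' @param scale standardize each column to unit variance (zero-variance
#'   columns are dropped from the index) before computing the scatters?
#' @return An object of class `scatter_summary`: list with `j3`,
#'   `sw_trace`, `sb_trace`, `class_means`, `grand_mean`, `class_sizes`.
#' @examples
#' x <- matrix(c(0, 2, 10, 12))
#' j3_index(x, labels = c("a", "a", "b", "b"))$j3  # 26
#' @export
j3_index <- function(x, labels = NULL, scale = FALSE) {
  p <- fm_parts(x, labels)
  if (is.null(p$labels)) stop("j3_index needs class labels", call. = FALSE)
  X <- p$values
  lab <- as.character(p$labels)
  classes <- sort(unique(lab))
  if (length(classes) < 2L)
    stop("J3 needs at least 2 classes", call. = FALSE)
  if (scale) {
    sdv <- apply(X, 2L, stats::sd)
    keep <- sdv > 0
    X <- sweep(X[, keep, drop = FALSE], 2L, sdv[keep], "/")
  }
  m <- colMeans(X)
  sw <- 0; sb <- 0
  class_means <- matrix(NA_real_, length(classes), ncol(X),
                        dimnames = list(classes, colnames(X)))
  sizes <- integer(length(classes))
  for (i in seq_along(classes)) {
    Xi <- X[lab == classes[i], , drop = FALSE]
    mi <- colMeans(Xi)
    class_means[i, ] <- mi
    sizes[i] <- nrow(Xi)
    sw <- sw + sum(sweep(Xi, 2L, mi, "-")^2)
    sb <- sb + nrow(Xi) * sum((mi - m)^2)
  }
  if (sw <= 0)
    stop("zero within-class scatter: J3 undefined", call. = FALSE)
  structure(list(j3 = (sb + sw) / sw, sw_trace = sw, sb_trace = sb,
                 class_means = class_means, grand_mean = m,
                 class_sizes = stats::setNames(sizes, classes)),
            class = "scatter_summary")
}

#' @export
print.scatter_summary <- function(x, ...) {
  cat(sprintf("<scatter_summary> J3 = %.4g (trace Sb = %.4g, trace Sw = %.4g; %d classes)\n",
              x$j3, x$sb_trace, x$sw_trace, length(x$class_sizes)))
  invisible(x)
}

#' Confusion matrix
#'
#' @param true,predicted class labels of equal length.
#' @param classes label order; defaults to the sorted union.
#' @return An object of class `confusion_matrix`: an integer matrix with
#'   rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(true, predicted,
                             classes = sort(unique(c(true, predicted)))) {
  stopifnot(length(true) == length(predicted))
  m <- table(factor(true, levels = classes),
             factor(predicted, levels = classes))
  structure(unclass(m), class = "confusion_matrix", class_order = classes)
}

#' Per-class and overall classification metrics
#'
#' One-vs-rest counts per class: precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, accuracy `(TP + TN) / (TP + FP + TN + FN)`. The
#' overall values are unweighted means over classes. A class never
#' predicted (`TP + FP = 0`) has undefined precision, reported as `NA` and
#' excluded from the macro mean with a warning.
#'
#' @param cm a [confusion_matrix()] (or plain square count matrix with
#'   rows = true class).
#' @return List with `per_class` (data frame: class, precision, recall,
#'   accuracy) and `overall` (named vector of macro precision, recall,
#'   accuracy).
#' @export
class_metrics <- function(cm) {
  m <- unclass(as.matrix(cm))
  if (sum(m) == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- attr(cm, "class_order") %||% rownames(m) %||%
    as.character(seq_len(nrow(m)))
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- sum(m) - tp - fp - fn
  pr <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rl <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  acc <- (tp + tn) / sum(m)
  if (anyNA(pr))
    warning("precision undefined for never-predicted class(es): ",
            paste(classes[is.na(pr)], collapse = ", "),
            "; excluded from the macro mean", call. = FALSE)
  list(per_class = data.frame(class = classes, precision = pr,
                              recall = rl, accuracy = acc,
                              row.names = NULL),
       overall = c(precision = mean(pr, na.rm = TRUE),
                   recall = mean(rl, na.rm = TRUE),
                   accuracy = mean(acc, na.rm = TRUE)))
}

#' Cross-validated evaluation of the waveform classifier
#'
#' Splits the labeled spikes into `k` near-equal parts (class-stratified at
#' the spike level by default, or grouped so that all spikes of one neuron
#' stay in the same fold when `group_by` is supplied). In every fold the
#' standardization, PCA and per-class FCM centers are fit on the k-1
#' training parts only and the held-out part is classified; set
#' `pca_global = TRUE` to instead fit the PCA once on all data (the laxer
#' protocol). Metrics are aggregated as mean and standard error over folds.
#'
#' @param x labeled [feature_matrix()] or matrix with `labels`.
#' @param labels per-spike labels (overrides labels in `x`).
#' @param k number of folds; every class must have at least `k` spikes.
#' @param clusters_per_class,cpv,n_components,m,tol,max_iter,seed passed to
#'   [spiketype()]; `seed` also fixes the fold assignment.
#' @param group_by optional per-spike grouping id (e.g. neuron); folds then
#'   partition groups, not spikes.
#' @param pca_global fit PCA on the full data instead of per fold?
#' @return An object of class `evaluation_report`: list with `per_fold`
#'   (confusion matrices), `per_class` (data frame of mean and SEM of
#'   precision/recall/accuracy), `overall` (macro mean and SEM), `correct`
#'   (per-spike correctness, data order), `fold` (per-spike fold id),
#'   `seed`, `config`.
#' @export
cross_validate <- function(x, labels = NULL, k = 10L,
                           clusters_per_class = 2L, cpv = 0.90,
                           n_components = NULL, m = 2.0, tol = 1e-5,
                           max_iter = 300L, seed = 1L,
                           group_by = NULL, pca_global = FALSE) {
  p <- fm_parts(x, labels)
  if (is.null(p$labels)) stop("cross_validate needs labels", call. = FALSE)
  lab <- as.character(p$labels)
  n <- nrow(p$values)
  classes <- sort(unique(lab))

  fold <- integer(n)
  if (is.null(group_by)) {
    counts <- table(lab)
    if (any(counts < k))
      stop("class '", names(counts)[counts < k][1L],
           "' has fewer spikes than folds (", k, ")", call. = FALSE)
    fold <- with_seed(seed, {
      f <- integer(n)
      for (cl in classes) {
        idx <- which(lab == cl)
        f[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
  } else {
    stopifnot(length(group_by) == n)
    groups <- unique(group_by)
    if (length(groups) < k)
      stop("fewer groups (", length(groups), ") than folds (", k, ")",
           call. = FALSE)
    gf <- with_seed(seed, rep_len(seq_len(k), length(groups))[
      sample.int(length(groups))])
    fold <- gf[match(group_by, groups)]
  }

  fc <- if (inherits(x, "feature_matrix"))
    list(kind = x$kind) else NULL
  global_pca <- if (pca_global)
    fit_pca(p$values, cpv = cpv, n_components = n_components)

  per_fold <- vector("list", k)
  correct <- logical(n)
  predicted <- character(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    xtr <- p$values[tr, , drop = FALSE]
    if (pca_global) {
      str <- apply_pca(global_pca, xtr)
      fit <- spiketype(str$values, labels = lab[tr],
                       clusters_per_class = clusters_per_class,
                       n_components = ncol(str$values),
                       m = m, tol = tol, max_iter = max_iter,
                       seed = seed + f, feature_config = fc)
      scores_te <- apply_pca(global_pca, p$values[te, , drop = FALSE])
      pred <- predict(fit, scores_te$values)
    } else {
      fit <- spiketype(xtr, labels = lab[tr],
                       clusters_per_class = clusters_per_class,
                       cpv = cpv, n_components = n_components,
                       m = m, tol = tol, max_iter = max_iter,
                       seed = seed + f, feature_config = fc)
      pred <- predict(fit, p$values[te, , drop = FALSE])
    }
    predicted[te] <- as.character(pred)
    correct[te] <- predicted[te] == lab[te]
    per_fold[[f]] <- confusion_matrix(lab[te], predicted[te],
                                      classes = classes)
  }

  fold_metrics <- lapply(per_fold, function(cm)
    suppressWarnings(class_metrics(cm)))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  agg <- function(get) {
    vals <- t(vapply(fold_metrics, get, numeric(3)))
    c(mean = colMeans(vals, na.rm = TRUE),
      sem = apply(vals, 2L, function(col) sem(col[!is.na(col)])))
  }
  per_class <- do.call(rbind, lapply(seq_along(classes), function(i) {
    vals <- agg(function(fm) unlist(fm$per_class[i, c("precision", "recall",
                                                      "accuracy")]))
    data.frame(class = classes[i],
               precision = vals[["mean.precision"]],
               precision_sem = vals[["sem.precision"]],
               recall = vals[["mean.recall"]],
               recall_sem = vals[["sem.recall"]],
               accuracy = vals[["mean.accuracy"]],
               accuracy_sem = vals[["sem.accuracy"]],
               row.names = NULL)
  }))
  ov <- agg(function(fm) fm$overall)
  overall <- data.frame(
    precision = ov[["mean.precision"]], precision_sem = ov[["sem.precision"]],
    recall = ov[["mean.recall"]], recall_sem = ov[["sem.recall"]],
    accuracy = ov[["mean.accuracy"]], accuracy_sem = ov[["sem.accuracy"]])

  structure(list(per_fold = per_fold, per_class = per_class,
                 overall = overall, correct = correct,
                 predicted = predicted, fold = fold, seed = seed,
                 config = list(k = k, clusters_per_class = clusters_per_class,
                               cpv = cpv, n_components = n_components,
                               m = m, tol = tol, max_iter = max_iter,
                               pca_global = pca_global,
                               grouped = !is.null(group_by))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$config$k, x$seed))
  ov <- x$overall
  cat(sprintf("  overall: accuracy %.2f +/- %.2f%%, precision %.2f +/- %.2f%%, recall %.2f +/- %.2f%%\n",
              100 * ov$accuracy, 100 * ov$accuracy_sem,
              100 * ov$precision, 100 * ov$precision_sem,
              100 * ov$recall, 100 * ov$recall_sem))
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-6s accuracy %.2f +/- %.2f%%, precision %.2f +/- %.2f%%, recall %.2f +/- %.2f%%\n",
                pc$class[i],
                100 * pc$accuracy[i], 100 * pc$accuracy_sem[i],
                100 * pc$precision[i], 100 * pc$precision_sem[i],
                100 * pc$recall[i], 100 * pc$recall_sem[i]))
  invisible(x)
}

#' McNemar's test for two paired classifiers
#'
#' Continuity-corrected McNemar statistic
#' `(|b - c| - 1)^2 / (b + c)` on the discordant counts b (A correct, B
#' wrong) and c (A wrong, B correct), referred to chi-squared with 1 df.
#'
#' @param correct_a,correct_b logical vectors of per-item correctness for
#'   the two classifiers, same items in the same order.
#' @return List with `statistic`, `p_value`, `b`, `c`. When `b + c = 0`
#'   the statistic is undefined (`NA`) and `p_value = 1`, with a warning.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  a <- as.logical(correct_a); bb <- as.logical(correct_b)
  b <- sum(a & !bb)
  cc <- sum(!a & bb)
  if (b + cc == 0L) {
    warning("no discordant pairs: McNemar statistic undefined",
            call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, b = b, c = cc))
  }
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = cc)
}

#' Cochran's Q test for several paired classifiers
#'
#' Tests whether `k >= 3` classifiers evaluated on the same items have
#' equal marginal correctness rates. `Q = (k-1) (k sum_j C_j^2 - T^2) /
#' (k T - sum_i R_i^2)` with column totals `C_j`, row totals `R_i` and
#' grand total `T`, referred to chi-squared with `k - 1` df.
#'
#' @param correctness logical (or 0/1) matrix, items x classifiers.
#' @return List with `statistic`, `p_value`, `df`. When every item is
#'   answered identically by all classifiers the statistic is undefined
#'   (`NA`) and `p_value = 1`, with a warning.
#' @export
cochran_q <- function(correctness) {
  X <- as.matrix(correctness) * 1
  k <- ncol(X)
  if (k < 3L) stop("Cochran's Q needs at least 3 classifiers", call. = FALSE)
  Cj <- colSums(X)
  Ri <- rowSums(X)
  T0 <- sum(X)
  denom <- k * T0 - sum(Ri^2)
  if (denom <= 0) {
    warning("all rows constant: Cochran's Q undefined", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, df = k - 1L))
  }
  Q <- (k - 1) * (k * sum(Cj^2) - T0^2) / denom
  list(statistic = Q,
       p_value = stats::pchisq(Q, df = k - 1L, lower.tail = FALSE),
       df = k - 1L)
}

#' Bonferroni correction
#'
#' Adjusts p-values for multiple comparisons: `p_adj = min(1, p * m)`.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values (via [stats::p.adjust()]).
#' @export
bonferroni <- function(p) {
  if (length(p) < 1L) stop("no p-values supplied", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni")
}
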