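#' Discrete cosine transform (DCT-II)
#'
#' Computes `v(k) = alpha(k) * sum_n u(n) * cos((2n+1) pi k / (2N))` for
#' `k = 0..N-1`. Two normalizations are supported: the standard orthonormal
#' convention `alpha(0) = sqrt(1/N)`, `alpha(k>=1) = sqrt(2/N)` (the
#' default, which makes the transform an orthogonal map satisfying
#' Parseval's identity), and a `"literal"` variant
#' `alpha(k) = sqrt((k+1)/N)` that progressively amplifies higher-order
#' coefficients and is not energy-preserving. The two agree for k = 0 and
#' k = 1.
#'
#' @param u numeric vector of length N >= 1.
#' @param alpha normalization convention, `"ortho"` or `"literal"`.
#' @return Numeric vector of N coefficients `v(0)..v(N-1)`.
#' @examples
#' dct_ii(rep(1, 100))[1]   # 10: the DC coefficient of a constant
#' @export
dct_ii <- function(u, alpha = c("ortho", "literal")) {
  alpha <- match.arg(alpha)
  if (length(u) < 1L) stop("dct input must be non-empty", call. = FALSE)
  drop(dct_matrix(length(u), alpha) %*% as.numeric(u))
}

# N x N DCT-II matrix, rows indexed by k = 0..N-1.
dct_matrix <- function(N, alpha = "ortho") {
  k <- 0:(N - 1L)
  n <- 0:(N - 1L)
  C <- cos(outer(k, 2 * n + 1) * pi / (2 * N))
  a <- if (alpha == "literal") sqrt((k + 1) / N)
       else c(sqrt(1 / N), rep(sqrt(2 / N), N - 1L))
  C * a
}

#' DCT feature matrix of a spike set
#'
#' Zero-pads each spike epoch at the tail (post-spike side, preserving the
#' pre-peak alignment) to `n_coeff` samples and transforms it with
#' [dct_ii()]. The raw mV values are transformed without baseline
#' subtraction: threshold-level differences between cell types are
#' themselves informative. With 60-sample epochs and the default
#' `n_coeff = 100` every spike yields the coefficients `v(0)..v(99)`.
#'
#' @param spikes a [spike_set()].
#' @param n_coeff number of DCT coefficients (and padded length).
#' @param alpha normalization convention, see [dct_ii()].
#' @return A [feature_matrix()] of kind `"dct"` with columns `v0..v<n-1>`,
#'   carrying the spike set's labels and source ids.
#' @export
dct_features <- function(spikes, n_coeff = 100, alpha = c("ortho", "literal")) {
  stopifnot(inherits(spikes, "spike_set"))
  alpha <- match.arg(alpha)
  w <- ncol(spikes$waveforms)
  if (w > n_coeff)
    stop(sprintf("spike rows (%d samples) are longer than n_coeff = %d",
                 w, n_coeff), call. = FALSE)
  padded <- cbind(spikes$waveforms,
                  matrix(0, nrow(spikes$waveforms), n_coeff - w))
  vals <- padded %*% t(dct_matrix(n_coeff, alpha))
  colnames(vals) <- paste0("v", 0:(n_coeff - 1L))
  feature_matrix(vals, kind = "dct",
                 labels = spikes$labels, source_ids = spikes$source_ids)
}

#' Raw-waveform feature matrix
#'
#' Uses the epoch samples themselves as the feature vector (for baseline
#' comparisons against transformed features).
#'
#' @param spikes a [spike_set()].
#' @return A [feature_matrix()] of kind `"raw"`.
#' @export
raw_features <- function(spikes) {
  stopifnot(inherits(spikes, "spike_set"))
  vals <- spikes$waveforms
  colnames(vals) <- paste0("s", seq_len(ncol(vals)) - 1L)
  feature_matrix(vals, kind = "raw",
                 labels = spikes$labels, source_ids = spikes$source_ids)
}

#' Action-potential shape features
#'
#' Measures seven morphometric variables on each spike epoch:
#' \describe{
#'   \item{apt_mv}{AP threshold: voltage at the first pre-peak sample where
#'     dV/dt reaches `dvdt_threshold_v_per_s` (central differences).}
#'   \item{apd_ms}{AP duration: full width at half amplitude, i.e. at the
#'     level APT + A/2 where A = V_peak - APT; crossings are located with
#'     sub-sample linear interpolation.}
#'   \item{ahp_mv}{Afterhyperpolarization: APT minus the post-peak minimum,
#'     floored at 0.}
#'   \item{rt_ms}{Rise time, 10\% to 90\% of A on the rising phase.}
#'   \item{ft_ms}{Fall time, 90\% to 10\% of A on the falling phase.}
#'   \item{rr_v_per_s}{Rise rate: maximum dV/dt.}
#'   \item{fr_v_per_s}{Fall rate: |minimum dV/dt|.}
#' }
#' Spikes on which a definition fails (e.g. no dV/dt crossing before the
#' peak) are reported and dropped with a warning; an all-invalid set is an
#' error.
#'
#' @param spikes a [spike_set()]; each row must contain exactly one AP with
#'   its maximum at the set's `peak_offset`.
#' @param dvdt_threshold_v_per_s threshold-detection slope criterion (V/s).
#' @return A [feature_matrix()] of kind `"ap_shape"` with 7 columns and an
#'   attribute `n_invalid` on the `values` matrix counting dropped spikes.
#' @export
ap_shape_features <- function(spikes, dvdt_threshold_v_per_s = 10) {
  stopifnot(inherits(spikes, "spike_set"))
  n <- nrow(spikes$waveforms)
  if (n == 0L) stop("empty spike set", call. = FALSE)
  out <- matrix(NA_real_, n, 7L)
  colnames(out) <- c("apt_mv", "apd_ms", "ahp_mv", "rt_ms", "ft_ms",
                     "rr_v_per_s", "fr_v_per_s")
  pk <- spikes$peak_offset + 1L   # 1-based peak index
  for (i in seq_len(n))
    out[i, ] <- ap_shape_one(spikes$waveforms[i, ], pk, spikes$fs,
                             dvdt_threshold_v_per_s)
  bad <- !stats::complete.cases(out)
  if (all(bad))
    stop("no spike yielded a valid shape-feature vector", call. = FALSE)
  if (any(bad))
    warning(sum(bad), " of ", n,
            " spikes had undefined shape features and were dropped",
            call. = FALSE)
  fm <- feature_matrix(out[!bad, , drop = FALSE], kind = "ap_shape",
                       labels = if (!is.null(spikes$labels)) spikes$labels[!bad],
                       source_ids = if (!is.null(spikes$source_ids))
                         spikes$source_ids[!bad])
  fm$kept_rows <- which(!bad)   # original spike indices of the retained rows
  fm
}

# One spike's 7 features; NA-filled vector if a definition fails.
ap_shape_one <- function(v, pk, fs, dvdt_thr) {
  n <- length(v)
  invalid <- rep(NA_real_, 7L)
  if (pk < 3L || pk > n - 2L) return(invalid)
  # dV/dt in V/s (= mV/ms): central differences, one-sided at the ends
  dv <- c(v[2L] - v[1L],
          (v[3:n] - v[1:(n - 2L)]) / 2,
          v[n] - v[n - 1L]) * fs / 1000
  apt_i <- which(dv[1:pk] >= dvdt_thr)
  if (!length(apt_i)) return(invalid)
  apt_i <- apt_i[1L]
  apt <- v[apt_i]
  A <- v[pk] - apt
  if (A <= 0) return(invalid)

  rise_t <- function(level) {   # interpolated crossing time before the peak
    below <- which(v[1:(pk - 1L)] <= level)
    if (!length(below)) return(NA_real_)
    i <- below[length(below)]
    if (v[i + 1L] == v[i]) return(i)
    i + (level - v[i]) / (v[i + 1L] - v[i])
  }
  fall_t <- function(level) {   # interpolated crossing time after the peak
    below <- which(v[pk:n] <= level)
    if (!length(below)) return(NA_real_)
    i <- pk + below[1L] - 1L
    if (i == pk || v[i - 1L] == v[i]) return(i)
    (i - 1L) + (v[i - 1L] - level) / (v[i - 1L] - v[i])
  }

  half <- apt + A / 2
  t_r50 <- rise_t(half); t_f50 <- fall_t(half)
  t_r10 <- rise_t(apt + 0.1 * A); t_r90 <- rise_t(apt + 0.9 * A)
  t_f90 <- fall_t(apt + 0.9 * A); t_f10 <- fall_t(apt + 0.1 * A)
  if (anyNA(c(t_r50, t_f50, t_r10, t_r90, t_f90, t_f10))) return(invalid)

  ms <- 1000 / fs
  c(apt_mv = apt,
    apd_ms = (t_f50 - t_r50) * ms,
    ahp_mv = max(0, apt - min(v[(pk + 1L):n])),
    rt_ms = (t_r90 - t_r10) * ms,
    ft_ms = (t_f10 - t_f90) * ms,
    rr_v_per_s = max(dv),
    fr_v_per_s = abs(min(dv)))
}

#' Correlation-matrix principal component analysis
#'
#' Standardizes each feature column by its training mean and standard
#' deviation and eigendecomposes the resulting correlation matrix. The
#' smallest number of components whose cumulative proportion of variance
#' reaches `cpv` is retained (default 90\%), unless `n_components`
#' overrides the rule. Each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x a [feature_matrix()] or numeric matrix (rows = spikes).
#' @param cpv cumulative-proportion-of-variance retention threshold in
#'   (0, 1].
#' @param n_components optional fixed number of components, overriding the
#'   CPV rule.
#' @return An object of class `ap_pca`: list with `center`, `scale`,
#'   `components` (d x q loadings), `explained_ratio` (length q),
#'   `eigenvalues` (all d, which sum to d), `q`, `cpv`.
#' @export
fit_pca <- function(x, cpv = 0.90, n_components = NULL) {
  p <- fm_parts(x)
  X <- p$values
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  cen <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  zero_var <- sc <= 0 | !is.finite(sc)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance column(s); scale set to 1",
            call. = FALSE)
    sc[zero_var] <- 1
  }
  Z <- sweep(sweep(X, 2L, cen, "-"), 2L, sc, "/")
  R <- crossprod(Z) / (nrow(Z) - 1L)
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  d <- ncol(X)
  ratio <- vals / d
  q <- if (!is.null(n_components)) {
    as.integer(n_components)
  } else {
    cum <- cumsum(ratio)
    as.integer(which(cum >= cpv - 1e-12)[1L])
  }
  if (is.na(q) || q < 1L || q > d)
    stop("invalid number of retained components", call. = FALSE)
  comp <- e$vectors[, seq_len(q), drop = FALSE]
  for (j in seq_len(q)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  rownames(comp) <- colnames(X)
  structure(list(center = cen, scale = sc, components = comp,
                 explained_ratio = ratio[seq_len(q)],
                 eigenvalues = vals, q = q, cpv = cpv),
            class = "ap_pca")
}

#' @export
print.ap_pca <- function(x, ...) {
  cat(sprintf("<ap_pca> %d features -> %d components (CPV %.1f%% at threshold %g%%)\n",
              length(x$center), x$q, 100 * sum(x$explained_ratio),
              100 * x$cpv))
  invisible(x)
}

#' Project features onto a fitted PCA model
#'
#' Standardizes `x` with the model's stored training mean and standard
#' deviation (no re-fitting) and projects onto the retained components.
#'
#' @param model an `ap_pca` model from [fit_pca()].
#' @param x a [feature_matrix()] or numeric matrix with the model's
#'   feature dimension.
#' @return A [feature_matrix()] of kind `"pc_scores"` with `q` columns
#'   `PC1..PCq`, carrying labels/source ids when `x` had them.
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "ap_pca"))
  p <- fm_parts(x)
  if (ncol(p$values) != length(model$center))
    stop(sprintf("feature dimension %d does not match the PCA model (%d)",
                 ncol(p$values), length(model$center)), call. = FALSE)
  Z <- sweep(sweep(p$values, 2L, model$center, "-"), 2L, model$scale, "/")
  S <- Z %*% model$components
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  feature_matrix(S, kind = "pc_scores",
                 labels = p$labels, source_ids = p$source_ids)
}
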