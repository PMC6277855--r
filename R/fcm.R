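#' Fuzzy c-means clustering
#'
#' Standard FCM alternating optimization: memberships
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))` followed by centers as
#' `u^m`-weighted means, iterated until the largest center displacement
#' falls below `tol` or `max_iter` is reached. Initial centers are `c`
#' distinct data points sampled under `seed`, making a run fully
#' reproducible. A point coinciding exactly with a center receives full
#' membership in (the earliest of) those centers.
#'
#' @param x numeric matrix or [feature_matrix()], rows = points.
#' @param c number of clusters, `1 <= c <= n`.
#' @param m fuzzifier, > 1.
#' @param tol convergence tolerance on the maximum center displacement.
#' @param max_iter iteration cap.
#' @param seed integer seed for the center initialization (`NULL` leaves
#'   the RNG state alone).
#' @return An object of class `fcm`: list with `centers` (c x d),
#'   `membership` (n x c, rows summing to 1), `objective_trace`
#'   (per-iteration objective, non-increasing), `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100, 0, .5), ncol = 2),
#'            matrix(rnorm(100, 10, .5), ncol = 2))
#' f <- fcm(x, c = 2, seed = 1)
#' round(f$centers)
#' @export
fcm <- function(x, c, m = 2.0, tol = 1e-5, max_iter = 300L, seed = NULL) {
  X <- fm_parts(x)$values
  n <- nrow(X)
  if (c > n) stop("more clusters (", c, ") than points (", n, ")",
                  call. = FALSE)
  if (c < 1L) stop("c must be >= 1", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)

  init_idx <- with_seed(seed, sample.int(n, c))
  centers <- X[init_idx, , drop = FALSE]

  sq_dist <- function(ctr) {
    # n x c matrix of squared Euclidean distances
    d2 <- outer(rowSums(X^2), rep(1, nrow(ctr))) +
      outer(rep(1, n), rowSums(ctr^2)) - 2 * X %*% t(ctr)
    pmax(d2, 0)
  }

  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  expo <- 1 / (m - 1)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(centers)
    zero <- d2 < .Machine$double.eps
    u <- (1 / pmax(d2, .Machine$double.xmin))^expo
    u <- u / rowSums(u)
    hit <- rowSums(zero) > 0L
    if (any(hit)) {           # exact coincidence: all mass on earliest hit
      u[hit, ] <- 0
      u[cbind(which(hit), max.col(zero[hit, , drop = FALSE], "first"))] <- 1
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    new_centers <- crossprod(um, X) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  dimnames(centers) <- list(NULL, colnames(X))
  structure(list(centers = centers, membership = u,
                 objective_trace = obj, iterations = iter,
                 converged = converged),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("<fcm> %d centers in %d dims; %d iterations (%s), objective %.6g\n",
              nrow(x$centers), ncol(x$centers), x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

# Run expr under a temporary RNG state seeded with `seed`; restore the
# caller's state afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
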