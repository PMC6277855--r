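test_that("FCM satisfies its algebraic invariants on random data", {
  set.seed(51)
  for (rep in 1:3) {
    x <- matrix(rnorm(60 * 3), 60, 3)
    f <- fcm(x, c = 4, seed = rep)
    expect_equal(rowSums(f$membership), rep(1, 60), tolerance = 1e-9)
    expect_true(all(f$membership >= 0 & f$membership <= 1))
    expect_true(all(diff(f$objective_trace) <= 1e-9))
  }
})

test_that("FCM with one cluster reduces to the arithmetic mean", {
  set.seed(52)
  x <- matrix(rnorm(100), 50, 2)
  f <- fcm(x, c = 1, seed = 1)
  expect_equal(f$centers[1, ], colMeans(x), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(f$membership == 1))
})

test_that("FCM recovers the centers of two separated blobs", {
  blobs <- two_blobs(n_per = 100, sd = 0.5, seed = 53)
  truth <- rbind(colMeans(blobs$x[1:100, ]), colMeans(blobs$x[101:200, ]))
  f <- fcm(blobs$x, c = 2, seed = 3)
  # match centers to the nearer truth row
  d <- as.matrix(dist(rbind(f$centers, truth)))[1:2, 3:4]
  perm <- unname(apply(d, 1, which.min))
  expect_identical(sort(perm), 1:2)
  expect_lt(max(d[cbind(1:2, perm)]), 0.2)
  expect_true(f$converged)
  # identical seed, identical run
  f2 <- fcm(blobs$x, c = 2, seed = 3)
  expect_identical(f$centers, f2$centers)
})

test_that("FCM agrees with an independent implementation on blob data", {
  skip_if_not_installed("e1071")
  blobs <- two_blobs(n_per = 100, sd = 0.5, seed = 54)
  f <- fcm(blobs$x, c = 2, seed = 1, tol = 1e-8)
  set.seed(1)
  ref <- e1071::cmeans(blobs$x, centers = 2, m = 2)
  ours <- f$centers[order(f$centers[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(ours, theirs, tolerance = 1e-2, ignore_attr = TRUE)
  expect_error(fcm(blobs$x[1:3, ], c = 5), "more clusters")
})

test_that("training requires labels and enough spikes per class", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(spiketype(x), "label")
  expect_error(
    spiketype(x, labels = c(rep("A", 19), "B"), clusters_per_class = 2,
              n_components = 2),
    "'B' has 1 spikes")
})

test_that("one cluster per class stores the class PC-score centroids", {
  blobs <- two_blobs(n_per = 50, centers = rbind(c(0, 0), c(8, 2)), seed = 55)
  lab <- c("lo", "hi")[blobs$labels]
  fit <- spiketype(blobs$x, labels = lab, clusters_per_class = 1,
                   n_components = 2)
  scores <- apply_pca(fit$pca, blobs$x)$values
  for (cl in c("hi", "lo")) {
    i <- which(fit$center_labels == cl)
    expect_equal(fit$centers[i, ], colMeans(scores[lab == cl, ]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # and prediction then equals a nearest-class-centroid classifier
  set.seed(56)
  q <- matrix(rnorm(400, 4, 3), 200, 2)
  qs <- apply_pca(fit$pca, q)$values
  d_lo <- colSums((t(qs) - fit$centers[fit$center_labels == "lo", ])^2)
  d_hi <- colSums((t(qs) - fit$centers[fit$center_labels == "hi", ])^2)
  expect_identical(as.character(predict(fit, q)),
                   ifelse(d_lo <= d_hi, "lo", "hi"))
})

test_that("classification matches exhaustive nearest-center search", {
  set.seed(57)
  centers <- matrix(rnorm(12, sd = 3), 6, 2)
  fake <- structure(list(
    pca = structure(list(center = c(0, 0), scale = c(1, 1),
                         components = diag(2), explained_ratio = c(.5, .5),
                         eigenvalues = c(1, 1), q = 2L, cpv = 0.9),
                    class = "ap_pca"),
    centers = centers,
    center_labels = paste0("C", 1:6),
    feature_config = NULL, training_summary = NULL, call = NULL),
    class = "spiketype")
  pts <- matrix(rnorm(2000, sd = 3), 1000, 2)
  pred <- predict(fake, pts, type = "response")
  oracle <- apply(pts, 1, function(p) {
    d <- sqrt(colSums((t(centers) - p)^2))
    c(which.min(d), min(d))
  })
  expect_identical(pred$label, paste0("C", oracle[1, ]))
  expect_equal(pred$distance, oracle[2, ], tolerance = 1e-9)

  # a point exactly at a stored center
  at <- predict(fake, centers[4, , drop = FALSE], type = "response")
  expect_identical(at$label, "C4")
  expect_equal(at$distance, 0)

  # equidistant query resolves to the earlier-stored center
  tie <- structure(list(
    pca = fake$pca, centers = rbind(c(0, 0), c(2, 0)),
    center_labels = c("A", "B"), feature_config = NULL,
    training_summary = NULL, call = NULL), class = "spiketype")
  expect_identical(as.character(predict(tie, matrix(c(1, 0), 1))), "A")

  # invariant to center re-ordering away from ties
  perm <- c(3, 1, 6, 2, 5, 4)
  fake2 <- fake
  fake2$centers <- centers[perm, ]
  fake2$center_labels <- fake$center_labels[perm]
  expect_identical(predict(fake2, pts, type = "response")$label,
                   pred$label)
  expect_error(predict(fake, pts[, 1, drop = FALSE]), "dimension")
})

test_that("a well-separated 3-class training set is memorized almost perfectly", {
  blobs <- two_blobs(n_per = 80,
                     centers = rbind(c(0, 0), c(12, 0), c(0, 12)),
                     sd = 0.6, seed = 58)
  lab <- c("PV", "SST", "Pyr")[blobs$labels]
  fit <- spiketype(blobs$x, labels = lab, clusters_per_class = 2,
                   n_components = 2, seed = 2)
  acc <- mean(as.character(predict(fit, blobs$x)) == lab)
  expect_gte(acc, 0.99)

  # the noisy spike fixture still resubstitutes well
  fm <- dct_features(small_spikes())
  fit2 <- spiketype(fm, seed = 2)
  expect_gte(mean(as.character(predict(fit2, fm)) == fm$labels), 0.9)
})

test_that("neuron-level calls use majority vote with distance tie-breaks", {
  fake <- structure(list(
    pca = structure(list(center = c(0, 0), scale = c(1, 1),
                         components = diag(2), explained_ratio = c(.5, .5),
                         eigenvalues = c(1, 1), q = 2L, cpv = 0.9),
                    class = "ap_pca"),
    centers = rbind(c(0, 0), c(10, 0)),
    center_labels = c("PV", "SST"), feature_config = NULL,
    training_summary = NULL, call = NULL), class = "spiketype")
  # unanimity
  near_pv <- matrix(rnorm(20, 0, .1), 10, 2)
  expect_identical(as.character(classify_neuron(fake, near_pv)), "PV")
  # 6/4 majority
  mixed <- rbind(matrix(rnorm(12, 0, .1), 6, 2),
                 matrix(rnorm(8, 10, .1), 4, 2) - c(0, 0))
  mixed[7:10, 1] <- 10
  expect_identical(as.character(classify_neuron(fake, mixed)), "PV")
  # 5/5 vote tie: SST spikes sit closer to their center
  tie <- rbind(cbind(rep(3, 5), 0),     # PV side, distance 3
               cbind(rep(9, 5), 0))     # SST side, distance 1
  expect_identical(as.character(classify_neuron(fake, tie)), "SST")
})
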