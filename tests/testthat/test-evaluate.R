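test_that("J3 reproduces the hand-computed 1-D example and its limits", {
  # classes {0,2} and {10,12}: trace(Sw) = 4, trace(Sb) = 100, J3 = 26
  s <- j3_index(matrix(c(0, 2, 10, 12)), labels = c("a", "a", "b", "b"))
  expect_equal(s$sw_trace, 4)
  expect_equal(s$sb_trace, 100)
  expect_equal(s$j3, 26)

  # identical class means: Sb = 0, J3 = 1
  x <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  s0 <- j3_index(x, labels = c("a", "a", "b", "b"))
  expect_equal(s0$sb_trace, 0)
  expect_equal(s0$j3, 1)

  expect_error(j3_index(x, labels = rep("a", 4)), "2 classes")
  expect_error(j3_index(matrix(c(1, 1, 2, 2)),
                        labels = c("a", "a", "b", "b")),
               "zero within-class scatter")
})

test_that("J3 grows monotonically as one class mean moves away", {
  set.seed(61)
  base <- matrix(rnorm(200), 100, 2)
  lab <- rep(c("a", "b"), each = 50)
  j <- vapply(seq(0, 10, by = 2), function(shift) {
    x <- base
    x[lab == "b", 1] <- x[lab == "b", 1] + shift
    j3_index(x, labels = lab)$j3
  }, 0)
  expect_true(all(diff(j) > 0))
})

test_that("J3 is invariant under rotation, translation and uniform scaling", {
  set.seed(62)
  x <- cbind(rnorm(80), rnorm(80), rnorm(80))
  x[41:80, ] <- x[41:80, ] + 3
  lab <- rep(c("a", "b"), each = 40)
  j0 <- j3_index(x, labels = lab)$j3
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(j3_index(x %*% R, labels = lab)$j3, j0, tolerance = 1e-9)
  expect_equal(j3_index(sweep(x, 2, c(5, -3, 100), "+"), labels = lab)$j3,
               j0, tolerance = 1e-9)
  expect_equal(j3_index(2.5 * x, labels = lab)$j3, j0, tolerance = 1e-9)
})

test_that("class metrics match hand-computed one-vs-rest counts", {
  cm <- structure(rbind(c(8, 1, 0), c(2, 9, 1), c(0, 0, 9)),
                  class = "confusion_matrix", class_order = c("A", "B", "C"))
  m <- class_metrics(cm)
  expect_equal(m$per_class$precision[1], 0.8)
  expect_equal(m$per_class$recall[1], 8 / 9)
  expect_equal(m$per_class$accuracy[1], 0.9)

  # perfect diagonal
  perfect <- confusion_matrix(rep(c("x", "y"), 5), rep(c("x", "y"), 5))
  mp <- class_metrics(perfect)
  expect_equal(unname(mp$overall), c(1, 1, 1))

  # macro averages sit between per-class extremes; accuracy identity holds
  set.seed(63)
  r <- matrix(rpois(9, 10), 3, 3)
  rownames(r) <- colnames(r) <- c("a", "b", "c")
  mr <- class_metrics(structure(r, class = "confusion_matrix",
                                class_order = c("a", "b", "c")))
  expect_gte(mr$overall[["accuracy"]], min(mr$per_class$accuracy))
  expect_lte(mr$overall[["accuracy"]], max(mr$per_class$accuracy))
  tp <- diag(r); fp <- colSums(r) - tp; fn <- rowSums(r) - tp
  tn <- sum(r) - tp - fp - fn
  expect_equal(mr$per_class$accuracy, unname((tp + tn) / sum(r)))

  # never-predicted class: NA precision, excluded with warning
  cm0 <- confusion_matrix(c("a", "a", "b"), c("a", "a", "a"),
                          classes = c("a", "b"))
  expect_warning(m0 <- class_metrics(cm0), "never-predicted")
  expect_true(is.na(m0$per_class$precision[2]))
  expect_equal(m0$overall[["precision"]], 2 / 3)
})

test_that("cross-validation partitions every spike into exactly one test fold", {
  set.seed(64)
  x <- matrix(rnorm(200), 100, 2)
  x[51:100, ] <- x[51:100, ] + 6
  lab <- rep(c("a", "b"), each = 50)
  cv <- cross_validate(x, labels = lab, k = 10, clusters_per_class = 1,
                       n_components = 2, seed = 9)
  expect_identical(sort(unique(cv$fold)), 1:10)
  expect_identical(tabulate(cv$fold), rep(10L, 10))
  total <- Reduce(`+`, lapply(cv$per_fold, function(m) sum(m)))
  expect_identical(total, 100L)
  # fully separable data classifies perfectly
  expect_equal(cv$overall$accuracy, 1)
  expect_equal(cv$overall$accuracy_sem, 0)
  # same seed is bit-reproducible
  cv2 <- cross_validate(x, labels = lab, k = 10, clusters_per_class = 1,
                        n_components = 2, seed = 9)
  expect_identical(cv$correct, cv2$correct)
  expect_identical(cv$fold, cv2$fold)
  expect_error(cross_validate(x[1:12, ], labels = lab[c(1:10, 51, 52)],
                              k = 10),
               "fewer spikes than folds")
})

test_that("label permutation drives accuracy to chance", {
  set.seed(65)
  x <- matrix(rnorm(600), 300, 2)
  x[101:200, ] <- x[101:200, ] + 5
  x[201:300, 1] <- x[201:300, 1] + 10
  lab <- sample(rep(c("a", "b", "c"), each = 100))   # labels shuffled
  cv <- cross_validate(x, labels = lab, k = 10, clusters_per_class = 1,
                       n_components = 2, seed = 3)
  correct <- sum(cv$correct)
  # 99% binomial band around 1/3
  band <- qbinom(c(0.005, 0.995), 300, 1 / 3)
  expect_gte(correct, band[1])
  expect_lte(correct, band[2])
})

test_that("grouped folds keep all spikes of a neuron together", {
  sp <- small_spikes()
  fm <- dct_features(sp)
  cv <- cross_validate(fm, k = 3, seed = 2, group_by = sp$source_ids)
  for (g in unique(sp$source_ids))
    expect_identical(length(unique(cv$fold[sp$source_ids == g])), 1L)
})

test_that("McNemar reproduces the continuity-corrected hand example", {
  # b = 15, c = 5: (|15-5| - 1)^2 / 20 = 4.05
  a <- rep(TRUE, 100)
  b <- rep(TRUE, 100)
  a[1:5] <- FALSE            # c = 5 (A wrong, B right)
  b[6:20] <- FALSE           # b = 15 (A right, B wrong)
  m <- mcnemar_test(a, b)
  expect_equal(m$statistic, 4.05)
  expect_identical(c(m$b, m$c), c(15L, 5L))

  # identical vectors: p = 1 with warning
  expect_warning(m0 <- mcnemar_test(a, a), "discordant")
  expect_equal(m0$p_value, 1)

  # against the standard implementation on random correctness vectors
  set.seed(66)
  for (rep in 1:5) {
    ca <- runif(200) > 0.3
    cb <- runif(200) > 0.4
    ours <- mcnemar_test(ca, cb)
    ref <- stats::mcnemar.test(table(factor(ca, c(FALSE, TRUE)),
                                     factor(cb, c(FALSE, TRUE))),
                               correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("Cochran's Q matches the formula oracle and degenerate cases", {
  q_oracle <- function(X) {   # independent coding of the statistic
    k <- ncol(X); Cj <- colSums(X); Ri <- rowSums(X)
    (k - 1) * (k * sum(Cj^2) - sum(X)^2) / (k * sum(X) - sum(Ri^2))
  }
  set.seed(67)
  for (rep in 1:5) {
    X <- matrix(runif(150) > 0.4, 50, 3)
    while (all(rowSums(X) %in% c(0, 3))) X <- matrix(runif(150) > 0.4, 50, 3)
    q <- cochran_q(X)
    expect_equal(q$statistic, q_oracle(X * 1), tolerance = 1e-9)
    expect_identical(q$df, 2L)
    expect_equal(q$p_value, pchisq(q$statistic, 2, lower.tail = FALSE))
  }
  # all classifiers identical: undefined, p = 1
  same <- cbind(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE),
                c(TRUE, FALSE, TRUE))
  expect_warning(q0 <- cochran_q(same), "constant")
  expect_equal(q0$p_value, 1)
  expect_error(cochran_q(same[, 1:2]), "at least 3")
})

test_that("Bonferroni multiplies and caps p-values", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(c(0.4, 0.9, 0.001)), c(1, 1, 0.003))
  expect_error(bonferroni(numeric(0)), "no p-values")
})
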