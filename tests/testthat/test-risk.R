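test_that("biomarker probability matches hand-evaluated cases", {
  expect_equal(biomarker_probability(c(10, 0, 0, 0, 0), 100),
               0.06772009, tolerance = 1e-7)
  expect_equal(biomarker_probability(c(0, 0, 0, 0, 100), 100),
               0.006772009, tolerance = 1e-8)
  expect_equal(biomarker_probability(rep(0, 5), 50), 0)
  expect_equal(biomarker_probability(rep(50, 5), 50), 1)
  expect_error(biomarker_probability(c(1, 0, 0, 0, 0), 0), "n_cells")
  expect_error(biomarker_probability(c(60, 0, 0, 0, 0), 50), "counts")
})

test_that("moving an event from 100x to 1x strictly increases p", {
  p_hi <- biomarker_probability(c(0, 0, 0, 0, 1), 100)
  p_lo <- biomarker_probability(c(1, 0, 0, 0, 0), 100)
  expect_gt(p_lo, p_hi)
  # and the index-weight variant preserves the same ordering
  expect_gt(biomarker_probability(c(1, 0, 0, 0, 0), 100, variant = "index"),
            biomarker_probability(c(0, 0, 0, 0, 1), 100, variant = "index"))
})

test_that("ROC-AUC weights normalize and match the analytic case", {
  set.seed(1)
  # biomarker 1 separates perfectly; the other 7 are identical across drugs
  P <- cbind(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
             matrix(0.5, 6, 7))
  labels <- c(0, 0, 0, 2, 2, 2)
  w <- auc_weights(P, labels)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(w[1]), 1 / 4.5, tolerance = 1e-12)
  expect_equal(unname(w[2]), 0.5 / 4.5, tolerance = 1e-12)
  # permuting biomarker order permutes the weights identically
  perm <- sample(8)
  expect_equal(unname(auc_weights(P[, perm], labels)), unname(w[perm]))
  expect_error(auc_weights(P, rep(2, 6)), "class")
})

test_that("ars_score is the bounded convex combination", {
  expect_equal(ars_score(c(0.5, rep(0, 7)), c(1, rep(0, 7))), 0.5)
  expect_equal(ars_score(rep(0, 8), rep(1 / 8, 8)), 0)
  expect_equal(ars_score(rep(1, 8), rep(1 / 8, 8)), 1)
  expect_equal(ars_score(rep(0.1, 8), rep(1 / 8, 8)), 0.1)
  expect_error(ars_score(rep(0.1, 7), rep(1 / 8, 8)), "mismatch")
  expect_error(ars_score(rep(0.1, 8), rep(1, 8)), "sum to 1")
})

test_that("classification boundaries belong to the lower class", {
  expect_identical(classify(0.3, l = 0.3, h = 0.6), 0L)
  expect_identical(classify(0.6, l = 0.3, h = 0.6), 1L)
  expect_identical(classify(0.6 + 1e-12, l = 0.3, h = 0.6), 2L)
  expect_error(classify(0.5, 0.6, 0.3), "l < h")
})

test_that("worked-example class metrics reproduce the reported values", {
  # truth: three low, one borderline (sotalol), six high;
  # predictions: identical except bepridil called borderline
  lib <- drug_library()
  truth <- normalize_labels_for_test(lib$true_class)
  pred <- truth
  pred[lib$name == "bepridil"] <- 1L
  m <- class_metrics(truth, pred)
  expect_equal(unname(m$f1), c(1, 2 / 3, 10 / 11), tolerance = 1e-12)
  expect_equal(round(m$macro_f1, 3), 0.859)
  expect_equal(m$accuracy, 0.9)
  expect_equal(unname(binary_confusion(truth, pred)), c(7, 3, 0, 0))
})

test_that("degenerate prediction patterns score as derived by hand", {
  m <- class_metrics(0:2, 0:2)
  expect_equal(unname(m$f1), c(1, 1, 1))
  expect_equal(m$macro_f1, 1)
  m <- class_metrics(0:2, c(0L, 0L, 0L))
  # class 0: P = 1/3, R = 1 -> F1 = 0.5; classes 1, 2: F1 = 0
  expect_equal(m$macro_f1, 1 / 6, tolerance = 1e-12)
  expect_error(class_metrics(integer(0), integer(0)), "non-empty")
})

test_that("threshold grid search agrees with an exhaustive oracle", {
  expect_equal(optimize_thresholds(c(0.1, 0.2, 0.3), c(0, 1, 2))$macro_f1, 1)
  # independent re-implementation of the 40 x 40 exhaustive search
  oracle <- function(x, y) {
    gl <- seq(min(x), median(x), length.out = 40)
    gh <- seq(median(x), max(x), length.out = 40)
    best <- -Inf; bl <- NA; bh <- NA
    for (l in gl) for (h in gh) if (l < h) {
      pred <- ifelse(x <= l, 0L, ifelse(x <= h, 1L, 2L))
      f1 <- vapply(0:2, function(k) {
        tp <- sum(y == k & pred == k)
        fp <- sum(y != k & pred == k)
        fn <- sum(y == k & pred != k)
        pr <- if (tp + fp) tp / (tp + fp) else 0
        rc <- if (tp + fn) tp / (tp + fn) else 0
        if (pr + rc) 2 * pr * rc / (pr + rc) else 0
      }, numeric(1))
      mf <- mean(f1)
      if (mf > best + 1e-12) { best <- mf; bl <- l; bh <- h }
    }
    list(l = bl, h = bh, macro_f1 = best)
  }
  set.seed(42)
  for (rep in 1:5) {
    x <- runif(10)
    y <- sample(c(0, 0, 0, 1, 2, 2, 2, 2, 2, 2))
    got <- optimize_thresholds(x, y)
    want <- oracle(x, y)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
    expect_equal(got$l, want$l, tolerance = 1e-12)
    expect_equal(got$h, want$h, tolerance = 1e-12)
  }
  # shuffled labels cannot be separated perfectly
  set.seed(7)
  x <- sort(runif(10))
  y <- sample(c(0, 2, 1, 2, 0, 2, 2, 0, 2, 2))
  expect_lt(optimize_thresholds(x, y)$macro_f1, 1)
  expect_error(optimize_thresholds(rep(0.5, 5), c(0, 1, 2, 0, 1)),
               "degenerate")
})

test_that("LOOCV holds folds out correctly on separable scores", {
  # composition chosen so every fold's median-anchored grid can isolate
  # all three classes: wide inter-class gaps, borderline scores clustered
  # tighter than the grid spacing (the optimizer's smallest-h tie-break
  # parks h on the remaining borderline score)
  x <- c(0.020, 0.021, 0.022, 0.023, 0.024, 0.50, 0.505, 0.90, 0.92, 0.94)
  P <- matrix(rep(x, 8), 10, 8)
  labels <- c(0, 0, 0, 0, 0, 1, 1, 2, 2, 2)
  lo <- loocv(P, labels)
  expect_equal(lo$pooled_accuracy, 1)
  expect_equal(lo$pooled_macro_f1, 1)
  expect_true(all(lo$per_fold$correct))
  expect_error(loocv(P[1:2, ], labels[1:2]), "at least 3")
})

test_that("permutation test uses the add-one convention", {
  P <- rbind(matrix(0.02, 4, 8), matrix(0.30, 2, 8), matrix(0.70, 4, 8))
  P <- P + matrix(seq(0, 0.01, length.out = 80), 10, 8)
  labels <- c(0, 0, 0, 0, 1, 1, 2, 2, 2, 2)
  pt <- permutation_test(P, labels, B = 49, seed = 2)
  expect_equal(pt$observed, 1)
  # permutations can tie the observed statistic but never exceed it
  expect_equal(pt$p_value,
               (1 + sum(pt$permuted >= 1, na.rm = TRUE)) / 50)
  expect_error(permutation_test(P, labels, B = 0), "B")
})

test_that("bootstrap threshold CIs are ordered and widen with noise", {
  # a balanced panel large enough that resampling variation does not
  # drown the score-noise effect
  labels <- rep(c(0, 1, 2), each = 10)
  mk <- function(sd, seed) {
    set.seed(seed)
    x <- rep(c(0.1, 0.5, 0.9), each = 10) + seq(0, 0.02, length.out = 30)
    pmin(pmax(matrix(rep(x, 8), 30, 8) +
                matrix(rnorm(240, 0, sd), 30, 8), 0), 1)
  }
  bt_tight <- bootstrap_thresholds(mk(0.002, 1), labels, B = 60, seed = 3)
  bt_noisy <- bootstrap_thresholds(mk(0.10, 1), labels, B = 60, seed = 3)
  expect_lte(bt_tight$l_ci[1], bt_tight$l_ci[2])
  expect_lte(bt_tight$h_ci[1], bt_tight$h_ci[2])
  expect_true(all(bt_tight$l_boot < bt_tight$h_boot))
  expect_gt(diff(bt_noisy$l_ci), diff(bt_tight$l_ci))
  expect_gt(diff(bt_noisy$h_ci), diff(bt_tight$h_ci))
})

test_that("paired model comparison follows signed-rank conventions", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_warning(res <- compare_models(x, x), "zero")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # exact small-n null: enumeration over all sign assignments
  set.seed(9)
  a <- runif(6); b <- a + c(0.05, -0.03, 0.08, -0.02, 0.04, -0.06)
  res <- compare_models(a, b)
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  v_all <- signs %*% r
  p_exact <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("score ordering is invariant to consistent biomarker reordering", {
  panel <- planted_demo_panel(n_cells = 150, seed = 8)
  risk <- score_drug_panel(panel$event_matrices, panel$n_cells,
                           panel$classes)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  ems_perm <- lapply(panel$event_matrices, function(m) m[perm, ])
  risk2 <- score_drug_panel(ems_perm, panel$n_cells, panel$classes)
  expect_equal(unname(risk2$scores), unname(risk$scores), tolerance = 1e-12)
})
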