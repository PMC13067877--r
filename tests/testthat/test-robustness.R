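test_that("full-population subsamples reproduce the full score exactly", {
  panel <- planted_demo_panel(n_cells = 120, seed = 4)
  risk <- score_drug_panel(panel$event_matrices, panel$n_cells,
                           panel$classes)
  R <- subsample_scores(panel$flags, n = 120, w = risk$weights, T_iter = 5,
                        seed = 1)
  expect_true(all(abs(R - risk$scores) < 1e-12))
  expect_true(all(R >= 0 & R <= 1))
  expect_error(subsample_scores(panel$flags, n = 121, w = risk$weights),
               "exceeds")
})

test_that("subsampling is seeded and i.i.d. Bernoulli flags obey the MC law", {
  pool <- bernoulli_pool()
  w <- setNames(c(1, rep(0, 7)), paste0("b", 1:8)) # one-hot on biomarker 1
  R1 <- subsample_scores(pool$flags, 100, w, T_iter = 50, seed = 5)
  R2 <- subsample_scores(pool$flags, 100, w, T_iter = 50, seed = 5)
  expect_identical(R1, R2)
  R3 <- subsample_scores(pool$flags, 100, w, T_iter = 50, seed = 6)
  expect_false(identical(R1, R3))
  # with flags ~ Bernoulli(q) at every concentration, E[p_hat] = q and
  # var = q(1-q)/n * sum(w_k^2) (closed-form oracle)
  q <- 0.3
  wk <- (1 / c(1, 3, 10, 30, 100)) / sum(1 / c(1, 3, 10, 30, 100))
  # subsample means converge to the finite pool's empirical rate, which
  # itself fluctuates around q at the 1/sqrt(8000) scale
  R <- subsample_scores(pool$flags["drug2"], 200, w, T_iter = 400, seed = 7)
  expect_equal(mean(R), q, tolerance = 0.05)
  v_expect <- q * (1 - q) / 200 * sum(wk^2)
  expect_equal(var(as.numeric(R)), v_expect, tolerance = 0.35)
})

test_that("pair score is the convex combination", {
  expect_equal(pair_score(0.2, 0.4, 0.5), 0.3)
  expect_equal(pair_score(0.2, 0.4, 1), 0.2)
  expect_equal(pair_score(0.7, 0.7, 0.123), 0.7)
  expect_error(pair_score(0.1, 0.2, 1.5), "alpha")
})

test_that("RMSE(alpha) follows its algebra and the grid argmin is sharp", {
  # craft probabilities: reference weight is one-hot on biomarker 1,
  # biomarker 2 = biomarker 1 + c  ->  RMSE(alpha) = (1 - alpha) * c
  set.seed(21)
  Parr <- array(0, c(2, 30, 8))
  Parr[, , 1] <- matrix(runif(60, 0.2, 0.4), 2, 30)
  cshift <- 0.2
  Parr[, , 2] <- Parr[, , 1] + cshift
  w <- c(1, rep(0, 7))
  pair <- matrix(c(1, 2), 1)
  expect_equal(rmse_alpha(Parr, w, 0.25, pair), 0.75 * cshift,
               tolerance = 1e-12)
  expect_equal(rmse_alpha(Parr, w, 1, pair), 0, tolerance = 1e-12)
  oa <- optimal_alpha(Parr, w, grid = seq(0, 1, 0.01), pairs = pair)
  expect_equal(oa$alpha, 1)
  expect_equal(oa$delta_rmse, 0.5 * cshift, tolerance = 1e-12)
  # coarse-grid argmin within one step of a fine-grid brute force
  fine <- optimal_alpha(Parr, w, grid = seq(0, 1, 0.001), pairs = pair)
  expect_lt(abs(oa$alpha - fine$alpha), 0.01 + 1e-12)
  # a pair identical to the reference has zero RMSE for any alpha
  Parr2 <- Parr; Parr2[, , 2] <- Parr2[, , 1]
  for (a in c(0, 0.3, 1))
    expect_equal(rmse_alpha(Parr2, w, a, pair), 0)
})

test_that("FP/FN percentages count threshold crossings as defined", {
  thr <- c(0.3, 0.6)
  ref <- c(0.9, 0.8, 0.1, 0.2)   # classes H H L L
  prd <- c(0.9, 0.1, 0.2, 0.8)   # classes H L L H
  rates <- fp_fn_rates(prd, ref, thr)
  expect_equal(unname(rates["fp_pct"]), 25)
  expect_equal(unname(rates["fn_pct"]), 25)
  expect_equal(unname(fp_fn_rates(ref, ref, thr)), c(0, 0))
  # shifting predictions down converts FP into FN monotonically
  fns <- vapply(c(0, 0.3, 0.8), function(s)
    fp_fn_rates(pmax(prd - s, 0), ref, thr)["fn_pct"], numeric(1))
  expect_true(all(diff(fns) >= 0))
  expect_error(fp_fn_rates(prd[1:3], ref, thr), "length")
})

test_that("pair analysis is consistent with its reference", {
  panel <- planted_demo_panel(n_cells = 150, seed = 6)
  risk <- score_drug_panel(panel$event_matrices, panel$n_cells,
                           panel$classes)
  Parr <- subsample_probs(panel$flags, 60, T_iter = 20, seed = 2)
  pa <- pair_analysis(Parr, risk$weights, c(risk$l, risk$h))
  expect_equal(nrow(pa), 28)
  expect_true(all(pa$rmse >= 0))
  expect_true(all(pa$fp_pct >= 0 & pa$fp_pct <= 100))
  expect_true(all(pa$fn_pct >= 0 & pa$fn_pct <= 100))
  # degenerate reference: weights concentrated on one biomarker make the
  # pair (j, j) equal to the reference -> zero RMSE, bias and error
  w1 <- setNames(c(1, rep(0, 7)), paste0("b", 1:8))
  Pd <- Parr; for (j in 2:8) Pd[, , j] <- Pd[, , 1]
  pad <- pair_analysis(Pd, w1, c(risk$l, risk$h))
  expect_true(all(abs(pad$rmse) < 1e-12))
  expect_true(all(abs(pad$median_bias) < 1e-12))
  expect_true(all(pad$err_pct == 0))
})

test_that("ARS variance scales as 1/n on i.i.d. Bernoulli cells", {
  pool <- bernoulli_pool()
  w <- rep(1 / 8, 8)
  vv <- variance_vs_size(pool$flags, c(25, 50, 100, 200, 400), w,
                         T_iter = 200, seed = 11)
  expect_lt(abs(vv$slope + 1), 0.15)
  expect_gt(vv$r_squared, 0.95)
  # doubling n roughly halves the variance
  ratio <- vv$table$variance[1] / vv$table$variance[2]
  expect_gt(ratio, 1.4); expect_lt(ratio, 2.9)
  # constant flags: zero variance everywhere, regression flagged degenerate
  const <- lapply(pool$flags, function(f) array(TRUE, dim(f)))
  vvc <- variance_vs_size(const, c(25, 50, 100), w, T_iter = 20, seed = 1)
  expect_true(vvc$degenerate)
  expect_true(all(vvc$table$variance == 0))
  expect_error(variance_vs_size(pool$flags, c(25, 50), w), "3 sizes")
})

test_that("estimator variance of the mean ARS decreases with iterations", {
  pool <- bernoulli_pool()
  w <- rep(1 / 8, 8)
  it <- iteration_sensitivity(pool$flags["drug1"], n = 100, w = w,
                              N_list = c(10, 40, 160), outer = 25, seed = 3)
  expect_lt(it$estimator_variance[3], it$estimator_variance[1])
  # ~ var_single / N (closed-form oracle within Monte-Carlo slack)
  expect_equal(it$estimator_variance[1] / it$estimator_variance[3],
               16, tolerance = 0.8)
  const <- lapply(pool$flags["drug1"], function(f) array(TRUE, dim(f)))
  itc <- iteration_sensitivity(const, 100, w, N_list = c(5, 10), outer = 5)
  expect_true(all(itc$estimator_variance == 0))
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  set.seed(13)
  P <- matrix(runif(40), 5, 8)
  P[, 2] <- -P[, 1] # perfectly anti-monotone pair
  C <- biomarker_correlation(P)
  expect_equal(dim(C), c(8, 8))
  expect_true(all(diag(C) == 1))
  expect_equal(C[1, 2], -1)
  oracle <- cor(apply(P, 2, rank))
  expect_equal(unname(C), unname(oracle), tolerance = 1e-12)
  # constant column -> missing entries
  P[, 3] <- 0.5
  C2 <- biomarker_correlation(P)
  expect_true(all(is.na(C2[3, -3])))
  expect_error(biomarker_correlation(P[1:2, ]), "3 observations")
})
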