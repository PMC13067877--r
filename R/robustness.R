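#' Subsampled per-biomarker probabilities
#'
#' For each of `T` iterations draws a uniform without-replacement subset of
#' `n` cells (independently across iterations and drugs) and recomputes the
#' inverse-concentration-weighted instability probability of each
#' biomarker, yielding the building block of the subsampling framework.
#'
#' @param flags_list Per-drug list of logical arrays
#'   `[n_cells, 8, n_conc]` (cell-level biomarker flags).
#' @param n Subset size (1..population size).
#' @param T_iter Number of iterations (default 200).
#' @param seed RNG seed.
#' @param multiples Concentration multiples.
#' @param variant Concentration-weight variant (mirrors
#'   [biomarker_probability()]).
#' @return Array `[n_drugs, T_iter, 8]` of probabilities.
#' @export
subsample_probs <- function(flags_list, n, T_iter = 200, seed = 1,
                            multiples = c(1, 3, 10, 30, 100),
                            variant = "concentration") {
  nd <- length(flags_list)
  n_cells <- dim(flags_list[[1]])[1]
  if (n > n_cells) stop("subset size exceeds population size")
  if (n < 1 || T_iter < 1) stop("need n >= 1 and T_iter >= 1")
  wk <- conc_weights(multiples, variant)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- array(NA_real_, c(nd, T_iter, 8),
               dimnames = list(names(flags_list), NULL, BIOMARKER_NAMES))
  for (d in seq_len(nd)) {
    fl <- flags_list[[d]]
    for (t in seq_len(T_iter)) {
      idx <- if (n == n_cells) seq_len(n_cells) else sample(n_cells, n)
      counts <- apply(fl[idx, , , drop = FALSE], c(2, 3), sum)
      out[d, t, ] <- as.numeric(counts %*% wk) / n
    }
  }
  out
}

#' Subsampled risk-score matrix
#'
#' The master matrix `R[d, t]`: the ARS of drug `d` on the `t`-th random
#' subset, `r = sum_j w_j p_hat_j`.
#'
#' @inheritParams subsample_probs
#' @param w Biomarker weights (length 8, sum 1).
#' @return Matrix `n_drugs x T_iter`, entries in `[0, 1]`.
#' @export
subsample_scores <- function(flags_list, n, w, T_iter = 200, seed = 1,
                             multiples = c(1, 3, 10, 30, 100),
                             variant = "concentration") {
  Parr <- subsample_probs(flags_list, n, T_iter, seed, multiples, variant)
  probs_to_scores(Parr, w)
}

# collapse a [d, t, 8] probability array to scores with weights w
probs_to_scores <- function(Parr, w) {
  stopifnot(abs(sum(w) - 1) < 1e-8)
  R <- apply(Parr, c(1, 2), function(p) sum(p * w))
  matrix(R, nrow = dim(Parr)[1], dimnames = dimnames(Parr)[1])
}

#' Two-biomarker pair score
#'
#' Convex combination `r = alpha * p_i + (1 - alpha) * p_j` of two
#' biomarker probabilities (default alpha 0.5).
#'
#' @param p_i,p_j Probabilities. @param alpha Mixing weight in `[0, 1]`.
#' @return Pair score.
#' @export
pair_score <- function(p_i, p_j, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * p_i + (1 - alpha) * p_j
}

#' RMSE of a biomarker pair against the 8-biomarker reference
#'
#' `RMSE(alpha) = sqrt(mean over drugs and iterations of
#' (alpha p_i + (1-alpha) p_j - r8)^2)`, where `r8` is the 8-biomarker
#' reference score from the same subsample draws. `pairs = NULL` averages
#' over all 28 unordered pairs.
#'
#' @param Parr Probability array from [subsample_probs()].
#' @param w Biomarker weights defining the reference score.
#' @param alpha Mixing weight.
#' @param pairs 2-column matrix of biomarker index pairs, or `NULL` for all
#'   28.
#' @return RMSE (scalar).
#' @export
rmse_alpha <- function(Parr, w, alpha, pairs = NULL) {
  if (!length(Parr)) stop("empty input")
  if (is.null(pairs)) pairs <- t(combn(8, 2))
  R8 <- probs_to_scores(Parr, w)
  se <- 0; m <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    diffs <- alpha * Parr[, , i] + (1 - alpha) * Parr[, , j] - R8
    se <- se + sum(diffs^2); m <- m + length(diffs)
  }
  sqrt(se / m)
}

#' Grid-optimal mixing weight alpha
#'
#' Scans `grid` for the alpha minimizing [rmse_alpha()] and reports
#' `delta_rmse = RMSE(0.5) - RMSE(alpha*)`, the improvement the optimal
#' mixing offers over the equal-weight default.
#'
#' @inheritParams rmse_alpha
#' @param grid Candidate alphas.
#' @return List `alpha`, `rmse`, `rmse_half`, `delta_rmse`, `grid_rmse`.
#' @export
optimal_alpha <- function(Parr, w, grid = seq(0, 1, by = 0.01),
                          pairs = NULL) {
  gr <- vapply(grid, function(a) rmse_alpha(Parr, w, a, pairs), numeric(1))
  i <- which.min(gr)
  rmse_half <- rmse_alpha(Parr, w, 0.5, pairs)
  list(alpha = grid[i], rmse = gr[i], rmse_half = rmse_half,
       delta_rmse = rmse_half - gr[i], grid_rmse = setNames(gr, grid))
}

#' False-positive / false-negative percentages of a reduced score
#'
#' Classifies both score sets with the thresholds derived from the
#' 8-biomarker reference and reports, over all observations,
#' `%FP = 100 * mean(pred == k & ref != k)` and
#' `%FN = 100 * mean(pred != k & ref == k)` for the class of interest `k`
#' (default the high-risk class).
#'
#' @param pred_scores Scores of the reduced (e.g. 2-biomarker) model.
#' @param ref_scores Reference 8-biomarker scores (same observations).
#' @param thresholds `c(l, h)` derived from the reference score.
#' @param class_of_interest 0, 1 or 2 (default 2 = high).
#' @return Named vector `fp_pct`, `fn_pct`.
#' @export
fp_fn_rates <- function(pred_scores, ref_scores, thresholds,
                        class_of_interest = 2L) {
  if (length(pred_scores) != length(ref_scores))
    stop("score sets must have the same length")
  ref <- classify(ref_scores, thresholds[1], thresholds[2])
  prd <- classify(pred_scores, thresholds[1], thresholds[2])
  k <- class_of_interest
  c(fp_pct = 100 * mean(prd == k & ref != k),
    fn_pct = 100 * mean(prd != k & ref == k))
}

#' Full 28-pair biomarker-reduction analysis
#'
#' For every unordered biomarker pair: RMSE against the 8-biomarker
#' reference (same subsample draws), median bias (median over drugs of the
#' per-drug median pair score minus median reference score), and %FP/%FN
#' for the high-risk class under the reference-derived thresholds. Pairs
#' with negative median bias under-call risk (FN-driven); positive bias
#' over-calls it (FP-driven).
#'
#' @inheritParams rmse_alpha
#' @param thresholds `c(l, h)` from the reference score.
#' @param alpha Mixing weight (default 0.5).
#' @return data.frame, one row per pair: `i`, `j`, `pair`, `rmse`,
#'   `median_bias`, `fp_pct`, `fn_pct`, `err_pct`, `sqrt_rmse` (bubble-size
#'   key).
#' @export
pair_analysis <- function(Parr, w, thresholds, alpha = 0.5) {
  pairs <- t(combn(8, 2))
  R8 <- probs_to_scores(Parr, w)
  med8 <- apply(R8, 1, median)
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    R2 <- alpha * Parr[, , i] + (1 - alpha) * Parr[, , j]
    rmse <- sqrt(mean((R2 - R8)^2))
    med2 <- apply(matrix(R2, nrow = nrow(R8)), 1, median)
    rates <- fp_fn_rates(as.numeric(R2), as.numeric(R8), thresholds, 2L)
    data.frame(i = i, j = j, pair = paste0("b", i, "-b", j), rmse = rmse,
               median_bias = median(med2 - med8),
               fp_pct = rates["fp_pct"], fn_pct = rates["fn_pct"],
               err_pct = rates["fp_pct"] + rates["fn_pct"],
               sqrt_rmse = sqrt(rmse), row.names = NULL)
  })
  do.call(rbind, out)
}

#' ARS variance versus subsample size
#'
#' Computes the variance of the subsampled score over `T_iter` iterations
#' at each size, then fits ordinary least squares in log-log space. For
#' exchangeable (Bernoulli) cell flags the Monte-Carlo law gives variance
#' proportional to 1/n, i.e. a slope of -1.
#'
#' @inheritParams subsample_probs
#' @param sizes Subsample sizes (>= 3 values for the regression).
#' @param w Biomarker weights.
#' @return List: `table` (size, per-drug mean variance), `slope`,
#'   `intercept`, `r_squared`, `degenerate` (TRUE when variances vanish and
#'   no regression is possible).
#' @export
variance_vs_size <- function(flags_list, sizes, w, T_iter = 200, seed = 1,
                             multiples = c(1, 3, 10, 30, 100),
                             variant = "concentration") {
  if (length(sizes) < 3) stop("need at least 3 sizes")
  vars <- vapply(seq_along(sizes), function(s) {
    R <- subsample_scores(flags_list, sizes[s], w, T_iter,
                          seed = seed + s, multiples = multiples,
                          variant = variant)
    mean(apply(R, 1, var))
  }, numeric(1))
  tab <- data.frame(n = sizes, variance = vars)
  if (any(vars <= 0)) {
    return(list(table = tab, slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, degenerate = TRUE))
  }
  fit <- lm(log(vars) ~ log(sizes))
  list(table = tab, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, degenerate = FALSE)
}

#' Sensitivity of the mean ARS to the number of resampling iterations
#'
#' For each candidate iteration count `N`, estimates the variance of the
#' mean-of-N subsample scores over `outer` independent replicates. For
#' i.i.d. subsample scores this decays as `var_single / N`.
#'
#' @inheritParams subsample_probs
#' @param n Subsample size (e.g. 100).
#' @param N_list Iteration counts to probe (study values 10, 50, 100, 200,
#'   400).
#' @param outer Outer replicates per N (default 30).
#' @param w Biomarker weights.
#' @return data.frame `N`, `estimator_variance` (mean across drugs),
#'   `standard_error`.
#' @export
iteration_sensitivity <- function(flags_list, n, w,
                                  N_list = c(10, 50, 100, 200, 400),
                                  outer = 30, seed = 1,
                                  multiples = c(1, 3, 10, 30, 100),
                                  variant = "concentration") {
  if (!length(N_list)) stop("N_list must be non-empty")
  res <- vapply(seq_along(N_list), function(k) {
    N <- N_list[k]
    means <- vapply(seq_len(outer), function(rep) {
      R <- subsample_scores(flags_list, n, w, N,
                            seed = seed + 1000 * k + rep,
                            multiples = multiples, variant = variant)
      rowMeans(R)
    }, numeric(length(flags_list)))
    mean(apply(matrix(means, ncol = outer), 1, var))
  }, numeric(1))
  data.frame(N = N_list, estimator_variance = res,
             standard_error = sqrt(res))
}

#' Pairwise Spearman correlation among biomarker probabilities
#'
#' Rank correlation (midranks for ties) across observations; constant
#' columns yield NA entries, reported as missing.
#'
#' @param P Matrix observations x 8 of biomarker probabilities (or event
#'   indicators).
#' @return 8 x 8 symmetric matrix, unit diagonal.
#' @export
biomarker_correlation <- function(P) {
  if (nrow(P) < 3) stop("need at least 3 observations")
  suppressWarnings(C <- cor(P, method = "spearman"))
  diag(C) <- 1
  dimnames(C) <- list(BIOMARKER_NAMES, BIOMARKER_NAMES)
  C
}
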