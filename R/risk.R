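#' Aggregate cell-level flags into an event matrix
#'
#' @param flags Logical array `[n_cells, 8, n_conc]` of biomarker events.
#' @return Integer matrix 8 x n_conc of cells flagged per (biomarker,
#'   concentration).
#' @export
event_matrix_from_flags <- function(flags) {
  stopifnot(length(dim(flags)) == 3, dim(flags)[2] == 8)
  m <- apply(flags, c(2, 3), sum)
  storage.mode(m) <- "integer"
  rownames(m) <- BIOMARKER_NAMES
  m
}

# inverse-concentration weights: omega_k = 1/C_k (default, weighting events
# near therapeutic exposure most) or 1/k (rank variant); normalized to sum 1
conc_weights <- function(multiples, variant = c("concentration", "index")) {
  variant <- match.arg(variant)
  w <- if (variant == "concentration") 1 / multiples
       else 1 / seq_along(multiples)
  w / sum(w)
}

#' Per-biomarker instability probability with inverse-concentration weights
#'
#' `p = sum_k (M_k / C_k) / (N * sum_k 1/C_k)`: the fraction of flagged
#' cells aggregated over concentrations, down-weighting supratherapeutic
#' multiples so events near clinical exposure dominate. The `index` variant
#' uses 1/k (concentration rank) instead of 1/C_k.
#'
#' @param counts Flagged-cell counts per concentration (length = number of
#'   concentrations), each in `0..n_cells`.
#' @param n_cells Population size N (> 0).
#' @param multiples Concentration multiples (default the study grid).
#' @param variant `"concentration"` (1/C_k, default) or `"index"` (1/k).
#' @return Probability in `[0, 1]`.
#' @export
biomarker_probability <- function(counts, n_cells,
                                  multiples = c(1, 3, 10, 30, 100),
                                  variant = "concentration") {
  if (n_cells <= 0) stop("n_cells must be > 0")
  if (length(counts) != length(multiples))
    stop("counts and multiples length mismatch")
  if (any(counts < 0 | counts > n_cells))
    stop("counts must be within 0..n_cells")
  w <- conc_weights(multiples, variant)
  sum(w * counts / n_cells)
}

#' Event probabilities for all biomarkers of one drug
#'
#' @param M 8 x n_conc event matrix (see [event_matrix_from_flags()]).
#' @inheritParams biomarker_probability
#' @return Named numeric vector of 8 probabilities.
#' @export
biomarker_probabilities <- function(M, n_cells,
                                    multiples = c(1, 3, 10, 30, 100),
                                    variant = "concentration") {
  setNames(vapply(seq_len(nrow(M)), function(j)
    biomarker_probability(M[j, ], n_cells, multiples, variant),
    numeric(1)), BIOMARKER_NAMES)
}

# rank-based (Mann-Whitney) AUC with midrank tie handling
mw_auc <- function(x, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes for AUC")
  r <- rank(x) # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC-AUC biomarker weights
#'
#' For each biomarker, the AUC of the binary "pro vs non-pro" ROC over all
#' drugs (rank-based Mann-Whitney statistic with midranks), normalized so
#' the eight weights sum to 1. Borderline compounds group with the
#' proarrhythmic class for the binary labels.
#'
#' @param P Matrix drugs x 8 of biomarker probabilities.
#' @param labels Per-drug classes: integers (0 low, 1 borderline, 2 high) or
#'   a logical "is proarrhythmic" vector.
#' @return Numeric weight vector of length 8, summing to 1.
#' @export
auc_weights <- function(P, labels) {
  stopifnot(ncol(P) == 8, nrow(P) == length(labels))
  pos <- if (is.logical(labels)) labels else labels >= 1
  if (length(unique(pos)) < 2)
    stop("need at least one drug in each binary class")
  auc <- vapply(seq_len(ncol(P)), function(j) mw_auc(P[, j], pos),
                numeric(1))
  setNames(auc / sum(auc), colnames(P) %||% BIOMARKER_NAMES)
}

#' Arrhythmic risk score
#'
#' `x = sum_j w_j p_j`, a convex combination of the eight biomarker
#' probabilities, bounded in `[0, 1]`.
#'
#' @param p Probabilities (length 8, in `[0, 1]`).
#' @param w Weights (length 8, summing to 1).
#' @return Score in `[0, 1]`.
#' @export
ars_score <- function(p, w) {
  if (length(p) != length(w)) stop("p and w length mismatch")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  sum(w * p)
}

#' Three-class risk classification from two thresholds
#'
#' Class 0 (low) for `x <= l`, 1 (borderline) for `l < x <= h`,
#' 2 (high) for `x > h`. Boundaries belong to the lower class.
#'
#' @param x Score(s). @param l,h Thresholds with `l < h`.
#' @return Integer class(es) in `{0, 1, 2}`.
#' @export
classify <- function(x, l, h) {
  if (!(l < h)) stop("need l < h")
  ifelse(x <= l, 0L, ifelse(x <= h, 1L, 2L))
}

#' Multi-class classification metrics
#'
#' One-vs-rest precision, recall and F1 per class (F1 of a class absent
#' from both truth and prediction is defined as 0 within the macro
#' average), Macro-F1 (unweighted mean of the three F1 values), accuracy
#' and the 3x3 confusion matrix.
#'
#' @param y_true,y_pred Integer classes in `{0, 1, 2}` (equal length).
#' @return List: `precision`, `recall`, `f1` (length-3, names "0","1","2"),
#'   `macro_f1`, `accuracy`, `confusion`.
#' @export
class_metrics <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be equal-length, non-empty")
  if (!all(c(y_true, y_pred) %in% 0:2)) stop("classes must be in {0,1,2}")
  conf <- table(true = factor(y_true, 0:2), pred = factor(y_pred, 0:2))
  prec <- reca <- f1 <- setNames(numeric(3), 0:2)
  for (k in 1:3) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    reca[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + reca[k] > 0)
      2 * prec[k] * reca[k] / (prec[k] + reca[k]) else 0
  }
  list(precision = prec, recall = reca, f1 = f1,
       macro_f1 = mean(f1), accuracy = mean(y_true == y_pred),
       confusion = conf)
}

#' Binary (pro vs non-pro) confusion counts
#'
#' Collapses classes 1 and 2 into "proarrhythmic" and reports TP, TN, FP,
#' FN — the class-imbalance sensitivity analysis.
#'
#' @inheritParams class_metrics
#' @return Named integer vector `tp`, `tn`, `fp`, `fn`.
#' @export
binary_confusion <- function(y_true, y_pred) {
  pt <- y_true >= 1; pp <- y_pred >= 1
  c(tp = sum(pt & pp), tn = sum(!pt & !pp),
    fp = sum(!pt & pp), fn = sum(pt & !pp))
}

#' Grid search for the optimal (l, h) thresholds
#'
#' Forty equally spaced candidates for `l` spanning `[min(x), median(x)]`
#' and forty for `h` spanning `[median(x), max(x)]`; every pair with
#' `l < h` is evaluated and the pair maximizing Macro-F1 returned. Ties are
#' broken by smallest `l`, then smallest `h`.
#'
#' @param x Risk scores. @param y True classes in `{0, 1, 2}`.
#' @param n_grid Candidates per threshold (default 40).
#' @return List `l`, `h`, `macro_f1`, plus the evaluated `grid_l`,
#'   `grid_h`.
#' @export
optimize_thresholds <- function(x, y, n_grid = 40) {
  if (length(unique(x)) < 2) stop("degenerate scores: all equal")
  gl <- seq(min(x), median(x), length.out = n_grid)
  gh <- seq(median(x), max(x), length.out = n_grid)
  best <- list(l = NA_real_, h = NA_real_, macro_f1 = -Inf)
  for (l in gl) for (h in gh) {
    if (!(l < h)) next
    mf <- class_metrics(y, classify(x, l, h))$macro_f1
    if (mf > best$macro_f1 + 1e-12) best <- list(l = l, h = h, macro_f1 = mf)
  }
  if (!is.finite(best$macro_f1)) stop("no valid (l, h) pair on the grid")
  c(best, list(grid_l = gl, grid_h = gh))
}

#' Score a drug panel and optimize its risk classes
#'
#' The full scoring pipeline on aggregated event matrices: per-drug
#' biomarker probabilities (inverse-concentration weighting), ROC-AUC
#' biomarker weights, ARS scores, grid-searched thresholds, and the
#' resulting three-class and binary metrics.
#'
#' @param event_matrices Named list (per drug) of 8 x n_conc count matrices.
#' @param n_cells Population size N (scalar or per-drug vector).
#' @param labels Named or ordered true classes (0/1/2 integers or
#'   `low`/`borderline`/`high` strings).
#' @param multiples Concentration multiples.
#' @param variant Concentration-weight variant (see
#'   [biomarker_probability()]); the variant in force is recorded in the
#'   result.
#' @return List of class `risk_result`: `P` (drugs x 8), `weights`,
#'   `scores`, `l`, `h`, `predicted`, `metrics`, `binary`, `labels`,
#'   `variant`.
#' @export
score_drug_panel <- function(event_matrices, n_cells, labels,
                             multiples = c(1, 3, 10, 30, 100),
                             variant = "concentration") {
  labels <- normalize_labels(labels, names(event_matrices))
  nd <- length(event_matrices)
  if (length(n_cells) == 1) n_cells <- rep(n_cells, nd)
  P <- t(vapply(seq_len(nd), function(d)
    biomarker_probabilities(event_matrices[[d]], n_cells[d], multiples,
                            variant), numeric(8)))
  rownames(P) <- names(event_matrices)
  # a panel with a single binary class cannot support ROC weights or
  # threshold optimization; fall back to the plain uniform-weight score
  two_class <- length(unique(labels >= 1)) == 2
  if (two_class) {
    w <- auc_weights(P, labels)
    weights_method <- "roc_auc"
  } else {
    w <- setNames(rep(1 / 8, 8), colnames(P))
    weights_method <- "uniform"
  }
  x <- as.numeric(P %*% w)
  names(x) <- rownames(P)
  opt <- if (two_class && length(unique(x)) >= 2)
    optimize_thresholds(x, labels) else list(l = NA_real_, h = NA_real_)
  pred <- if (is.na(opt$l)) rep(NA_integer_, nd)
          else classify(x, opt$l, opt$h)
  structure(list(P = P, weights = w, weights_method = weights_method,
                 scores = x, l = opt$l, h = opt$h,
                 predicted = pred,
                 metrics = if (!anyNA(pred)) class_metrics(labels, pred),
                 binary = if (!anyNA(pred)) binary_confusion(labels, pred),
                 labels = labels, variant = variant),
            class = "risk_result")
}

normalize_labels <- function(labels, drug_names = NULL) {
  if (is.character(labels))
    labels <- c(low = 0L, borderline = 1L, high = 2L)[labels]
  labels <- as.integer(labels)
  if (!all(labels %in% 0:2)) stop("labels must be 0/1/2")
  if (!is.null(drug_names) && !is.null(names(labels)))
    labels <- labels[drug_names]
  unname(labels)
}

#' Leave-one-out cross-validation of the scoring pipeline
#'
#' One compound held out per fold; biomarker weights and thresholds are
#' recomputed on the remaining drugs and the held-out compound classified
#' with them. Reports per-fold correctness, pooled accuracy, pooled
#' Macro-F1 over the collected held-out predictions, and the mean of the
#' per-fold (single-drug) Macro-F1 values; a single held-out drug makes
#' the per-fold Macro-F1 low-information, so both aggregations are
#' reported. Folds whose training set loses a class entirely are flagged
#' (`fold_ok = FALSE`) rather than fatal.
#'
#' @param P Matrix drugs x 8 of biomarker probabilities.
#' @param labels True classes (0/1/2).
#' @return List: `per_fold` data.frame (`drug`, `true`, `pred`, `correct`,
#'   `fold_macro_f1`, `fold_ok`), `pooled_accuracy`, `pooled_macro_f1`,
#'   `mean_fold_macro_f1`.
#' @export
loocv <- function(P, labels) {
  labels <- normalize_labels(labels)
  nd <- nrow(P)
  if (nd < 3) stop("need at least 3 drugs")
  pred <- integer(nd); ok <- logical(nd); fold_f1 <- numeric(nd)
  for (d in seq_len(nd)) {
    tr_idx <- setdiff(seq_len(nd), d)
    yt <- labels[tr_idx]
    ok[d] <- length(unique(yt >= 1)) == 2
    if (!ok[d]) { pred[d] <- NA_integer_; fold_f1[d] <- NA_real_; next }
    w <- auc_weights(P[tr_idx, , drop = FALSE], yt)
    xt <- as.numeric(P[tr_idx, , drop = FALSE] %*% w)
    opt <- tryCatch(optimize_thresholds(xt, yt), error = function(e) NULL)
    if (is.null(opt)) { pred[d] <- NA_integer_; ok[d] <- FALSE; next }
    xo <- sum(P[d, ] * w)
    pred[d] <- classify(xo, opt$l, opt$h)
    fold_f1[d] <- class_metrics(labels[d], pred[d])$macro_f1
  }
  valid <- !is.na(pred)
  pooled <- class_metrics(labels[valid], pred[valid])
  list(per_fold = data.frame(
         drug = rownames(P) %||% seq_len(nd), true = labels, pred = pred,
         correct = labels == pred, fold_macro_f1 = fold_f1, fold_ok = ok),
       pooled_accuracy = mean(labels[valid] == pred[valid]),
       pooled_macro_f1 = pooled$macro_f1,
       mean_fold_macro_f1 = mean(fold_f1, na.rm = TRUE))
}

#' Permutation test of the optimized Macro-F1
#'
#' Permutes the drug labels B times, re-runs weights + threshold
#' optimization each time, and reports the add-one permutation p-value
#' `(1 + #{perm >= observed}) / (B + 1)`.
#'
#' @param P Matrix drugs x 8. @param labels True classes.
#' @param B Number of permutations (>= 1). @param seed RNG seed.
#' @return List `p_value`, `observed`, `permuted` (vector of B statistics).
#' @export
permutation_test <- function(P, labels, B = 1000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  labels <- normalize_labels(labels)
  stat <- function(y) {
    w <- tryCatch(auc_weights(P, y), error = function(e) NULL)
    if (is.null(w)) return(NA_real_)
    x <- as.numeric(P %*% w)
    tryCatch(optimize_thresholds(x, y)$macro_f1, error = function(e) NA_real_)
  }
  obs <- stat(labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- vapply(seq_len(B), function(b) stat(sample(labels)), numeric(1))
  list(p_value = (1 + sum(perm >= obs, na.rm = TRUE)) / (B + 1),
       observed = obs, permuted = perm)
}

#' Bootstrap confidence intervals for the thresholds
#'
#' Resamples the drug set with replacement (resamples missing one of the
#' binary classes, or with degenerate scores, are redrawn and counted),
#' re-estimates weights and thresholds each time, and returns percentile
#' 95% confidence intervals (2.5-97.5).
#'
#' @inheritParams permutation_test
#' @param max_redraw Redraw budget per resample.
#' @return List `l_ci`, `h_ci` (length-2), `l_boot`, `h_boot`, `n_redrawn`.
#' @export
bootstrap_thresholds <- function(P, labels, B = 1000, seed = 1,
                                 max_redraw = 100) {
  if (B < 1) stop("B must be >= 1")
  labels <- normalize_labels(labels)
  nd <- nrow(P)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lb <- hb <- numeric(B); redrawn <- 0L
  for (b in seq_len(B)) {
    for (k in seq_len(max_redraw)) {
      idx <- sample(nd, nd, replace = TRUE)
      y <- labels[idx]
      res <- tryCatch({
        w <- auc_weights(P[idx, , drop = FALSE], y)
        x <- as.numeric(P[idx, , drop = FALSE] %*% w)
        optimize_thresholds(x, y)
      }, error = function(e) NULL)
      if (!is.null(res)) break
      redrawn <- redrawn + 1L
    }
    if (is.null(res)) stop("could not draw a valid bootstrap resample")
    lb[b] <- res$l; hb[b] <- res$h
  }
  list(l_ci = unname(quantile(lb, c(0.025, 0.975))),
       h_ci = unname(quantile(hb, c(0.025, 0.975))),
       l_boot = lb, h_boot = hb, n_redrawn = redrawn)
}

#' Paired comparison of two score vectors (Wilcoxon signed rank)
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-drug differences
#' (e.g. isolated-cell vs coupled-tissue scores). Zero differences are
#' dropped (standard convention); if every difference is zero the statistic
#' is 0 and p = 1, with a warning.
#'
#' @param x_a,x_b Paired score vectors (same drugs, same order).
#' @return List `statistic`, `p_value`, `n_nonzero`.
#' @export
compare_models <- function(x_a, x_b) {
  if (length(x_a) != length(x_b)) stop("score vectors must be paired")
  d <- x_a - x_b
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L))
  }
  wt <- suppressWarnings(wilcox.test(x_a[nz], x_b[nz], paired = TRUE,
                                     exact = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = sum(nz))
}
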