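#' Experimental calibration ranges for action-potential biomarkers
#'
#' The 5th-95th percentile acceptance bands of the five calibration
#' biomarkers measured from human ventricular recordings: RMP -95..-85 mV,
#' APA 102.7..116.4 mV, APD20 138..188 ms, APD50 181..251 ms,
#' APD90 250..331 ms. Bounds are inclusive at both ends.
#'
#' @param rmp,apa,apd20,apd50,apd90 Length-2 `c(low, high)` bands.
#' @return List of class `calibration_ranges`.
#' @export
calibration_ranges <- function(rmp = c(-95, -85), apa = c(102.7, 116.4),
                               apd20 = c(138, 188), apd50 = c(181, 251),
                               apd90 = c(250, 331)) {
  rr <- list(rmp = rmp, apa = apa, apd20 = apd20, apd50 = apd50,
             apd90 = apd90)
  for (nm in names(rr))
    if (length(rr[[nm]]) != 2 || rr[[nm]][1] >= rr[[nm]][2])
      stop("range ", nm, " must be c(low, high) with low < high")
  structure(rr, class = "calibration_ranges")
}

#' Latin hypercube sample of conductance scale factors
#'
#' One stratified uniform sample per model over `[low_frac, high_frac]`
#' (default 0.2..3.0, i.e. -80% to +200% of the reference conductances) in
#' each varied-current dimension: per dimension, exactly one sample falls in
#' each of `n_models` equal-width strata.
#'
#' @param n_models Number of models (>= 1).
#' @param low_frac,high_frac Range bounds, `low_frac < high_frac`.
#' @param seed RNG seed (reproducible).
#' @param currents Currents to vary; default all nine scaled currents.
#' @return Matrix `n_models x length(currents)` with current names as
#'   columns; unvaried currents are omitted (treated as 1 downstream).
#' @export
lhs_sample <- function(n_models, low_frac = 0.2, high_frac = 3.0, seed = 1,
                       currents = SCALED_CURRENTS) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (!(low_frac < high_frac)) stop("need low_frac < high_frac")
  currents <- match.arg(currents, SCALED_CURRENTS, several.ok = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- lhs::randomLHS(n_models, length(currents))
  m <- low_frac + u * (high_frac - low_frac)
  colnames(m) <- currents
  m
}

#' Stability filter for a drug-free paced trace
#'
#' Classifies a trace as `accepted` or excluded with one of the reasons
#' `alternans` (one of the last-3 APD90s deviates more than 5% from both
#' others), `repolarization_abnormality` (EAD on the last beat, or failure
#' to repolarize below -50 mV), or `self_stimulation` (diastolic dV/dt
#' above 0.01 mV/ms). The same detectors as biomarkers B6, B7/B3 and B1,
#' evaluated drug-free. Reasons are checked in the order self-stimulation,
#' repolarization abnormality, alternans; the first match is reported.
#'
#' @param trace `ap_trace` with >= 3 recorded beats.
#' @param thresholds [detector_thresholds()].
#' @return List with `accepted` (logical) and `reason` (`NA` or one of the
#'   three exclusion reasons).
#' @export
stability_filter <- function(trace, thresholds = detector_thresholds()) {
  if (trace$n_beats < 3) stop("trace must have >= 3 recorded beats")
  th <- thresholds
  f <- extract_features(trace, trace$n_beats)
  dvdt_dia <- max_diastolic_dvdt(trace)
  self_stim <- !is.na(dvdt_dia) && dvdt_dia > th$b1_dvdt
  repol_fail <- (f$capture && is.na(f$apd90)) || f$rmp > th$b3_rmp
  ead <- ead_flag(trace, th$b7_ead_dvdt, th$b7_min_duration,
                  th$b7_window_frac)
  alt <- alternans_flag(last_apd90s(trace, 3), th$b6_alternans)
  reason <- if (self_stim) "self_stimulation"
            else if (repol_fail || ead) "repolarization_abnormality"
            else if (alt) "alternans"
            else NA_character_
  list(accepted = is.na(reason), reason = reason)
}

#' Calibration filter against experimental percentile bands
#'
#' TRUE iff rmp, apa, apd20, apd50 and apd90 all lie inside their inclusive
#' `[low, high]` bands.
#'
#' @param features `ap_features` (or a named list with the five fields).
#' @param ranges [calibration_ranges()].
#' @return Logical.
#' @export
calibration_filter <- function(features, ranges = calibration_ranges()) {
  for (nm in names(ranges)) {
    x <- features[[nm]]
    if (is.null(x) || is.na(x))
      stop("missing calibration feature: ", nm)
    if (x < ranges[[nm]][1] || x > ranges[[nm]][2]) return(FALSE)
  }
  TRUE
}

#' Generate, stability-filter and calibrate a virtual population
#'
#' Draws `n_models` Latin hypercube conductance samples, paces each model,
#' applies the stability filter and then the experimental calibration
#' filter (in that order). Per-model status is exhaustive:
#' `accepted`, `excluded:no_capture`, `excluded:<stability reason>` or
#' `excluded:calibration`.
#'
#' @param n_models Number of LHS samples.
#' @param protocol [pacing_protocol()]; the desk-scale default paces
#'   50 beats (override `n_beats = 500` for the full protocol).
#' @param seed RNG seed for the LHS draw.
#' @param low_frac,high_frac LHS range (default -80%..+200%).
#' @param ranges [calibration_ranges()].
#' @param thresholds [detector_thresholds()] for the stability filter.
#' @param currents Currents varied by the LHS.
#' @param keep_states Keep each accepted model's end-of-pacing state (needed
#'   to seed tissue simulations without re-pacing).
#' @param progress Print a dot every 10 models.
#' @return List of class `population_set`: `scales` (matrix), `status`
#'   (character), `features` (data.frame of baseline features),
#'   `states` (list or NULL), `seed`, `ranges`, `protocol`,
#'   `b8_triangulation` (95th percentile of accepted baseline
#'   triangulation, the default B8 threshold).
#' @export
build_population <- function(n_models, protocol = pacing_protocol(),
                             seed = 1, low_frac = 0.2, high_frac = 3.0,
                             ranges = calibration_ranges(),
                             thresholds = detector_thresholds(),
                             currents = SCALED_CURRENTS,
                             keep_states = TRUE, progress = FALSE) {
  scales <- lhs_sample(n_models, low_frac, high_frac, seed, currents)
  status <- character(n_models)
  feats <- vector("list", n_models)
  states <- if (keep_states) vector("list", n_models) else NULL
  for (i in seq_len(n_models)) {
    g <- conductance_scaling()
    g[colnames(scales)] <- scales[i, ]
    tr <- tryCatch(run_single_cell(g, protocol, drift_guard = FALSE),
                   error = function(e) NULL)
    if (is.null(tr) || !tr$capture) {
      status[i] <- "excluded:no_capture"
      feats[[i]] <- extract_features_na()
    } else {
      sf <- stability_filter(tr, thresholds)
      f <- extract_features(tr, tr$n_beats)
      feats[[i]] <- f
      if (!sf$accepted) {
        status[i] <- paste0("excluded:", sf$reason)
      } else if (!isTRUE(tryCatch(calibration_filter(f, ranges),
                                  error = function(e) FALSE))) {
        status[i] <- "excluded:calibration"
      } else {
        status[i] <- "accepted"
        if (keep_states) states[[i]] <- tr$final_state
      }
    }
    if (progress && i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  fdf <- do.call(rbind, lapply(feats, function(f)
    as.data.frame(f[c("rmp", "apa", "peak", "apd20", "apd30", "apd50",
                      "apd90", "triangulation")])))
  acc <- status == "accepted"
  tri <- fdf$triangulation[acc]
  structure(list(scales = scales, status = status, features = fdf,
                 states = states, seed = seed,
                 ranges = ranges, protocol = protocol,
                 b8_triangulation = if (any(acc))
                   unname(quantile(tri, 0.95, na.rm = TRUE)) else Inf),
            class = "population_set")
}

extract_features_na <- function() {
  structure(list(rmp = NA_real_, apa = NA_real_, peak = NA_real_,
                 apd20 = NA_real_, apd30 = NA_real_, apd50 = NA_real_,
                 apd90 = NA_real_, dvdt_max_upstroke = NA_real_,
                 dvdt_max_diastolic = NA_real_, triangulation = NA_real_,
                 capture = FALSE), class = "ap_features")
}

#' Persist / load a population as CSV + JSON metadata
#'
#' One row per model (scale factors, status, baseline features); seed,
#' ranges and protocol go to a JSON sidecar.
#'
#' @param pop `population_set`.
#' @param path CSV path (metadata at `paste0(path, ".json")`).
#' @export
write_population <- function(pop, path) {
  df <- cbind(as.data.frame(pop$scales), status = pop$status, pop$features)
  write.csv(df, path, row.names = FALSE)
  meta <- list(seed = pop$seed, ranges = unclass(pop$ranges),
               protocol = unclass(pop$protocol),
               b8_triangulation = pop$b8_triangulation)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @param accepted_only Return only accepted models.
#' @return For `accepted_models()`: list with `scales` matrix and `states`
#'   (if kept) of the accepted population.
#' @export
accepted_models <- function(pop, accepted_only = TRUE) {
  idx <- which(pop$status == "accepted")
  list(idx = idx,
       scales = pop$scales[idx, , drop = FALSE],
       states = if (!is.null(pop$states)) pop$states[idx],
       features = pop$features[idx, , drop = FALSE])
}
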