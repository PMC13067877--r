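#' Detector thresholds for the eight instability biomarkers
#'
#' Defaults follow the study conventions: B1 diastolic dV/dt threshold
#' 0.01 mV/ms; B2 APD90 prolongation 20%; B3 resting potential -50 mV;
#' B4/B5 peak bounds 0 and 50 mV; B6 alternans deviation 5%. The B7 EAD
#' rule flags positive dV/dt above `b7_ead_dvdt` sustained for at least
#' `b7_min_duration` ms during late repolarization (between the last
#' crossing of `b7_window_frac` repolarization and the APD90 crossing) on
#' the last beat. The B8 triangulation threshold has no published constant;
#' the pipelines set it to the drug-free population's 95th percentile of
#' APD90 - APD30 (the `Inf` default disables B8 until a value is supplied).
#' All comparisons are strict: values exactly at a threshold do not flag.
#'
#' @param b1_dvdt mV/ms. @param b2_prolongation fraction. @param b3_rmp mV.
#' @param b4_peak mV. @param b5_peak mV. @param b6_alternans fraction.
#' @param b7_ead_dvdt mV/ms. @param b7_min_duration ms.
#' @param b7_window_frac repolarization fraction opening the EAD window.
#' @param b8_triangulation ms.
#' @return List of class `detector_thresholds`.
#' @export
detector_thresholds <- function(b1_dvdt = 0.01, b2_prolongation = 0.20,
                                b3_rmp = -50, b4_peak = 0, b5_peak = 50,
                                b6_alternans = 0.05, b7_ead_dvdt = 0.01,
                                b7_min_duration = 2, b7_window_frac = 0.25,
                                b8_triangulation = Inf) {
  structure(list(b1_dvdt = b1_dvdt, b2_prolongation = b2_prolongation,
                 b3_rmp = b3_rmp, b4_peak = b4_peak, b5_peak = b5_peak,
                 b6_alternans = b6_alternans, b7_ead_dvdt = b7_ead_dvdt,
                 b7_min_duration = b7_min_duration,
                 b7_window_frac = b7_window_frac,
                 b8_triangulation = b8_triangulation),
            class = "detector_thresholds")
}

# first downward crossing of `level` after index `from`
first_crossing_down <- function(tt, vv, level, from = 1L) {
  n <- length(vv)
  if (from >= n) return(NA_real_)
  above <- vv[from:n] > level
  cross <- which(above[-length(above)] & !above[-1])
  if (!length(cross)) return(NA_real_)
  i <- from + cross[1] - 1L
  frac <- (vv[i] - level) / (vv[i] - vv[i + 1])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

# last downward crossing of `level` after index `from` within (tt, vv);
# linear interpolation between samples. NA if vv stays above level at end.
last_crossing_down <- function(tt, vv, level, from = 1L) {
  n <- length(vv)
  if (from >= n) return(NA_real_)
  above <- vv[from:n] > level
  if (above[length(above)]) return(NA_real_) # not repolarized to level
  cross <- which(above[-length(above)] & !above[-1])
  if (!length(cross)) {
    # already below level for the whole tail
    return(if (!above[1]) tt[from] else NA_real_)
  }
  i <- from + cross[length(cross)] - 1L
  frac <- (vv[i] - level) / (vv[i] - vv[i + 1])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' Extract action-potential features from one beat
#'
#' APDx is measured from the time of maximum upstroke dV/dt to the last
#' downward crossing of x% repolarization of the amplitude (so EADs and
#' notch-dome morphologies extend, not truncate, the duration). RMP is the
#' minimum voltage in the diastolic interval preceding the stimulus (the
#' last `rmp_window` ms of the previous beat; for the first recorded beat,
#' the beat's onset value). A non-captured beat (peak <= 0 mV) returns
#' duration features as NA rather than erroring.
#'
#' @param trace An `ap_trace` (from [run_single_cell()] or
#'   [make_ap_trace()]).
#' @param beat Beat index within the recorded window (default: last beat).
#' @param rmp_window Diastolic window before the stimulus used for RMP (ms).
#' @return List of class `ap_features`: `rmp`, `apa`, `peak`, `apd20`,
#'   `apd30`, `apd50`, `apd90`, `dvdt_max_upstroke`, `dvdt_max_diastolic`,
#'   `triangulation`, `capture`.
#' @export
extract_features <- function(trace, beat = trace$n_beats, rmp_window = 50) {
  w <- beat_window(trace, beat)
  tt <- trace$t[w]; vv <- trace$v[w]
  step <- trace$dt
  # RMP from the diastole preceding this beat's stimulus
  if (beat > 1) {
    pre <- trace$t >= (tt[1] - rmp_window) & trace$t < tt[1]
    rmp <- min(trace$v[pre])
  } else rmp <- vv[1]
  ipk <- which.max(vv)
  peak <- vv[ipk]
  apa <- peak - rmp
  capture <- peak > 0
  dvdt <- diff(vv) / diff(tt)
  na_feats <- list(rmp = rmp, apa = apa, peak = peak, apd20 = NA_real_,
                   apd30 = NA_real_, apd50 = NA_real_, apd90 = NA_real_,
                   dvdt_max_upstroke = NA_real_,
                   dvdt_max_diastolic = NA_real_,
                   triangulation = NA_real_, capture = FALSE)
  if (!capture) return(structure(na_feats, class = "ap_features"))
  iup <- which.max(dvdt[seq_len(max(ipk - 1L, 1L))])
  t_up <- 0.5 * (tt[iup] + tt[iup + 1L])
  dvdt_up <- dvdt[iup]
  apd <- function(x) {
    lev <- peak - (x / 100) * apa
    tc <- last_crossing_down(tt, vv, lev, from = ipk)
    if (is.na(tc)) NA_real_ else tc - t_up
  }
  apd20 <- apd(20); apd30 <- apd(30); apd50 <- apd(50); apd90 <- apd(90)
  # diastolic dV/dt: from the 95% repolarization crossing to the beat end;
  # if late depolarization carries V back above the level for good (so no
  # "last" crossing exists), the first crossing opens the window instead
  t95 <- last_crossing_down(tt, vv, peak - 0.95 * apa, from = ipk)
  if (is.na(t95)) t95 <- first_crossing_down(tt, vv, peak - 0.95 * apa,
                                             from = ipk)
  dvdt_dia <- NA_real_
  if (!is.na(t95)) {
    sel <- which(tt[-length(tt)] >= t95)
    if (length(sel)) dvdt_dia <- max(dvdt[sel])
  }
  structure(list(rmp = rmp, apa = apa, peak = peak, apd20 = apd20,
                 apd30 = apd30, apd50 = apd50, apd90 = apd90,
                 dvdt_max_upstroke = dvdt_up, dvdt_max_diastolic = dvdt_dia,
                 triangulation = if (is.na(apd90) || is.na(apd30)) NA_real_
                                 else apd90 - apd30,
                 capture = TRUE),
            class = "ap_features")
}

# APD90 of each of the last `n` recorded beats
last_apd90s <- function(trace, n = 3) {
  beats <- seq(trace$n_beats - n + 1L, trace$n_beats)
  vapply(beats, function(b) extract_features(trace, b)$apd90, numeric(1))
}

# max diastolic dV/dt over all recorded beats (B1 / self-stimulation)
max_diastolic_dvdt <- function(trace) {
  d <- vapply(seq_len(trace$n_beats), function(b)
    extract_features(trace, b)$dvdt_max_diastolic, numeric(1))
  if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
}

# alternans rule: one of the last-3 APD90s deviates > frac from BOTH others
alternans_flag <- function(apd90s, frac) {
  if (any(is.na(apd90s))) return(FALSE)
  for (i in 1:3) {
    others <- apd90s[-i]
    if (all(abs(apd90s[i] - others) / others > frac)) return(TRUE)
  }
  FALSE
}

# EAD detector on the last beat: positive dV/dt above `thr` sustained for
# >= min_dur ms inside the late-repolarization window (from the last
# crossing of `window_frac` repolarization to the APD90 crossing or beat
# end). The window start skips the spike-notch-dome morphology, whose
# physiological dome rise is not an EAD.
ead_flag <- function(trace, thr, min_dur, window_frac) {
  w <- beat_window(trace, trace$n_beats)
  tt <- trace$t[w]; vv <- trace$v[w]
  ipk <- which.max(vv)
  peak <- vv[ipk]
  f <- extract_features(trace, trace$n_beats)
  if (!f$capture) return(FALSE)
  lev_open <- peak - window_frac * f$apa
  t_open <- last_crossing_down(tt, vv, lev_open, from = ipk)
  if (is.na(t_open)) return(FALSE)
  t_close <- last_crossing_down(tt, vv, peak - 0.90 * f$apa, from = ipk)
  if (is.na(t_close)) t_close <- tt[length(tt)]
  sel <- which(tt[-length(tt)] >= t_open & tt[-length(tt)] < t_close)
  if (length(sel) < 2) return(FALSE)
  dvdt <- diff(vv) / diff(tt)
  runs <- rle(dvdt[sel] > thr)
  any(runs$values & runs$lengths * trace$dt >= min_dur)
}

#' Detect the eight instability biomarker events on a drugged trace
#'
#' Applies detectors B1-B8 to the recorded beats of `drug_trace`:
#' B1 diastolic depolarization (max diastolic dV/dt above threshold),
#' B2 APD90 prolongation beyond 20% of the cell's drug-free APD90,
#' B3 elevated resting potential, B4 low peak, B5 high peak,
#' B6 alternans over the last 3 beats, B7 EAD on the last beat,
#' B8 triangulation (APD90 - APD30) above threshold.
#' All inequalities are strict. A captured beat whose voltage never
#' repolarizes to the 90% level counts as prolonged (B2).
#'
#' @param drug_trace `ap_trace` with >= 3 recorded beats.
#' @param baseline_apd90 The same cell's drug-free APD90 (ms), > 0.
#' @param thresholds [detector_thresholds()].
#' @return Named logical vector `b1`..`b8` (class `event_flags`).
#' @export
detect_events <- function(drug_trace, baseline_apd90,
                          thresholds = detector_thresholds()) {
  if (drug_trace$n_beats < 3) stop("trace must have >= 3 recorded beats")
  if (!is.finite(baseline_apd90) || baseline_apd90 <= 0)
    stop("baseline_apd90 must be a positive number")
  th <- thresholds
  f <- extract_features(drug_trace, drug_trace$n_beats)
  dvdt_dia <- max_diastolic_dvdt(drug_trace)
  b1 <- !is.na(dvdt_dia) && dvdt_dia > th$b1_dvdt
  b2 <- if (f$capture && is.na(f$apd90)) TRUE
        else !is.na(f$apd90) &&
             (f$apd90 - baseline_apd90) / baseline_apd90 > th$b2_prolongation
  b3 <- f$rmp > th$b3_rmp
  b4 <- f$peak < th$b4_peak
  b5 <- f$peak > th$b5_peak
  b6 <- alternans_flag(last_apd90s(drug_trace, 3), th$b6_alternans)
  b7 <- ead_flag(drug_trace, th$b7_ead_dvdt, th$b7_min_duration,
                 th$b7_window_frac)
  b8 <- !is.na(f$triangulation) && f$triangulation > th$b8_triangulation
  structure(setNames(c(b1, b2, b3, b4, b5, b6, b7, b8), BIOMARKER_NAMES),
            class = "event_flags")
}

#' Net ionic charge over one beat (qNet)
#'
#' Trapezoidal integral of ICaL + INaL + IKr + IKs + IK1 + Ito over one
#' beat, outward positive, in uC/uF. The source text computes qNet at the
#' cellular level without printing a formula; this is the standard CiPA
#' definition and is flagged as an interpretation.
#'
#' @param t Time grid (ms) covering exactly one beat.
#' @param currents Matrix with (at least) columns `ICaL`, `INaL`, `IKr`,
#'   `IKs`, `IK1`, `Ito` in uA/uF, rows matching `t`.
#' @return Charge in uC/uF.
#' @export
qnet <- function(t, currents) {
  need <- c("ICaL", "INaL", "IKr", "IKs", "IK1", "Ito")
  if (is.null(colnames(currents)) || !all(need %in% colnames(currents)))
    stop("currents must have columns ", paste(need, collapse = ", "))
  if (nrow(currents) != length(t)) stop("time grid and currents mismatch")
  inet <- rowSums(currents[, need, drop = FALSE])
  # trapezoid; uA/uF * ms = 1e-3 uC/uF
  sum(diff(t) * (head(inet, -1) + tail(inet, -1)) / 2) / 1000
}

#' qNet of the last recorded beat of a trace
#'
#' @param trace `ap_trace` recorded with `record_currents = TRUE`.
#' @return Charge in uC/uF.
#' @export
qnet_trace <- function(trace) {
  if (is.null(trace$currents)) stop("trace has no recorded currents")
  w <- beat_window(trace, trace$n_beats)
  cur <- trace$currents[w, , drop = FALSE]
  colnames(cur) <- as.character(ord_current_names_cpp())
  qnet(trace$t[w], cur)
}
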