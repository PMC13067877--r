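#' Cell-level biomarker flags for one drug over a population
#'
#' For every accepted model: applies the pore-block scaling at each
#' concentration multiple, re-paces from the model's drug-free end state
#' (`drug_beats` beats, so the drugged limit is approached without
#' repeating the full pre-pacing), and runs the eight detectors against the
#' model's own drug-free APD90. The B8 triangulation threshold defaults to
#' the population's drug-free 95th percentile.
#'
#' @param pop `population_set` built with `keep_states = TRUE`.
#' @param drug Compound (name, record or library row).
#' @param multiples Concentration grid (default 1, 3, 10, 30, 100 x EFTPC).
#' @param drug_beats Paced beats under drug before the recorded window.
#' @param thresholds [detector_thresholds()]; a non-finite
#'   `b8_triangulation` is replaced by the population default.
#' @param protocol Pacing protocol for the drugged runs; defaults to the
#'   population's protocol with `n_beats = drug_beats`.
#' @return Logical array `[n_accepted, 8, n_multiples]`.
#' @export
drug_event_flags <- function(pop, drug, multiples = c(1, 3, 10, 30, 100),
                             drug_beats = 20,
                             thresholds = detector_thresholds(),
                             protocol = NULL) {
  acc <- accepted_models(pop)
  if (!length(acc$idx)) stop("population has no accepted models")
  if (is.null(acc$states) || any(vapply(acc$states, is.null, logical(1))))
    stop("population must be built with keep_states = TRUE")
  if (!is.finite(thresholds$b8_triangulation))
    thresholds$b8_triangulation <- pop$b8_triangulation
  if (is.null(protocol)) {
    protocol <- pop$protocol
    protocol$n_beats <- max(drug_beats, protocol$n_recorded_beats)
  }
  rec <- as_drug_record(drug)
  n <- length(acc$idx)
  out <- array(FALSE, c(n, 8, length(multiples)),
               dimnames = list(NULL, BIOMARKER_NAMES, NULL))
  for (i in seq_len(n)) {
    g0 <- conductance_scaling()
    g0[colnames(acc$scales)] <- acc$scales[i, ]
    base_apd90 <- acc$features$apd90[i]
    for (k in seq_along(multiples)) {
      g <- apply_drug(g0, rec, multiples[k])
      tr <- tryCatch(
        run_single_cell(g, protocol, initial = acc$states[[i]],
                        drift_guard = FALSE),
        error = function(e) NULL)
      if (is.null(tr)) { out[i, , k] <- TRUE; next } # numerical blow-up
      if (!tr$capture) { out[i, "b4", k] <- TRUE; next }
      out[i, , k] <- as.logical(detect_events(tr, base_apd90, thresholds))
    }
  }
  out
}

#' Run a full drug panel on a population (isolated-cell mode)
#'
#' Convenience wrapper: [drug_event_flags()] for every library compound,
#' aggregated to event matrices and scored with [score_drug_panel()].
#'
#' @inheritParams drug_event_flags
#' @param lib [drug_library()].
#' @return List: `flags` (per drug), `event_matrices`, `risk`
#'   (`risk_result`).
#' @export
run_drug_panel <- function(pop, lib = drug_library(),
                           multiples = c(1, 3, 10, 30, 100),
                           drug_beats = 20,
                           thresholds = detector_thresholds()) {
  flags <- lapply(seq_len(nrow(lib)), function(d)
    drug_event_flags(pop, lib[d, ], multiples, drug_beats, thresholds))
  names(flags) <- lib$name
  ems <- lapply(flags, event_matrix_from_flags)
  n_cells <- dim(flags[[1]])[1]
  risk <- score_drug_panel(ems, n_cells, setNames(lib$true_class, lib$name),
                           multiples)
  list(flags = flags, event_matrices = ems, risk = risk)
}

#' Event CSV dialect: one row per (drug, concentration multiple, cell)
#'
#' Columns `drug`, `concentration_multiple`, `cell`, `b1`..`b8` (0/1).
#' [read_event_csv()] reconstructs the per-drug flag arrays.
#'
#' @param flags_list Per-drug list of `[cells, 8, n_conc]` flag arrays.
#' @param multiples Concentration multiples matching dim 3.
#' @param file Output path.
#' @export
write_event_csv <- function(flags_list, multiples, file) {
  rows <- lapply(names(flags_list), function(d) {
    fl <- flags_list[[d]]
    do.call(rbind, lapply(seq_along(multiples), function(k) {
      data.frame(drug = d, concentration_multiple = multiples[k],
                 cell = seq_len(dim(fl)[1]),
                 as.data.frame(fl[, , k] * 1L))
    }))
  })
  df <- do.call(rbind, rows)
  names(df)[4:11] <- BIOMARKER_NAMES
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_event_csv
#' @return For `read_event_csv()`: list with `flags` (per-drug arrays) and
#'   `multiples`.
#' @export
read_event_csv <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("drug", "concentration_multiple", "cell", BIOMARKER_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event CSV missing column(s): ", paste(miss, collapse = ", "))
  multiples <- sort(unique(df$concentration_multiple))
  drugs <- unique(df$drug)
  flags <- lapply(drugs, function(d) {
    sub <- df[df$drug == d, ]
    cells <- sort(unique(sub$cell))
    arr <- array(FALSE, c(length(cells), 8, length(multiples)),
                 dimnames = list(NULL, BIOMARKER_NAMES, NULL))
    for (k in seq_along(multiples)) {
      sk <- sub[sub$concentration_multiple == multiples[k], ]
      sk <- sk[order(sk$cell), ]
      arr[, , k] <- as.matrix(sk[, BIOMARKER_NAMES]) > 0
    }
    arr
  })
  names(flags) <- drugs
  list(flags = flags, multiples = multiples)
}

#' Serialize a risk result
#'
#' JSON report: probabilities, weights, scores, thresholds, predictions,
#' metrics and the concentration-weight variant in force.
#'
#' @param risk `risk_result`. @param file Output path.
#' @export
write_risk_result <- function(risk, file) {
  out <- list(
    variant = risk$variant,
    weights_method = risk$weights_method,
    probabilities = as.data.frame(risk$P),
    weights = as.list(risk$weights),
    scores = as.list(risk$scores),
    thresholds = list(l = risk$l, h = risk$h),
    predicted = as.list(setNames(risk$predicted, names(risk$scores))),
    labels = risk$labels,
    metrics = list(f1 = as.list(risk$metrics$f1),
                   macro_f1 = risk$metrics$macro_f1,
                   accuracy = risk$metrics$accuracy),
    binary = as.list(risk$binary))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
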