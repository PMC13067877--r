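# shared test utilities: cached paced runs (the baseline limit cycle is
# reused by several files) and hand-built traces

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

baseline_amp <- function() cached("amp", find_stimulus_amplitude())

baseline_trace <- function(n_beats = 40) {
  cached(paste0("base", n_beats),
         run_single_cell(protocol = pacing_protocol(
           n_beats = n_beats, stim_amplitude = baseline_amp())))
}

quick_protocol <- function(n_beats = 25, ...) {
  pacing_protocol(n_beats = n_beats, stim_amplitude = baseline_amp(), ...)
}

# an ap_trace built directly from a voltage vector (square pulses etc.)
manual_trace <- function(v, dt, bcl) {
  n_per <- round(bcl / dt)
  n_beats <- length(v) / n_per
  structure(list(t = (seq_along(v) - 1) * dt, v = v,
                 beat_start_idx = 1L + (seq_len(n_beats) - 1L) * n_per,
                 dt = dt, bcl = bcl, n_beats = n_beats,
                 stim = list(amplitude = NA_real_, duration = 0),
                 scaling = NULL, final_state = NULL, currents = NULL,
                 capture = max(v) > 0),
            class = "ap_trace")
}

normalize_labels_for_test <- function(x)
  unname(c(low = 0L, borderline = 1L, high = 2L)[x])

# planted two-drug Bernoulli pool for robustness tests (large enough that
# subsamples up to 400 cells stay a small fraction of the pool)
bernoulli_pool <- function(n_cells = 8000, q = c(0.1, 0.3), seed = 42) {
  cached(paste("pool", n_cells, paste(q, collapse = "_"), seed, sep = "_"), {
    probs <- array(0, c(length(q), 8, 5))
    for (d in seq_along(q)) probs[d, , ] <- q[d]
    dimnames(probs) <- list(paste0("drug", seq_along(q)), NULL, NULL)
    make_planted_events(planted_population_spec(
      n_cells, probs, setNames(seq_along(q) - 1L, rownames(probs)),
      seed = seed))
  })
}
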