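# Shared fixtures: published parameter specs, standard drives, and a
# memoized baseline trajectory (computed once per test run).

table1_spec <- function(...) cpg_spec(...)

forward_drive <- function(strength = 1.7, duration = 2, onset = 0) {
  drive_protocol(segment = 8, strength = strength, onset = onset,
                 duration = duration)
}

backward_drive <- function(strength = 1.7, duration = 2) {
  drive_protocol(segment = 1, strength = strength, duration = duration)
}

two_sided_drive <- function(duration = 35) {
  drive_protocol(segment = c(8, 8), strength = c(1.7, 1.72),
                 onset = 0, duration = duration,
                 side = c("left", "right"))
}

baseline_trajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cpg(table1_spec(), forward_drive(), t_end = 12)
    cache
  }
})

# hand-built trajectory from an explicit excitatory activity matrix
# (rows = time points, cols = segments); I populations set to zero
synthetic_trajectory <- function(time, E, spec = cpg_spec()) {
  n <- spec$n_segments
  stopifnot(ncol(E) == n)
  tb <- tibble::tibble(time = time)
  for (i in seq_len(n)) tb[[paste0("E", i)]] <- E[, i]
  for (i in seq_len(n)) tb[[paste0("I", i)]] <- 0
  attr(tb, "spec") <- spec
  attr(tb, "protocol") <- drive_protocol(segment = 8, strength = 1.7,
                                         duration = 2)
  attr(tb, "settings") <- solver_settings()
  class(tb) <- c("cpg_trajectory", class(tb))
  tb
}

# synthetic single-wave contraction table with given onsets/offsets
synthetic_contractions <- function(onsets, offsets, threshold = 0.3) {
  tb <- tibble::tibble(segment = seq_along(onsets), onset = onsets,
                       offset = offsets,
                       truncated_onset = FALSE, truncated_offset = FALSE)
  attr(tb, "threshold") <- threshold
  attr(tb, "side") <- "only"
  attr(tb, "n_segments") <- length(onsets)
  class(tb) <- c("cpg_contractions", class(tb))
  tb
}
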