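# Wave quantification: contraction intervals at a threshold, normalized
# durations, intersegmental phase lags, validity classification, wave
# counting, onset delay, and left/right synchrony.

# threshold crossings of one series, refined by linear interpolation.
# Samples lying exactly on the threshold count as crossings at that sample
# time. Returns a tibble of (onset, offset, truncated_onset,
# truncated_offset); intervals clipped by the trajectory boundaries are
# flagged truncated.
series_crossings <- function(time, x, threshold) {
  above <- x >= threshold
  if (!any(above))
    return(tibble(onset = numeric(), offset = numeric(),
                  truncated_onset = logical(), truncated_offset = logical()))
  n <- length(x)
  interp <- function(i) {
    # crossing between samples i-1 and i
    if (x[i] == threshold) return(time[i])
    if (x[i - 1] == threshold) return(time[i - 1])
    time[i - 1] + (threshold - x[i - 1]) * (time[i] - time[i - 1]) /
      (x[i] - x[i - 1])
  }
  d <- diff(above)
  ups <- which(d == 1) + 1   # first index above
  downs <- which(d == -1) + 1  # first index below
  onsets <- vapply(ups, interp, numeric(1))
  offsets <- vapply(downs, interp, numeric(1))
  t_on <- rep(FALSE, length(onsets))
  t_off <- rep(FALSE, length(offsets))
  if (above[1]) {
    onsets <- c(time[1], onsets)
    t_on <- c(TRUE, t_on)
  }
  if (above[n]) {
    offsets <- c(offsets, time[n])
    t_off <- c(t_off, TRUE)
  }
  tibble(onset = onsets, offset = offsets,
         truncated_onset = t_on, truncated_offset = t_off)
}

# restrict a trajectory to rows with time >= from, preserving attributes
window_trajectory <- function(trajectory, from) {
  if (is.null(from) || from <= min(trajectory$time)) return(trajectory)
  keep <- trajectory$time >= from
  out <- trajectory[keep, ]
  for (a in c("spec", "protocol", "settings"))
    attr(out, a) <- attr(trajectory, a)
  class(out) <- class(trajectory)
  out
}

#' Extract suprathreshold contraction intervals
#'
#' A model "contraction" of a segment is an interval of excitatory activity
#' above the contraction threshold \eqn{\theta_C}. Crossing times are
#' refined by linear interpolation between adjacent samples; intervals
#' clipped by the trajectory boundaries are flagged truncated.
#'
#' @param trajectory A [simulate_cpg()] trajectory.
#' @param threshold Contraction threshold \eqn{\theta_C} in (0, 1). The
#'   published analyses use 0.3, falling back to 0.2 in high-inhibition
#'   two-sided regimes where activity stays below 0.3.
#' @param side For two-sided trajectories, `"left"` or `"right"`.
#' @param from Optional time before which samples are discarded (transient
#'   removal).
#' @return A tibble of class \code{cpg_contractions} with columns
#'   `segment`, `onset`, `offset`, `truncated_onset`, `truncated_offset`
#'   (zero or more rows per segment), carrying `threshold`, `side` and
#'   `n_segments` as attributes.
#' @export
contraction_intervals <- function(trajectory, threshold, side = NULL,
                                  from = NULL) {
  if (nrow(trajectory) == 0) abort("empty trajectory")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1)")
  trajectory <- window_trajectory(trajectory, from)
  spec <- attr(trajectory, "spec")
  cols <- excitatory_columns(trajectory, side)
  res <- purrr::imap(cols, function(col, i) {
    mutate(series_crossings(trajectory$time, trajectory[[col]], threshold),
           segment = i, .before = 1)
  })
  out <- bind_rows(res)
  attr(out, "threshold") <- threshold
  attr(out, "side") <- side %||% "only"
  attr(out, "n_segments") <- spec$n_segments
  class(out) <- c("cpg_contractions", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# keep table attributes through subsetting
rewrap_contractions <- function(new, old) {
  for (a in c("threshold", "side", "n_segments"))
    attr(new, a) <- attr(old, a)
  if (!inherits(new, "cpg_contractions"))
    class(new) <- c("cpg_contractions", class(new))
  new
}

check_single_wave <- function(table) {
  n <- attr(table, "n_segments")
  counts <- table(factor(table$segment, levels = seq_len(n)))
  if (any(counts != 1))
    abort(paste0(
      "each segment must have exactly one contraction interval ",
      "(segments with 0 or >1: ",
      paste(which(counts != 1), collapse = ", "),
      "); for multi-wave trajectories use count_waves()"))
  invisible(table)
}

wave_span <- function(table, direction) {
  n <- attr(table, "n_segments")
  init <- if (direction == "forward") n else 1L
  term <- if (direction == "forward") 1L else n
  start <- min(table$onset[table$segment == init])
  end <- max(table$offset[table$segment == term])
  c(start = start, end = end)
}

#' Normalized contraction durations of a single wave
#'
#' Each segment's contraction duration divided by the total wave duration,
#' where the wave duration runs from the contraction onset of the
#' initiating segment to the contraction offset of the terminal segment
#' (A8 onset to A1 offset for a forward wave).
#'
#' @param table A [contraction_intervals()] result with exactly one
#'   interval per segment.
#' @param direction `"forward"` (initiated at the posterior segment) or
#'   `"backward"`.
#' @return A tibble with columns `segment`, `onset`, `offset`, `duration`,
#'   `normalized_duration`, carrying `wave_duration` and `direction` as
#'   attributes.
#' @export
normalized_durations <- function(table, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "cpg_contractions"))
  check_single_wave(table)
  span <- wave_span(table, direction)
  wd <- span[["end"]] - span[["start"]]
  out <- table |>
    arrange(.data$segment) |>
    mutate(duration = .data$offset - .data$onset,
           normalized_duration = .data$duration / wd) |>
    select("segment", "onset", "offset", "duration", "normalized_duration")
  attr(out, "wave_duration") <- wd
  attr(out, "direction") <- direction
  out
}

#' Intersegmental phase lags of a single wave
#'
#' The time from the contraction onset of one segment to the onset of the
#' next segment in the propagation direction, divided by the wave
#' duration. Returned in propagation order: A8 to A7 first for a forward
#' wave, A1 to A2 first for a backward one.
#'
#' @inheritParams normalized_durations
#' @return A tibble with columns `from_segment`, `to_segment`, `lag`
#'   (`n_segments - 1` rows), with `wave_duration` and `direction`
#'   attributes.
#' @export
intersegmental_phase_lags <- function(table,
                                      direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "cpg_contractions"))
  check_single_wave(table)
  n <- attr(table, "n_segments")
  span <- wave_span(table, direction)
  wd <- span[["end"]] - span[["start"]]
  ord <- if (direction == "forward") seq(n, 1) else seq(1, n)
  onsets <- table$onset[match(ord, table$segment)]
  out <- tibble(from_segment = ord[-n], to_segment = ord[-1],
                lag = diff(onsets) / wd)
  attr(out, "wave_duration") <- wd
  attr(out, "direction") <- direction
  out
}

#' Classify a wave as valid or invalid
#'
#' A valid propagating wave activates every segment above threshold in
#' propagation order and deactivates them in the same order. The
#' `"strict"` rule requires both onsets and offsets fully ordered; the
#' `"endpoint_relaxed"` rule additionally accepts the terminal segment
#' deactivating before its neighbour (in simulations without sensory
#' feedback the most anterior segment always deactivates before its
#' posterior neighbour, so the published robustness criterion relaxes that
#' final pair).
#'
#' @inheritParams normalized_durations
#' @param rule `"strict"` or `"endpoint_relaxed"`.
#' @return A one-row tibble with columns `valid` (logical), `reason`
#'   (character, `NA` when valid), `rule`, `direction`.
#' @export
classify_wave <- function(table, direction = c("forward", "backward"),
                          rule = c("strict", "endpoint_relaxed")) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  stopifnot(inherits(table, "cpg_contractions"))
  n <- attr(table, "n_segments")
  result <- function(valid, reason = NA_character_)
    tibble(valid = valid, reason = reason, rule = rule,
           direction = direction)
  counts <- table(factor(table$segment, levels = seq_len(n)))
  if (any(counts == 0)) return(result(FALSE, "missing segment"))
  if (any(counts > 1)) return(result(FALSE, "multiple intervals"))
  ord <- if (direction == "forward") seq(n, 1) else seq(1, n)
  idx <- match(ord, table$segment)
  onsets <- table$onset[idx]
  offsets <- table$offset[idx]
  if (any(table$truncated_onset) || any(table$truncated_offset))
    return(result(FALSE, "truncated interval"))
  if (any(diff(onsets) <= 0)) return(result(FALSE, "onset order"))
  off_diffs <- diff(offsets)
  required <- if (rule == "strict") off_diffs else head(off_diffs, -1)
  if (any(required <= 0)) return(result(FALSE, "offset order"))
  result(TRUE)
}

#' Count complete propagating waves in a trajectory
#'
#' A wave is counted for each suprathreshold excursion of the initiating
#' segment (A8 for forward waves) that is followed by threshold crossings
#' of every remaining segment, in propagation order, before the initiating
#' segment's next excursion. Excursions whose propagation is incomplete
#' contribute no wave. Under very strong sustained drive the initiating
#' segment stays continuously active; this counts as a single wave and the
#' prolonged initiating interval is flagged.
#'
#' @inheritParams contraction_intervals
#' @param direction `"forward"` or `"backward"`.
#' @return An object of class \code{cpg_wave_count}: a list with
#'   `n_waves`, `waves` (a list of single-wave \code{cpg_contractions}
#'   tables), `prolonged` (logical per wave: initiating segment still
#'   active after the terminal segment deactivated), `direction`,
#'   `threshold`.
#' @export
count_waves <- function(trajectory, threshold,
                        direction = c("forward", "backward"),
                        side = NULL, from = NULL) {
  direction <- match.arg(direction)
  tab <- contraction_intervals(trajectory, threshold, side = side,
                               from = from)
  n <- attr(tab, "n_segments")
  ord <- if (direction == "forward") seq(n, 1) else seq(1, n)
  init <- ord[1]
  # per-segment candidate excursions (well-defined onsets), sorted; plain
  # vectors for speed in the matching loop
  cand_rows <- lapply(seq_len(n), function(seg) {
    idx <- which(tab$segment == seg & !tab$truncated_onset)
    idx[order(tab$onset[idx])]
  })
  cand_onsets <- lapply(cand_rows, function(idx) tab$onset[idx])
  init_onsets <- cand_onsets[[init]]
  waves <- list()
  wave_starts <- numeric()
  for (k in seq_along(init_onsets)) {
    window_end <- if (k < length(init_onsets)) init_onsets[k + 1] else Inf
    picked <- c(cand_rows[[init]][k])
    prev_onset <- init_onsets[k]
    ok <- TRUE
    for (seg in ord[-1]) {
      ons <- cand_onsets[[seg]]
      j <- which(ons > prev_onset & ons < window_end)
      if (length(j) == 0) { ok <- FALSE; break }
      picked <- c(picked, cand_rows[[seg]][j[1]])
      prev_onset <- ons[j[1]]
    }
    if (ok) {
      waves <- c(waves, list(rewrap_contractions(tab[picked, ], tab)))
      wave_starts <- c(wave_starts, init_onsets[k])
    }
  }
  # the initiating segment counts as prolonged when its suprathreshold
  # activity before the next counted wave outlasts the terminal segment
  # (under strong sustained drive it stays active long after the wave)
  init_all_on <- tab$onset[tab$segment == init]
  init_all_off <- tab$offset[tab$segment == init]
  prolonged <- vapply(seq_along(waves), function(j) {
    upper <- if (j < length(waves)) wave_starts[j + 1] else Inf
    term_off <- waves[[j]]$offset[waves[[j]]$segment == ord[n]]
    sel <- init_all_on >= wave_starts[j] & init_all_on < upper
    max(init_all_off[sel]) > term_off
  }, logical(1))
  structure(list(n_waves = length(waves), waves = waves,
                 prolonged = prolonged, direction = direction,
                 threshold = threshold),
            class = "cpg_wave_count")
}

#' @export
print.cpg_wave_count <- function(x, ...) {
  cat(sprintf("<cpg_wave_count> %d %s wave(s) at threshold %g\n",
              x$n_waves, x$direction, x$threshold))
  invisible(x)
}

#' Delay between drive onset and wave onset
#'
#' The time from the onset of a single drive pulse to the first threshold
#' crossing of the driven segment's excitatory population. Returns `NA`
#' when no complete wave is generated.
#'
#' @inheritParams contraction_intervals
#' @param protocol The single-pulse [drive_protocol()] used for the
#'   simulation.
#' @return A single number (t.u.) or `NA`.
#' @export
wave_onset_delay <- function(trajectory, protocol, threshold) {
  stopifnot(inherits(protocol, "drive_protocol"), nrow(protocol) == 1)
  spec <- attr(trajectory, "spec")
  seg <- protocol$segment[1]
  side <- if (protocol$side[1] == "only") NULL else protocol$side[1]
  direction <- if (seg == spec$n_segments) "forward" else "backward"
  cw <- count_waves(trajectory, threshold, direction, side = side)
  if (cw$n_waves == 0) return(NA_real_)
  first_onset <- min(cw$waves[[1]]$onset[cw$waves[[1]]$segment == seg])
  first_onset - protocol$onset[1]
}

#' Single-wave metrics
#'
#' Convenience wrapper computing, for a trajectory containing one wave:
#' the contraction table at `threshold`, validity classification,
#' normalized durations, intersegmental phase lags and the wave duration.
#'
#' @inheritParams contraction_intervals
#' @inheritParams classify_wave
#' @param x A \code{cpg_trajectory} or a single-wave
#'   \code{cpg_contractions} table.
#' @param ... Passed to [contraction_intervals()] when `x` is a
#'   trajectory.
#' @return An object of class \code{cpg_wave_metrics}: a list with
#'   `direction`, `threshold`, `valid`, `reason`, `wave_duration`,
#'   `durations` (tibble) and `lags` (tibble). Use [tidy()] for a
#'   per-segment table and [glance()] for a one-row summary.
#' @export
wave_metrics <- function(x, threshold = NULL,
                         direction = c("forward", "backward"),
                         rule = c("strict", "endpoint_relaxed"), ...) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  tab <- if (inherits(x, "cpg_contractions")) x
         else contraction_intervals(x, threshold, ...)
  cls <- classify_wave(tab, direction, rule)
  n <- attr(tab, "n_segments")
  single <- all(table(factor(tab$segment, levels = seq_len(n))) == 1)
  dur <- lag <- NULL
  wd <- NA_real_
  if (single) {
    dur <- normalized_durations(tab, direction)
    lag <- intersegmental_phase_lags(tab, direction)
    wd <- attr(dur, "wave_duration")
  }
  structure(list(direction = direction, threshold = attr(tab, "threshold"),
                 valid = cls$valid, reason = cls$reason, rule = rule,
                 wave_duration = wd, durations = dur, lags = lag),
            class = "cpg_wave_metrics")
}

#' @export
print.cpg_wave_metrics <- function(x, ...) {
  cat(sprintf("<cpg_wave_metrics> %s wave at threshold %g: %s\n",
              x$direction, x$threshold,
              if (x$valid) "valid" else paste0("invalid (", x$reason, ")")))
  if (!is.null(x$durations))
    cat(sprintf(
      "  wave duration %.3f t.u.; mean normalized duration %.3f; mean phase lag %.3f\n",
      x$wave_duration, mean(x$durations$normalized_duration),
      mean(x$lags$lag)))
  invisible(x)
}

#' @export
tidy.cpg_wave_metrics <- function(x, ...) {
  if (is.null(x$durations))
    return(tibble(segment = integer(), onset = numeric(), offset = numeric(),
                  duration = numeric(), normalized_duration = numeric(),
                  lag_to_next = numeric()))
  lag_map <- setNames(x$lags$lag, x$lags$from_segment)
  x$durations |>
    mutate(lag_to_next = unname(lag_map[as.character(.data$segment)]))
}

#' @export
glance.cpg_wave_metrics <- function(x, ...) {
  tibble(direction = x$direction, threshold = x$threshold, valid = x$valid,
         reason = x$reason, wave_duration = x$wave_duration,
         mean_normalized_duration =
           if (is.null(x$durations)) NA_real_
           else mean(x$durations$normalized_duration),
         mean_phase_lag = if (is.null(x$lags)) NA_real_
                          else mean(x$lags$lag))
}

#' @export
tidy.cpg_wave_count <- function(x, ...) {
  if (x$n_waves == 0)
    return(tibble(wave = integer(), valid = logical(),
                  wave_duration = numeric(),
                  mean_normalized_duration = numeric(),
                  mean_phase_lag = numeric(), prolonged = logical()))
  bind_rows(lapply(seq_along(x$waves), function(k) {
    m <- wave_metrics(x$waves[[k]], direction = x$direction)
    tibble(wave = k, valid = m$valid, wave_duration = m$wave_duration,
           mean_normalized_duration = mean(m$durations$normalized_duration),
           mean_phase_lag = mean(m$lags$lag), prolonged = x$prolonged[k])
  }))
}

#' Left/right synchrony of a two-sided trajectory
#'
#' After discarding an initial transient, matches the k-th suprathreshold
#' excursion of each segment's left and right excitatory populations and
#' averages the absolute onset-time differences across all matched pairs.
#' Classification: `"synchronous"` when every excursion is matched and the
#' mean difference is at most `sync_tolerance`; `"alternating"` when each
#' side's excursions fall inside the other side's subthreshold gaps (no
#' overlap); `"asynchronous"` otherwise; `"no_wave"` when either side is
#' silent. Results with mean difference above `discard_above` are marked
#' `discarded` (the published phase diagrams grey such cells out).
#'
#' @inheritParams contraction_intervals
#' @param transient_cut Time before which activity is ignored; defaults to
#'   all but the final 9 t.u. of the trajectory.
#' @param sync_tolerance Maximum mean onset difference (t.u.) for the
#'   `"synchronous"` class (default 0.1).
#' @param discard_above Mean onset difference (t.u.) above which the
#'   result is flagged discarded (default 1).
#' @return A one-row tibble of class \code{cpg_sync} with columns
#'   `mean_onset_difference`, `classification`, `discarded`, `n_matched`,
#'   `n_unmatched`.
#' @export
left_right_sync <- function(trajectory, threshold, transient_cut = NULL,
                            sync_tolerance = 0.1, discard_above = 1.0) {
  spec <- attr(trajectory, "spec")
  if (!is_two_sided(spec)) abort("`trajectory` must be two-sided")
  if (is.null(transient_cut)) transient_cut <- max(trajectory$time) - 9
  if (transient_cut >= max(trajectory$time))
    abort("`transient_cut` must be smaller than the trajectory span")
  tabs <- lapply(c("left", "right"), function(s) {
    tab <- contraction_intervals(trajectory, threshold, side = s,
                                 from = transient_cut)
    # an excursion without a threshold crossing (tonically suprathreshold
    # activity clipped by the analysis window) has no defined onset and
    # cannot count as a wave
    filter(tab, !.data$truncated_onset)
  })
  names(tabs) <- c("left", "right")
  result <- function(mean_diff, class, matched, unmatched)
    structure(tibble(mean_onset_difference = mean_diff,
                     classification = class,
                     discarded = !is.na(mean_diff) &
                       mean_diff > discard_above,
                     n_matched = matched, n_unmatched = unmatched),
              class = c("cpg_sync", class(tibble())))
  if (nrow(tabs$left) == 0 || nrow(tabs$right) == 0)
    return(result(NA_real_, "no_wave", 0L, 0L))
  n <- spec$n_segments
  diffs <- c()
  unmatched <- 0L
  overlap_free <- TRUE
  for (seg in seq_len(n)) {
    L <- filter(tabs$left, .data$segment == seg) |> arrange(.data$onset)
    R <- filter(tabs$right, .data$segment == seg) |> arrange(.data$onset)
    m <- min(nrow(L), nrow(R))
    if (m > 0)
      diffs <- c(diffs, abs(L$onset[seq_len(m)] - R$onset[seq_len(m)]))
    unmatched <- unmatched + abs(nrow(L) - nrow(R))
    if (nrow(L) > 0 && nrow(R) > 0) {
      for (i in seq_len(nrow(L)))
        if (any(L$onset[i] < R$offset & R$onset < L$offset[i]))
          overlap_free <- FALSE
    }
  }
  if (length(diffs) == 0) return(result(NA_real_, "no_wave", 0L, unmatched))
  mean_diff <- mean(diffs)
  class <- if (unmatched == 0L && mean_diff <= sync_tolerance) "synchronous"
           else if (overlap_free) "alternating"
           else "asynchronous"
  result(mean_diff, class, length(diffs), unmatched)
}

#' Write single-wave metrics to a delimited file
#'
#' One row per wave with direction, validity, wave duration, the
#' per-segment normalized durations and the per-pair phase lags, plus a
#' JSON sidecar with the machine-readable summary.
#'
#' @param metrics A \code{cpg_wave_metrics} object or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wave_metrics <- function(metrics, path) {
  if (inherits(metrics, "cpg_wave_metrics")) metrics <- list(metrics)
  rows <- bind_rows(lapply(seq_along(metrics), function(k) {
    m <- metrics[[k]]
    row <- glance(m)
    if (!is.null(m$durations)) {
      nd <- setNames(as.list(m$durations$normalized_duration),
                     paste0("norm_duration_", m$durations$segment))
      lg <- setNames(as.list(m$lags$lag),
                     paste0("lag_", m$lags$from_segment, "_",
                            m$lags$to_segment))
      row <- bind_rows(mutate(row, wave = k, !!!nd, !!!lg))
    } else row$wave <- k
    row
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rows, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
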