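# Scripted protocols: drive sweeps, intersegmental coupling grids,
# connection-noise robustness, sensory feedback sweeps, rescue runs, and
# two-sided synchrony phase diagrams. Every sweep returns a long-format
# tibble, one row per grid cell; invalid cells carry a 0 sentinel for the
# metric columns alongside a machine-readable failure reason.

default_drive <- function(spec, strength = 1.7, duration = 2, onset = 0) {
  drive_protocol(segment = spec$n_segments, strength = strength,
                 onset = onset, duration = duration)
}

# glance-style metrics of the single wave in a trajectory; 0-sentinel row
# with a reason when no valid single wave exists
cell_metrics <- function(trajectory, threshold, direction = "forward",
                         rule = "strict") {
  cw <- count_waves(trajectory, threshold, direction)
  if (cw$n_waves != 1) {
    reason <- if (cw$n_waves == 0) "no wave" else "multiple waves"
    return(tibble(valid = FALSE, reason = reason,
                  mean_normalized_duration = 0, mean_phase_lag = 0,
                  wave_duration = 0))
  }
  m <- wave_metrics(cw$waves[[1]], direction = direction, rule = rule)
  tibble(valid = m$valid,
         reason = m$reason,
         mean_normalized_duration =
           if (m$valid) mean(m$durations$normalized_duration) else 0,
         mean_phase_lag = if (m$valid) mean(m$lags$lag) else 0,
         wave_duration = if (m$valid) m$wave_duration else 0)
}

#' Drive strength/duration sweep
#'
#' Simulates a rectangular pulse to the posterior excitatory population for
#' every combination of `strengths` and `durations`, recording the wave
#' onset delay and the number of complete forward waves. Weak, short drives
#' initiate no wave; intermediate sustained drives evoke repeated waves for
#' as long as the stimulus lasts; drives stronger than about 3.1 evoke a
#' single wave regardless of duration, with a prolonged initiating
#' contraction.
#'
#' @param strengths,durations Numeric vectors of pulse strengths and
#'   durations (t.u.).
#' @param spec A [cpg_spec()] (one-sided).
#' @param threshold Contraction threshold, default 0.3.
#' @param settings A [solver_settings()].
#' @param t_extra Simulated time beyond the pulse offset (default 15 t.u.,
#'   enough to complete the last wave).
#' @return A tibble with one row per cell: `strength`, `duration`,
#'   `onset_delay` (`NA` when no wave), `n_waves`, `prolonged`.
#' @export
sweep_drive <- function(strengths, durations, spec = cpg_spec(),
                        threshold = 0.3, settings = solver_settings(),
                        t_extra = 15) {
  stopifnot(all(strengths > 0), all(durations > 0))
  grid <- tidyr::expand_grid(strength = strengths, duration = durations)
  purrr::pmap(grid, function(strength, duration) {
    protocol <- default_drive(spec, strength, duration)
    traj <- simulate_cpg(spec, protocol, t_end = duration + t_extra,
                         settings = settings)
    cw <- count_waves(traj, threshold, "forward")
    delay <- if (cw$n_waves == 0) NA_real_ else
      min(cw$waves[[1]]$onset[cw$waves[[1]]$segment ==
                                spec$n_segments]) - protocol$onset[1]
    tibble(strength = strength, duration = duration,
           onset_delay = delay,
           n_waves = cw$n_waves,
           prolonged = any(cw$prolonged))
  }) |> bind_rows()
}

#' Intersegmental coupling grid
#'
#' Varies the excitatory (`b`) and inhibitory (`d`) nearest-neighbour
#' coupling weights jointly across the whole chain, simulating one forward
#' wave per cell and recording its validity and summary metrics.
#'
#' @param b_values,d_values Numeric vectors of coupling weights (`d`
#'   signed, expected negative).
#' @param spec Base [cpg_spec()]; its chain weights are overridden per
#'   cell.
#' @param drive_strength,drive_duration Pulse applied to the posterior
#'   segment (1.7 for 1.2 t.u., the published single-wave criterion drive).
#' @param rule Validity rule for the per-cell wave (default the
#'   endpoint-relaxed criterion used by the published grid analyses).
#' @inheritParams sweep_drive
#' @return A tibble with one row per `(b, d)` cell: validity, failure
#'   reason, mean normalized duration, mean phase lag, wave duration
#'   (0-sentinels when invalid).
#' @export
sweep_intersegmental <- function(b_values, d_values, spec = cpg_spec(),
                                 drive_strength = 1.7, drive_duration = 1.2,
                                 threshold = 0.3, rule = "endpoint_relaxed",
                                 settings = solver_settings(),
                                 t_extra = 15) {
  stopifnot(length(b_values) > 0, length(d_values) > 0)
  grid <- tidyr::expand_grid(b = b_values, d = d_values)
  purrr::pmap(grid, function(b, d) {
    sp <- cpg_spec(n_segments = spec$n_segments,
                   excitatory = spec$excitatory, inhibitory = spec$inhibitory,
                   segment = spec$segment,
                   chain = chain_coupling(b, d, spec$n_segments),
                   sensory = spec$sensory)
    traj <- simulate_cpg(sp, default_drive(sp, drive_strength,
                                           drive_duration),
                         t_end = drive_duration + t_extra,
                         settings = settings)
    mutate(cell_metrics(traj, threshold, rule = rule), b = b, d = d,
           .before = 1)
  }) |> bind_rows()
}

# draw one set of per-edge weights around `mean` with sd `sigma`,
# redrawing any sample whose sign differs from the mean's (rejection, not
# clipping, so no probability mass piles up at zero)
sample_signed_weights <- function(mean, sigma, n_edges) {
  if (sigma == 0) return(rep(mean, n_edges))
  s <- sign(mean)
  if (s == 0) return(rnorm(n_edges, mean, sigma))
  vapply(seq_len(n_edges), function(i) {
    repeat {
      w <- rnorm(1, mean, sigma)
      if (sign(w) == s) return(w)
    }
  }, numeric(1))
}

#' Robustness of wave generation to connection-strength noise
#'
#' Perturbs the intersegmental weights by Gaussian noise and measures the
#' fraction of trials in which a single valid forward wave is generated
#' (drive 1.7 for 1.2 t.u., validity under the endpoint-relaxed rule, as
#' in the published robustness criterion). Weights are sampled once per
#' undirected neighbour pair and applied symmetrically by default
#' (`edge_mode = "directed"` samples each direction independently);
#' samples are redrawn until they keep the mean's sign.
#'
#' @param b_mean,d_mean Mean excitatory and inhibitory coupling weights.
#' @param sigma_b,sigma_d Noise standard deviations.
#' @param trials Number of trials (20 in the published panels).
#' @param seed Integer seed; the result is reproducible given
#'   `(grid, seed)`.
#' @param spec Base [cpg_spec()].
#' @param edge_mode `"undirected"` or `"directed"`.
#' @inheritParams sweep_drive
#' @param drive_strength,drive_duration Drive pulse (defaults 1.7, 1.2).
#' @return A list of class \code{cpg_robustness} with `fraction`
#'   (successes/trials) and `trials` (a per-trial tibble with the success
#'   flag and failure reason).
#' @export
robustness_noise <- function(b_mean, d_mean, sigma_b, sigma_d, trials = 20,
                             seed = 1, spec = cpg_spec(),
                             edge_mode = c("undirected", "directed"),
                             drive_strength = 1.7, drive_duration = 1.2,
                             threshold = 0.3, settings = solver_settings(),
                             t_extra = 15) {
  stopifnot(trials >= 1, sigma_b >= 0, sigma_d >= 0)
  edge_mode <- match.arg(edge_mode)
  n <- spec$n_segments
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- purrr::map(seq_len(trials), function(trial) {
    b <- sample_signed_weights(b_mean, sigma_b, n - 1)
    d <- sample_signed_weights(d_mean, sigma_d, n - 1)
    if (edge_mode == "directed") {
      b2 <- sample_signed_weights(b_mean, sigma_b, n - 1)
      d2 <- sample_signed_weights(d_mean, sigma_d, n - 1)
      ch <- chain_coupling(b, d, n, e_ascending = b, e_descending = b2,
                           i_ascending = d, i_descending = d2)
    } else {
      ch <- chain_coupling(b, d, n)
    }
    sp <- cpg_spec(n_segments = n, excitatory = spec$excitatory,
                   inhibitory = spec$inhibitory, segment = spec$segment,
                   chain = ch, sensory = spec$sensory)
    traj <- simulate_cpg(sp, default_drive(sp, drive_strength,
                                           drive_duration),
                         t_end = drive_duration + t_extra,
                         settings = settings)
    cw <- count_waves(traj, threshold, "forward")
    valid <- cw$n_waves == 1 &&
      classify_wave(cw$waves[[1]], "forward", "endpoint_relaxed")$valid
    reason <- if (cw$n_waves == 0) "no wave"
              else if (cw$n_waves > 1) "multiple waves"
              else if (!valid) classify_wave(cw$waves[[1]], "forward",
                                             "endpoint_relaxed")$reason
              else NA_character_
    tibble(trial = trial, success = valid, reason = reason,
           mean_b = mean(b), mean_d = mean(d))
  }) |> bind_rows()
  structure(list(fraction = mean(rows$success), trials = rows,
                 seed = seed, b_mean = b_mean, d_mean = d_mean,
                 sigma_b = sigma_b, sigma_d = sigma_d),
            class = "cpg_robustness")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cpg_robustness <- function(x, ...) {
  cat(sprintf(
    "<cpg_robustness> b=%g, d=%g, sigma=(%g, %g): %d/%d waves (%.2f)\n",
    x$b_mean, x$d_mean, x$sigma_b, x$sigma_d, sum(x$trials$success),
    nrow(x$trials), x$fraction))
  invisible(x)
}

#' Sensory feedback sweep
#'
#' Varies the sensory-to-excitatory (\eqn{\beta}) and sensory-to-inhibitory
#' (\eqn{\gamma}) weights at fixed stretch gain \eqn{\alpha}, simulating
#' one forward wave per cell (drive 1.7 for 2.5 t.u. as in the published
#' protocol) and recording validity, mean metrics, and the full phase-lag
#' profile (as a list-column) so anterior/posterior effects can be
#' examined.
#'
#' @param beta_values,gamma_values Numeric vectors of sensory weights.
#' @param alpha Stretch gain (default 25).
#' @param spec Base [cpg_spec()] (without its own sensory spec).
#' @param drive_strength,drive_duration Pulse parameters (1.7, 2.5).
#' @inheritParams sweep_drive
#' @return A tibble with one row per `(beta, gamma)` cell, including
#'   list-columns `normalized_durations` and `phase_lags`.
#' @export
sensory_sweep <- function(beta_values, gamma_values, alpha = 25,
                          spec = cpg_spec(), drive_strength = 1.7,
                          drive_duration = 2.5, threshold = 0.3,
                          settings = solver_settings(), t_extra = 15) {
  grid <- tidyr::expand_grid(beta = beta_values, gamma = gamma_values)
  purrr::pmap(grid, function(beta, gamma) {
    sp <- cpg_spec(n_segments = spec$n_segments,
                   excitatory = spec$excitatory, inhibitory = spec$inhibitory,
                   segment = spec$segment, chain = spec$chain,
                   sensory = sensory_spec(alpha, beta, gamma))
    traj <- simulate_cpg(sp, default_drive(sp, drive_strength,
                                           drive_duration),
                         t_end = drive_duration + t_extra,
                         settings = settings)
    cw <- count_waves(traj, threshold, "forward")
    base <- tibble(beta = beta, gamma = gamma, alpha = alpha)
    if (cw$n_waves != 1)
      return(mutate(base, valid = FALSE,
                    reason = if (cw$n_waves == 0) "no wave"
                             else "multiple waves",
                    mean_normalized_duration = 0, mean_phase_lag = 0,
                    wave_duration = 0,
                    normalized_durations = list(NULL),
                    phase_lags = list(NULL)))
    m <- wave_metrics(cw$waves[[1]], direction = "forward")
    mutate(base, valid = m$valid, reason = m$reason,
           mean_normalized_duration = mean(m$durations$normalized_duration),
           mean_phase_lag = mean(m$lags$lag),
           wave_duration = m$wave_duration,
           normalized_durations = list(m$durations),
           phase_lags = list(m$lags))
  }) |> bind_rows()
}

#' Sensory rescue of a failing network
#'
#' Runs a (possibly mistuned) network without and with sensory feedback
#' under matched drives, returning both metric sets. Sensory feedback can
#' restore propagating waves in networks whose intersegmental coupling is
#' too weak or inhibition too strong to generate them on their own.
#'
#' @param broken_spec A [cpg_spec()] (typically one that fails to produce
#'   a wave).
#' @param sensory A [sensory_spec()] to add in the rescue condition.
#' @param drive_strength,drive_duration Matched drive pulse.
#' @param rule Validity rule, default the endpoint-relaxed success
#'   criterion used by the robustness analyses.
#' @inheritParams sweep_drive
#' @return A two-row tibble (`condition` = "without_sensory",
#'   "with_sensory") with validity and summary metrics.
#' @export
rescue_experiment <- function(broken_spec, sensory, drive_strength = 1.7,
                              drive_duration = 1.2, threshold = 0.3,
                              rule = "endpoint_relaxed",
                              settings = solver_settings(), t_extra = 15) {
  stopifnot(inherits(sensory, "sensory_spec"))
  run <- function(sp, condition) {
    traj <- simulate_cpg(sp, default_drive(sp, drive_strength,
                                           drive_duration),
                         t_end = drive_duration + t_extra,
                         settings = settings)
    mutate(cell_metrics(traj, threshold, rule = rule),
           condition = condition, .before = 1)
  }
  with_sensory <- cpg_spec(n_segments = broken_spec$n_segments,
                           excitatory = broken_spec$excitatory,
                           inhibitory = broken_spec$inhibitory,
                           segment = broken_spec$segment,
                           chain = broken_spec$chain, sensory = sensory)
  bind_rows(run(broken_spec, "without_sensory"),
            run(with_sensory, "with_sensory"))
}

#' Two-sided synchrony sweep
#'
#' Builds the two-sided model for every combination of a contralateral
#' coupling weight and one intersegmental weight (`b` or `d`; the other is
#' held at its published value), drives the posterior segments of both
#' sides with slightly different sustained inputs (1.7 left, 1.72 right,
#' 35 t.u. -- the small asymmetry avoids trivially instantaneous
#' synchronization in a deterministic model), and classifies the
#' post-transient left/right synchrony at each requested contraction
#' threshold. Also records whether propagating waves persist
#' post-transient on the left side.
#'
#' @param kind Contralateral connection kind (`"EE"`, `"IE"`, `"EI"`,
#'   `"II"`).
#' @param contralateral_values Numeric vector of contralateral weights.
#' @param chain_axis `"b"` or `"d"`: which intersegmental weight varies.
#' @param chain_values Values for the varying intersegmental weight.
#' @param spec Base one-sided [cpg_spec()].
#' @param thresholds Contraction thresholds to classify at (default both
#'   0.3 and 0.2; high-inhibition regimes keep activity below 0.3).
#' @param drive_left,drive_right,drive_duration Sustained drive pulses.
#' @param transient_keep Length of the final analysis window, t.u.
#'   (default 9).
#' @inheritParams left_right_sync
#' @inheritParams sweep_drive
#' @return A tibble with one row per (weight, chain value, threshold):
#'   synchrony classification, mean onset difference, discard flag, and
#'   `waves_propagate`.
#' @export
two_sided_sweep <- function(kind, contralateral_values,
                            chain_axis = c("b", "d"), chain_values,
                            spec = cpg_spec(), thresholds = c(0.3, 0.2),
                            drive_left = 1.7, drive_right = 1.72,
                            drive_duration = 35, transient_keep = 9,
                            sync_tolerance = 0.1, discard_above = 1.0,
                            settings = solver_settings(), t_extra = 5) {
  chain_axis <- match.arg(chain_axis)
  kind <- match.arg(kind, .contra_kinds)
  grid <- tidyr::expand_grid(weight = contralateral_values,
                             chain_value = chain_values)
  purrr::pmap(grid, function(weight, chain_value) {
    ch <- if (chain_axis == "b")
      chain_coupling(chain_value, -20, spec$n_segments)
    else chain_coupling(20, chain_value, spec$n_segments)
    sp <- cpg_spec(n_segments = spec$n_segments,
                   excitatory = spec$excitatory, inhibitory = spec$inhibitory,
                   segment = spec$segment, chain = ch,
                   contralateral = contralateral_spec(kind, weight))
    protocol <- drive_protocol(
      segment = rep(sp$n_segments, 2),
      strength = c(drive_left, drive_right),
      onset = 0, duration = drive_duration,
      side = c("left", "right"))
    t_end <- drive_duration + t_extra
    traj <- simulate_cpg(sp, protocol, t_end = t_end, settings = settings)
    cut <- t_end - transient_keep
    purrr::map(thresholds, function(th) {
      sync <- left_right_sync(traj, th, transient_cut = cut,
                              sync_tolerance = sync_tolerance,
                              discard_above = discard_above)
      cw <- count_waves(traj, th, "forward", side = "left", from = cut)
      tibble(kind = kind, weight = weight, chain_axis = chain_axis,
             chain_value = chain_value, threshold = th,
             classification = sync$classification,
             mean_onset_difference = sync$mean_onset_difference,
             discarded = sync$discarded,
             waves_propagate = cw$n_waves >= 1)
    }) |> bind_rows()
  }) |> bind_rows()
}
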