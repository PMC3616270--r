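# Numerical integration of the model and the trajectory container.

#' Solver settings
#'
#' Controls the time integrator. `"fixed_step"` uses classical RK4 with
#' step `max_step` (default 1e-3 t.u.); `"adaptive"` uses an embedded
#' Dormand-Prince 5(4) pair with the given tolerances and steps capped at
#' `max_step`. Either way the returned trajectory is sampled on a regular
#' grid of spacing `output_resolution` (default 0.005 t.u., fine enough
#' that threshold crossings refined by linear interpolation are insensitive
#' to sampling), and integration is performed piecewise between drive-pulse
#' edges so no step straddles a discontinuity.
#'
#' @param method `"fixed_step"` or `"adaptive"`.
#' @param relative_tolerance,absolute_tolerance Adaptive error tolerances.
#' @param max_step Maximum (or fixed) step size, t.u.
#' @param output_resolution Sampling interval of the returned trajectory.
#' @return An object of class \code{solver_settings}.
#' @export
solver_settings <- function(method = c("fixed_step", "adaptive"),
                            relative_tolerance = 1e-6,
                            absolute_tolerance = 1e-9,
                            max_step = NULL,
                            output_resolution = 0.005) {
  method <- match.arg(method)
  if (is.null(max_step))
    max_step <- if (method == "fixed_step") 1e-3 else 0.005
  stopifnot(relative_tolerance > 0, absolute_tolerance > 0, max_step > 0,
            output_resolution > 0)
  structure(list(method = method,
                 relative_tolerance = relative_tolerance,
                 absolute_tolerance = absolute_tolerance,
                 max_step = max_step,
                 output_resolution = output_resolution),
            class = "solver_settings")
}

#' Simulate the CPG network
#'
#' Integrates the model defined by `spec` under the external drive
#' `protocol` from the rest state (or a caller-supplied initial state) up
#' to `t_end`, returning a densely sampled trajectory. The result is a
#' tibble with one row per time sample and one column per population
#' (`E1..En`, `I1..In`, `S1..Sn` when sensory feedback is present, with
#' `left_`/`right_` prefixes for two-sided models), carrying the spec,
#' protocol and settings as attributes.
#'
#' @param spec A [cpg_spec()].
#' @param protocol A [drive_protocol()].
#' @param t_end End time (> 0), t.u.
#' @param settings A [solver_settings()].
#' @param initial_state Optional numeric state vector; defaults to rest
#'   (all zeros), the model's pre-wave equilibrium.
#' @return A tibble of class \code{cpg_trajectory}.
#' @examples
#' traj <- simulate_cpg(cpg_spec(),
#'                      drive_protocol(segment = 8, strength = 1.7,
#'                                     duration = 2),
#'                      t_end = 12)
#' @export
simulate_cpg <- function(spec, protocol, t_end,
                         settings = solver_settings(),
                         initial_state = NULL) {
  stopifnot(inherits(spec, "cpg_spec"), inherits(protocol, "drive_protocol"),
            inherits(settings, "solver_settings"), t_end > 0)
  par <- as_model_params(spec, protocol)
  nm <- state_names(spec)
  if (is.null(initial_state)) initial_state <- rest_state(spec)
  if (length(initial_state) != length(nm))
    abort(sprintf("initial state length %d does not match model dimension %d",
                  length(initial_state), length(nm)))
  res <- settings$output_resolution
  times <- seq(0, t_end, by = res)
  if (tail(times, 1) < t_end - 1e-12) times <- c(times, t_end)
  breaks <- sort(unique(c(protocol$onset,
                          protocol$onset + protocol$duration)))
  breaks <- breaks[breaks > 0 & breaks < t_end]
  out <- cpp_integrate(as.numeric(initial_state), times, breaks, par,
                       settings$method, settings$relative_tolerance,
                       settings$absolute_tolerance, settings$max_step)
  states <- out$states
  colnames(states) <- nm
  traj <- as_tibble(as.data.frame(states))
  traj <- tibble(time = out$times, !!!traj)
  attr(traj, "spec") <- spec
  attr(traj, "protocol") <- protocol
  attr(traj, "settings") <- settings
  class(traj) <- c("cpg_trajectory", class(traj))
  traj
}

#' @export
print.cpg_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<cpg_trajectory> %d samples over [%g, %g] t.u., %s model\n",
              nrow(x), min(x$time), max(x$time),
              if (is_two_sided(spec)) "two-sided" else "one-sided"))
  NextMethod()
}

# columns holding excitatory activity for one side, in segment order 1..n
excitatory_columns <- function(trajectory, side = NULL) {
  spec <- attr(trajectory, "spec")
  n <- spec$n_segments
  prefix <- if (is.null(side) || side == "only") "" else paste0(side, "_")
  cols <- paste0(prefix, "E", seq_len(n))
  if (!all(cols %in% names(trajectory)))
    abort(sprintf("trajectory lacks columns %s",
                  paste(setdiff(cols, names(trajectory)), collapse = ", ")))
  cols
}

#' Write / read a trajectory
#'
#' The trajectory table is written as a tab-delimited text file (full
#' double precision, `%.17g`) together with a JSON sidecar
#' `<path>.json` capturing the complete network spec, drive protocol and
#' solver settings, so the round trip is lossless.
#'
#' @param trajectory A [simulate_cpg()] result.
#' @param path Output file path for the table.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the reconstructed trajectory.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cpg_trajectory"))
  df <- as.data.frame(lapply(trajectory, function(col) sprintf("%.17g", col)))
  names(df) <- names(trajectory)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(spec = spec_to_list(attr(trajectory, "spec")),
               protocol = protocol_to_list(attr(trajectory, "protocol")),
               settings = unclass(attr(trajectory, "settings")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = "numeric")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  traj <- as_tibble(df)
  attr(traj, "spec") <- spec_from_list(meta$spec)
  attr(traj, "protocol") <- protocol_from_list(meta$protocol)
  st <- meta$settings
  attr(traj, "settings") <- solver_settings(
    method = st$method, relative_tolerance = st$relative_tolerance,
    absolute_tolerance = st$absolute_tolerance, max_step = st$max_step,
    output_resolution = st$output_resolution)
  class(traj) <- c("cpg_trajectory", class(traj))
  traj
}
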