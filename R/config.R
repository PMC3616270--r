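# Flat key = value configuration files mirroring the published parameter
# names, with an include/override mechanism and named presets for the
# standard simulation protocols.

#' Read / write a flat key = value configuration file
#'
#' The configuration format is plain text, one `key = value` pair per
#' line; `#` starts a comment. Keys mirror the published parameter table
#' (`a`, `b`, `c`, `d`, `e`, `f`, `tau_E`, `tau_I`, `tau_S`, `P_ext`,
#' `b_E`, `b_I`, `b_S`, `theta_E`, `theta_I`, `theta_S`) plus `alpha`,
#' `beta`, `gamma` (sensory feedback), `contralateral_kind` /
#' `contralateral_weight` (two-sided model), drive pulse fields
#' (`drive_segment`, `drive_onset`, `drive_duration`, and for two-sided
#' runs `P_ext_right`), and run controls (`t_end`, `theta_C`, `method`,
#' `output_resolution`, `max_step`). An `include = <preset or path>` line
#' loads another configuration first and overrides its keys. Setting
#' `negate_inhibitory = true` accepts configurations written with unsigned
#' inhibitory magnitudes by negating `c`, `d` and `f` on load.
#'
#' @param path File path, or the name of a packaged preset (see
#'   [preset_config()]).
#' @return A named list of configuration values (numbers parsed, `true`/
#'   `false` as logicals).
#' @export
read_cpg_config <- function(path) {
  if (!file.exists(path)) {
    preset <- preset_path(path)
    if (is.na(preset)) abort(sprintf("config file or preset '%s' not found",
                                     path))
    path <- preset
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                ln))[[1]]
    if (length(m) != 3)
      abort(sprintf("malformed configuration line: '%s'", ln))
    key <- m[2]
    raw <- trimws(m[3])
    val <- if (raw %in% c("true", "false")) raw == "true"
           else if (!is.na(suppressWarnings(as.numeric(raw))))
             as.numeric(raw)
           else raw
    if (key == "include") {
      base <- read_cpg_config(as.character(raw))
      cfg <- modifyList(base, cfg)
    } else {
      cfg[[key]] <- val
    }
  }
  if (isTRUE(cfg$negate_inhibitory)) {
    for (k in c("c", "d", "f")) if (!is.null(cfg[[k]]))
      cfg[[k]] <- -cfg[[k]]
    cfg$negate_inhibitory <- FALSE
  }
  cfg
}

#' @rdname read_cpg_config
#' @param config A named list of configuration values.
#' @export
write_cpg_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) sprintf("%.17g", v)
    else as.character(v)
  }
  writeLines(paste(names(config), "=", vapply(config, fmt, character(1))),
             path)
  invisible(path)
}

preset_path <- function(name) {
  f <- system.file("extdata", "configs", paste0(name, ".cfg"),
                   package = "crawlwave")
  if (nzchar(f)) f else NA_character_
}

#' Packaged configuration presets
#'
#' Named presets for the standard protocols: `"default"` (the published
#' parameter table, forward-wave drive), `"baseline"` (alias of the
#' default forward wave), `"backward"` (drive applied to A1),
#' `"sustained_drive"` (35 t.u. drive evoking repeated waves),
#' `"coupling_grid"` (base cell for intersegmental grids),
#' `"robustness_drive"` (the 1.2 t.u. single-wave criterion drive),
#' `"sensory"` (stretch feedback, alpha 25 / beta 20 / gamma 17, 2.5 t.u.
#' drive), `"rescue"` (weak-excitation chain plus rescuing feedback),
#' `"two_sided"` (E-to-E coupled hemisegments, asymmetric sustained
#' drives).
#'
#' @param name Preset name.
#' @return The parsed configuration list.
#' @export
preset_config <- function(name = "default") {
  p <- preset_path(name)
  if (is.na(p)) abort(sprintf("unknown preset '%s'", name))
  read_cpg_config(p)
}

# required keys and their validation for building a spec
validate_config <- function(cfg) {
  required <- c("n_segments", "a", "b", "c", "d", "e", "f", "tau_E",
                "tau_I", "b_E", "b_I", "theta_E", "theta_I")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    abort(sprintf("configuration is missing required key(s): %s",
                  paste(missing, collapse = ", ")))
  for (k in c("a", "b", "c", "d", "e", "f", "tau_E", "tau_I", "b_E", "b_I",
              "theta_E", "theta_I"))
    if (!is.numeric(cfg[[k]]))
      abort(sprintf("configuration key '%s' must be numeric", k))
  if (!is.null(cfg$contralateral_kind) &&
      !cfg$contralateral_kind %in% .contra_kinds)
    abort("'contralateral_kind' must be one of EE, IE, EI, II")
  invisible(cfg)
}

#' Build a network spec and drive protocol from a configuration
#'
#' @param cfg A configuration list from [read_cpg_config()] or
#'   [preset_config()].
#' @return A list with elements `spec` ([cpg_spec()]), `protocol`
#'   ([drive_protocol()]), `t_end`, `threshold` and `settings`.
#' @export
config_to_spec <- function(cfg) {
  validate_config(cfg)
  n <- as.integer(cfg$n_segments)
  sensory <- NULL
  if (!is.null(cfg$alpha)) {
    sensory <- sensory_spec(
      cfg$alpha, cfg$beta %||% 0, cfg$gamma %||% 0,
      population_spec(cfg$tau_S %||% cfg$tau_E,
                      sigmoid_spec(cfg$b_S %||% cfg$b_E,
                                   cfg$theta_S %||% 2),
                      ceiling = NA))
  }
  contralateral <- NULL
  if (!is.null(cfg$contralateral_kind))
    contralateral <- contralateral_spec(cfg$contralateral_kind,
                                        cfg$contralateral_weight %||% 0)
  spec <- cpg_spec(
    n_segments = n,
    excitatory = population_spec(cfg$tau_E,
                                 sigmoid_spec(cfg$b_E, cfg$theta_E)),
    inhibitory = population_spec(cfg$tau_I,
                                 sigmoid_spec(cfg$b_I, cfg$theta_I)),
    segment = segment_coupling(cfg$a, cfg$c, cfg$e, cfg$f),
    chain = chain_coupling(cfg$b, cfg$d, n),
    sensory = sensory, contralateral = contralateral)
  seg <- as.integer(cfg$drive_segment %||% n)
  onset <- cfg$drive_onset %||% 0
  duration <- cfg$drive_duration %||% 2
  protocol <- if (is.null(contralateral)) {
    drive_protocol(segment = seg, strength = cfg$P_ext %||% 1.7,
                   onset = onset, duration = duration)
  } else {
    drive_protocol(segment = rep(seg, 2),
                   strength = c(cfg$P_ext %||% 1.7,
                                cfg$P_ext_right %||% (cfg$P_ext %||% 1.7)),
                   onset = onset, duration = duration,
                   side = c("left", "right"))
  }
  settings <- solver_settings(
    method = cfg$method %||% "fixed_step",
    output_resolution = cfg$output_resolution %||% 0.005,
    max_step = cfg$max_step)
  list(spec = spec, protocol = protocol,
       t_end = cfg$t_end %||% (onset + duration + 15),
       threshold = cfg$theta_C %||% 0.3,
       settings = settings)
}
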