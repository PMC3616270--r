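# Model parameterization: sigmoids, populations, within-segment and
# intersegmental coupling, sensory feedback, contralateral coupling, and the
# full network specification. The default construction reproduces the
# published parameter table for wave propagation bit-exactly.

#' Sigmoidal response function specification
#'
#' The population response function is
#' \deqn{G(x) = \frac{1}{1 + e^{-\lambda(x-\theta)}} - \frac{1}{1+e^{\lambda\theta}},}
#' a logistic sigmoid shifted so that \eqn{G(0) = 0}: a population at rest
#' receiving no input stays at rest. \code{slope} is the maximum slope
#' \eqn{\lambda} and \code{threshold} the location \eqn{\theta} of that
#' maximum slope (the activation threshold).
#'
#' @param slope Positive real, maximum slope of the sigmoid.
#' @param threshold Real, input level of maximum slope.
#' @return An object of class \code{sigmoid_spec}.
#' @examples
#' gE <- sigmoid_spec(slope = 1.3, threshold = 4)
#' sigmoid_response(0, gE)   # 0 by construction
#' response_ceiling(gE)      # 0.9945, the excitatory ceiling k_E
#' @export
sigmoid_spec <- function(slope, threshold) {
  stopifnot(is.numeric(slope), length(slope) == 1, is.finite(slope),
            is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  if (slope <= 0) abort("`slope` must be > 0")
  structure(list(slope = slope, threshold = threshold),
            class = "sigmoid_spec")
}

#' Evaluate the shifted sigmoid response function
#'
#' @param x Numeric vector of input levels (finite).
#' @param spec A [sigmoid_spec()].
#' @return Numeric vector, strictly increasing in `x`, zero at `x = 0`.
#' @export
sigmoid_response <- function(x, spec) {
  stopifnot(inherits(spec, "sigmoid_spec"))
  if (!all(is.finite(x))) abort("`x` must be finite")
  1 / (1 + exp(-spec$slope * (x - spec$threshold))) -
    1 / (1 + exp(spec$slope * spec$threshold))
}

#' Supremum of the shifted sigmoid response
#'
#' The analytic limit of [sigmoid_response()] as the input grows large,
#' \eqn{1 - 1/(1+e^{\lambda\theta})}. For the default excitatory and
#' inhibitory sigmoids this gives the ceilings \eqn{k_E = 0.9945} and
#' \eqn{k_I = 0.9994} used as saturation factors in the rate equations.
#'
#' @inheritParams sigmoid_response
#' @return A single number in (0, 1).
#' @export
response_ceiling <- function(spec) {
  stopifnot(inherits(spec, "sigmoid_spec"))
  1 - 1 / (1 + exp(spec$slope * spec$threshold))
}

#' Neuronal population specification
#'
#' One Wilson-Cowan population: a decay time constant, a response sigmoid,
#' and (for excitatory/inhibitory populations) the ceiling factor that
#' saturates growth, \eqn{\tau \dot{x} = -x + (k - x) G(\mathrm{input})}.
#' By default the ceiling is derived analytically from the sigmoid via
#' [response_ceiling()]. Sensory populations carry no ceiling factor
#' (`ceiling = NA`); their activity is bounded through the dynamics by the
#' sigmoid's supremum.
#'
#' @param time_constant Positive real, decay time constant in model time
#'   units (t.u.).
#' @param sigmoid A [sigmoid_spec()].
#' @param ceiling Ceiling factor in (0, 1], or `NA` for none. Defaults to
#'   the sigmoid's analytic supremum.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(time_constant, sigmoid,
                            ceiling = response_ceiling(sigmoid)) {
  stopifnot(is.numeric(time_constant), length(time_constant) == 1,
            inherits(sigmoid, "sigmoid_spec"))
  if (!is.finite(time_constant) || time_constant <= 0)
    abort("`time_constant` must be > 0")
  if (!is.na(ceiling) && (ceiling <= 0 || ceiling > 1))
    abort("`ceiling` must lie in (0, 1]")
  structure(list(time_constant = time_constant, ceiling = ceiling,
                 sigmoid = sigmoid),
            class = "population_spec")
}

#' Within-segment coupling weights
#'
#' The four signed weights of one EI unit: recurrent excitation `a`
#' (E to E), inhibition of E by I `c`, excitation of I by E `e`, and
#' recurrent inhibition `f` (I to I). All weights are stored signed and
#' enter the sigmoid argument with a plus sign, so inhibitory weights are
#' negative. Defaults are the published values.
#'
#' @param self_excitation `a`, expected positive.
#' @param i_to_e `c`, expected negative.
#' @param e_to_i `e`, expected positive.
#' @param i_to_i `f`, expected negative.
#' @return An object of class \code{segment_coupling}.
#' @export
segment_coupling <- function(self_excitation = 16, i_to_e = -12,
                             e_to_i = 15, i_to_i = -3) {
  vals <- c(self_excitation, i_to_e, e_to_i, i_to_i)
  if (!all(is.finite(vals))) abort("segment coupling weights must be finite")
  structure(list(self_excitation = self_excitation, i_to_e = i_to_e,
                 e_to_i = e_to_i, i_to_i = i_to_i),
            class = "segment_coupling")
}

#' Intersegmental (chain) coupling weights
#'
#' Nearest-neighbour coupling along the chain of segments: excitatory
#' weights `b` between neighbouring E populations (bidirectional) and
#' inhibitory weights `d` from each segment's I population to both
#' neighbouring E populations. Edges are indexed in anterior-to-posterior
#' order: edge k joins segments k (A-k, more anterior) and k+1. Scalars are
#' recycled to all `n_segments - 1` edges; vectors give per-edge weights
#' applied symmetrically in both directions. `e_ascending` etc. allow a
#' per-directed-edge override (used by the directed variant of the
#' robustness noise experiment): `*_ascending[k]` weights the input segment
#' k+1 receives from segment k, `*_descending[k]` the reverse.
#'
#' @param e_weights `b`: scalar or length `n_segments - 1` vector, signed.
#' @param i_weights `d`: scalar or length `n_segments - 1` vector, signed.
#' @param n_segments Number of segments in the chain.
#' @param e_ascending,e_descending,i_ascending,i_descending Optional
#'   per-directed-edge weights overriding the symmetric ones.
#' @return An object of class \code{chain_coupling}.
#' @export
chain_coupling <- function(e_weights = 20, i_weights = -20, n_segments = 8,
                           e_ascending = NULL, e_descending = NULL,
                           i_ascending = NULL, i_descending = NULL) {
  m <- n_segments - 1
  expand <- function(w, nm) {
    if (length(w) == 1) w <- rep(w, m)
    if (length(w) != m)
      abort(sprintf("`%s` must have length 1 or %d", nm, m))
    if (!all(is.finite(w))) abort(sprintf("`%s` must be finite", nm))
    w
  }
  e_w <- expand(e_weights, "e_weights")
  i_w <- expand(i_weights, "i_weights")
  structure(list(
    e_ascending  = if (is.null(e_ascending)) e_w else expand(e_ascending, "e_ascending"),
    e_descending = if (is.null(e_descending)) e_w else expand(e_descending, "e_descending"),
    i_ascending  = if (is.null(i_ascending)) i_w else expand(i_ascending, "i_ascending"),
    i_descending = if (is.null(i_descending)) i_w else expand(i_descending, "i_descending")
  ), class = "chain_coupling")
}

#' Stretch-sensitive sensory feedback specification
#'
#' One sensory population per segment is driven by the rectified difference
#' in excitatory activity between a segment and its neighbours (a proxy for
#' stretch), with gain `stretch_gain` (\eqn{\alpha}). Its output feeds the
#' segment's excitatory population with weight `to_excitatory`
#' (\eqn{\beta}) and its inhibitory population with weight `to_inhibitory`
#' (\eqn{\gamma}).
#'
#' @param stretch_gain \eqn{\alpha \ge 0}.
#' @param to_excitatory \eqn{\beta}, signed.
#' @param to_inhibitory \eqn{\gamma}, signed.
#' @param population Sensory [population_spec()]; defaults to the published
#'   one (time constant 0.5, slope 1.3, threshold 2, no ceiling factor).
#' @return An object of class \code{sensory_spec}.
#' @export
sensory_spec <- function(stretch_gain, to_excitatory, to_inhibitory,
                         population = population_spec(0.5,
                                                      sigmoid_spec(1.3, 2),
                                                      ceiling = NA)) {
  stopifnot(is.numeric(stretch_gain), length(stretch_gain) == 1,
            inherits(population, "population_spec"))
  if (!is.finite(stretch_gain) || stretch_gain < 0)
    abort("`stretch_gain` must be >= 0")
  if (!all(is.finite(c(to_excitatory, to_inhibitory))))
    abort("sensory weights must be finite")
  structure(list(stretch_gain = stretch_gain,
                 to_excitatory = to_excitatory,
                 to_inhibitory = to_inhibitory,
                 population = population),
            class = "sensory_spec")
}

.contra_kinds <- c("EE", "IE", "EI", "II")

#' Contralateral coupling specification (two-sided model)
#'
#' Same-segment coupling across the midline, one of four kinds: `"EE"`
#' (E to contralateral E), `"IE"` (I to contralateral E), `"EI"` (E to
#' contralateral I), `"II"` (I to contralateral I). Presence of a
#' contralateral spec in [cpg_spec()] makes the model two-sided.
#'
#' @param kind One of `"EE"`, `"IE"`, `"EI"`, `"II"`.
#' @param weight Signed coupling weight.
#' @return An object of class \code{contralateral_spec}.
#' @export
contralateral_spec <- function(kind, weight) {
  kind <- match.arg(kind, .contra_kinds)
  if (!is.finite(weight)) abort("`weight` must be finite")
  structure(list(kind = kind, weight = weight),
            class = "contralateral_spec")
}

#' Full CPG network specification
#'
#' Assembles the complete parameterization of a one- or two-sided chain of
#' Wilson-Cowan EI units. Called with no arguments it reproduces the
#' published parameter set exactly: 8 segments, a = 16, b = 20, c = -12,
#' d = -20, e = 15, f = -3, all time constants 0.5 t.u., excitatory sigmoid
#' (1.3, 4), inhibitory sigmoid (2, 3.7), no sensory feedback, one-sided.
#'
#' @param n_segments Positive integer, 8 for the larval abdomen (A8 is the
#'   most posterior segment, index `n_segments`; A1, index 1, the most
#'   anterior).
#' @param excitatory,inhibitory [population_spec()]s.
#' @param segment A [segment_coupling()].
#' @param chain A [chain_coupling()] with `n_segments - 1` edges.
#' @param sensory Optional [sensory_spec()].
#' @param contralateral Optional [contralateral_spec()]; if present the
#'   model is two-sided with both sides sharing all other parameters.
#' @return An object of class \code{cpg_spec}.
#' @examples
#' spec <- cpg_spec()                      # published baseline
#' spec2 <- cpg_spec(chain = chain_coupling(e_weights = 18, i_weights = -15))
#' @export
cpg_spec <- function(n_segments = 8,
                     excitatory = population_spec(0.5, sigmoid_spec(1.3, 4)),
                     inhibitory = population_spec(0.5, sigmoid_spec(2, 3.7)),
                     segment = segment_coupling(),
                     chain = chain_coupling(n_segments = n_segments),
                     sensory = NULL,
                     contralateral = NULL) {
  stopifnot(n_segments >= 2, n_segments == as.integer(n_segments),
            inherits(excitatory, "population_spec"),
            inherits(inhibitory, "population_spec"),
            inherits(segment, "segment_coupling"),
            inherits(chain, "chain_coupling"))
  if (length(chain$e_ascending) != n_segments - 1)
    abort("chain edge arrays must have n_segments - 1 entries")
  if (!is.null(sensory) && !inherits(sensory, "sensory_spec"))
    abort("`sensory` must be a sensory_spec or NULL")
  if (!is.null(contralateral) && !inherits(contralateral, "contralateral_spec"))
    abort("`contralateral` must be a contralateral_spec or NULL")
  structure(list(n_segments = as.integer(n_segments),
                 excitatory = excitatory, inhibitory = inhibitory,
                 segment = segment, chain = chain,
                 sensory = sensory, contralateral = contralateral),
            class = "cpg_spec")
}

#' Is a network specification two-sided?
#' @param spec A [cpg_spec()].
#' @return `TRUE` if a contralateral coupling is present.
#' @export
is_two_sided <- function(spec) {
  stopifnot(inherits(spec, "cpg_spec"))
  !is.null(spec$contralateral)
}

#' @export
print.cpg_spec <- function(x, ...) {
  cat(sprintf("<cpg_spec> %d segments, %s%s%s\n", x$n_segments,
              if (is_two_sided(x)) sprintf("two-sided (%s, weight %g)",
                                           x$contralateral$kind,
                                           x$contralateral$weight)
              else "one-sided",
              if (!is.null(x$sensory))
                sprintf(", sensory (alpha=%g, beta=%g, gamma=%g)",
                        x$sensory$stretch_gain, x$sensory$to_excitatory,
                        x$sensory$to_inhibitory) else "",
              ""))
  s <- x$segment
  cat(sprintf("  segment: a=%g c=%g e=%g f=%g\n", s$self_excitation,
              s$i_to_e, s$e_to_i, s$i_to_i))
  cat(sprintf("  chain:   b=[%s] d=[%s]\n",
              paste(signif(x$chain$e_ascending, 4), collapse = " "),
              paste(signif(x$chain$i_ascending, 4), collapse = " ")))
  invisible(x)
}

#' Rectangular external drive protocol
#'
#' A drive protocol is a tibble of rectangular pulses delivered to
#' excitatory populations only (the model never drives inhibitory or
#' sensory populations). Forward waves are evoked by driving the most
#' posterior segment (index `n_segments`), backward waves by driving
#' segment 1. Multiple pulses superpose.
#'
#' @param segment Integer segment index (1 = A1 anterior, 8 = A8 posterior),
#'   recycled against the other arguments.
#' @param strength Drive strength `P_ext` (>= 0), dimensionless.
#' @param onset Pulse onset time (>= 0), t.u.
#' @param duration Pulse duration (> 0), t.u.
#' @param side `"only"` for one-sided models, `"left"`/`"right"` for
#'   two-sided ones.
#' @return A tibble of class \code{drive_protocol} with columns `side`,
#'   `segment`, `strength`, `onset`, `duration`.
#' @examples
#' drive_protocol(segment = 8, strength = 1.7, duration = 2)
#' @export
drive_protocol <- function(segment, strength, onset = 0, duration,
                           side = "only") {
  tb <- tibble(side = side, segment = as.integer(segment),
               strength = as.numeric(strength), onset = as.numeric(onset),
               duration = as.numeric(duration))
  if (!all(tb$side %in% c("only", "left", "right")))
    abort("`side` must be 'only', 'left' or 'right'")
  if (any(tb$strength < 0)) abort("`strength` must be >= 0")
  if (any(tb$onset < 0)) abort("`onset` must be >= 0")
  if (any(tb$duration <= 0)) abort("`duration` must be > 0")
  class(tb) <- c("drive_protocol", class(tb))
  tb
}

#' Evaluate the external drive at a time point
#'
#' Sums the strengths of all pulses of `protocol` targeting the given
#' segment and side whose window `[onset, onset + duration)` contains `t`.
#'
#' @param protocol A [drive_protocol()].
#' @param t Time (>= 0), t.u.
#' @param segment Segment index.
#' @param side `"only"`, `"left"` or `"right"`.
#' @return The summed drive strength (0 when no pulse is active).
#' @export
drive_value <- function(protocol, t, segment, side = "only") {
  stopifnot(inherits(protocol, "drive_protocol"), t >= 0)
  hit <- protocol$side == side & protocol$segment == segment &
    protocol$onset <= t & t < protocol$onset + protocol$duration
  sum(protocol$strength[hit])
}

# empty protocol (no drive)
no_drive <- function() {
  drive_protocol(segment = integer(), strength = numeric(),
                 onset = numeric(), duration = numeric(),
                 side = character())
}
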