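# Right-hand-side (time derivative) functions. The plain-R implementations
# here are the definitional reference for the dynamics; simulation uses the
# compiled mirror in src/integrate.cpp, which is cross-checked against these
# in the test suite.

# marshal a cpg_spec + drive_protocol into the flat parameter list the
# compiled code consumes
as_model_params <- function(spec, protocol) {
  stopifnot(inherits(spec, "cpg_spec"), inherits(protocol, "drive_protocol"))
  two <- is_two_sided(spec)
  if (two && any(protocol$side == "only"))
    abort("two-sided models need pulses with side 'left' or 'right'")
  if (!two && any(protocol$side != "only"))
    abort("one-sided models need pulses with side 'only'")
  sen <- spec$sensory
  pulses <- cbind(
    side = ifelse(protocol$side == "right", 1, 0),
    segment = protocol$segment,
    strength = protocol$strength,
    onset = protocol$onset,
    offset = protocol$onset + protocol$duration
  )
  list(
    n = spec$n_segments,
    a = spec$segment$self_excitation, c = spec$segment$i_to_e,
    e = spec$segment$e_to_i, f = spec$segment$i_to_i,
    kE = spec$excitatory$ceiling, kI = spec$inhibitory$ceiling,
    tauE = spec$excitatory$time_constant,
    tauI = spec$inhibitory$time_constant,
    tauS = if (is.null(sen)) 1 else sen$population$time_constant,
    lamE = spec$excitatory$sigmoid$slope,
    thE = spec$excitatory$sigmoid$threshold,
    lamI = spec$inhibitory$sigmoid$slope,
    thI = spec$inhibitory$sigmoid$threshold,
    lamS = if (is.null(sen)) 1 else sen$population$sigmoid$slope,
    thS = if (is.null(sen)) 0 else sen$population$sigmoid$threshold,
    sensory = !is.null(sen),
    alpha = if (is.null(sen)) 0 else sen$stretch_gain,
    beta = if (is.null(sen)) 0 else sen$to_excitatory,
    gamma = if (is.null(sen)) 0 else sen$to_inhibitory,
    two_sided = two,
    contra_kind = if (two) match(spec$contralateral$kind, .contra_kinds) - 1L
                  else 0L,
    contra_weight = if (two) spec$contralateral$weight else 0,
    b_asc = spec$chain$e_ascending, b_desc = spec$chain$e_descending,
    d_asc = spec$chain$i_ascending, d_desc = spec$chain$i_descending,
    pulses = matrix(pulses, ncol = 5)
  )
}

# population column names for a spec, in state-vector order
state_names <- function(spec) {
  n <- spec$n_segments
  base <- c(paste0("E", seq_len(n)), paste0("I", seq_len(n)))
  if (!is.null(spec$sensory)) base <- c(base, paste0("S", seq_len(n)))
  if (is_two_sided(spec))
    c(paste0("left_", base), paste0("right_", base))
  else base
}

#' Rest (all-zero) initial state for a network
#' @param spec A [cpg_spec()].
#' @return A named numeric vector of zeros, one entry per population.
#' @export
rest_state <- function(spec) {
  nm <- state_names(spec)
  setNames(numeric(length(nm)), nm)
}

#' Sensory input arguments from excitatory activity
#'
#' Computes the sigmoid argument of every sensory population from the
#' excitatory activity profile: interior segments receive
#' \eqn{\alpha [E_{i+1}-E_i]_+ + \alpha [E_{i-1}-E_i]_+} (rectified
#' differences from both neighbours, mimicking stretch from either side);
#' the end segments receive the single-neighbour term.
#'
#' @param E Numeric vector of excitatory activities, one per segment.
#' @param spec A [sensory_spec()].
#' @return Numeric vector of sensory sigmoid arguments, same length as `E`.
#' @export
sensory_drive <- function(E, spec) {
  stopifnot(inherits(spec, "sensory_spec"), is.numeric(E))
  n <- length(E)
  pos <- function(x) pmax(x, 0)
  up <- c(pos(E[-1] - E[-n]), 0)      # from the next (posterior) neighbour
  down <- c(0, pos(E[-n] - E[-1]))    # from the previous (anterior) neighbour
  spec$stretch_gain * (up + down)
}

# R reference RHS for one side. state is the named vector for that side,
# other_state the opposite side's (or NULL), side is "only"/"left"/"right".
rhs_side_r <- function(state, t, spec, protocol, side = "only",
                       other_state = NULL) {
  n <- spec$n_segments
  E <- state[seq_len(n)]
  I <- state[n + seq_len(n)]
  sen <- spec$sensory
  S <- if (!is.null(sen)) state[2 * n + seq_len(n)] else numeric(n)
  sc <- spec$segment
  ch <- spec$chain
  GE <- spec$excitatory$sigmoid
  GI <- spec$inhibitory$sigmoid
  kE <- spec$excitatory$ceiling
  kI <- spec$inhibitory$ceiling

  P <- vapply(seq_len(n), function(i) drive_value(protocol, t, i, side),
              numeric(1))
  # chain input into E_i: from anterior neighbour via ascending edge i-1,
  # from posterior neighbour via descending edge i
  from_ant <- c(0, ch$e_ascending * E[-n] + ch$i_ascending * I[-n])
  from_pos <- c(ch$e_descending * E[-1] + ch$i_descending * I[-1], 0)
  argE <- sc$self_excitation * E + sc$i_to_e * I + from_ant + from_pos + P
  argI <- sc$e_to_i * E + sc$i_to_i * I
  if (!is.null(sen)) {
    argE <- argE + sen$to_excitatory * S
    argI <- argI + sen$to_inhibitory * S
  }
  if (!is.null(other_state)) {
    ct <- spec$contralateral
    Eo <- other_state[seq_len(n)]
    Io <- other_state[n + seq_len(n)]
    switch(ct$kind,
           EE = argE <- argE + ct$weight * Eo,
           IE = argE <- argE + ct$weight * Io,
           EI = argI <- argI + ct$weight * Eo,
           II = argI <- argI + ct$weight * Io)
  }
  dE <- (-E + (kE - E) * sigmoid_response(argE, GE)) /
    spec$excitatory$time_constant
  dI <- (-I + (kI - I) * sigmoid_response(argI, GI)) /
    spec$inhibitory$time_constant
  if (!is.null(sen)) {
    dS <- (-S + sigmoid_response(sensory_drive(E, sen),
                                 sen$population$sigmoid)) /
      sen$population$time_constant
    c(dE, dI, dS)
  } else {
    c(dE, dI)
  }
}

#' Time derivatives of the network state (reference implementation)
#'
#' Evaluates the Wilson-Cowan chain right-hand side in plain R. For a
#' one-sided model the state is `(E_1..E_n, I_1..I_n, S_1..S_n?)`; a
#' two-sided model stacks the left block before the right block. This is
#' the definitional form of the dynamics; [simulate_cpg()] uses a compiled
#' mirror of it.
#'
#' @param state Numeric state vector (see [rest_state()] for layout and
#'   names).
#' @param t Time, t.u.
#' @param spec A [cpg_spec()].
#' @param protocol A [drive_protocol()].
#' @return Named numeric vector of derivatives, same layout as `state`.
#' @export
cpg_rhs <- function(state, t, spec, protocol = no_drive()) {
  stopifnot(inherits(spec, "cpg_spec"))
  nm <- state_names(spec)
  if (length(state) != length(nm))
    abort(sprintf("state length %d does not match model dimension %d",
                  length(state), length(nm)))
  if (is_two_sided(spec)) {
    L <- length(nm) / 2
    left <- state[seq_len(L)]
    right <- state[L + seq_len(L)]
    d <- c(rhs_side_r(left, t, spec, protocol, "left", right),
           rhs_side_r(right, t, spec, protocol, "right", left))
  } else {
    d <- rhs_side_r(state, t, spec, protocol, "only")
  }
  setNames(d, nm)
}
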