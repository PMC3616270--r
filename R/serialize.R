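# Lossless list/JSON serialization of spec objects (used by the trajectory
# sidecar and the run manifests).

spec_to_list <- function(spec) {
  pop <- function(p) list(time_constant = p$time_constant,
                          ceiling = if (is.na(p$ceiling)) NULL else p$ceiling,
                          slope = p$sigmoid$slope,
                          threshold = p$sigmoid$threshold)
  out <- list(
    n_segments = spec$n_segments,
    excitatory = pop(spec$excitatory),
    inhibitory = pop(spec$inhibitory),
    segment = unclass(spec$segment),
    chain = unclass(spec$chain)
  )
  if (!is.null(spec$sensory)) {
    s <- spec$sensory
    out$sensory <- list(stretch_gain = s$stretch_gain,
                        to_excitatory = s$to_excitatory,
                        to_inhibitory = s$to_inhibitory,
                        population = pop(s$population))
  }
  if (!is.null(spec$contralateral))
    out$contralateral <- unclass(spec$contralateral)
  out
}

spec_from_list <- function(l) {
  num <- function(x) as.numeric(unlist(x))
  pop <- function(p) {
    ceiling <- if (is.null(p$ceiling)) NA else num(p$ceiling)
    population_spec(num(p$time_constant),
                    sigmoid_spec(num(p$slope), num(p$threshold)),
                    ceiling = ceiling)
  }
  ch <- l$chain
  cpg_spec(
    n_segments = l$n_segments,
    excitatory = pop(l$excitatory),
    inhibitory = pop(l$inhibitory),
    segment = segment_coupling(num(l$segment$self_excitation),
                               num(l$segment$i_to_e),
                               num(l$segment$e_to_i),
                               num(l$segment$i_to_i)),
    chain = chain_coupling(e_weights = num(ch$e_ascending),
                           i_weights = num(ch$i_ascending),
                           n_segments = l$n_segments,
                           e_ascending = num(ch$e_ascending),
                           e_descending = num(ch$e_descending),
                           i_ascending = num(ch$i_ascending),
                           i_descending = num(ch$i_descending)),
    sensory = if (is.null(l$sensory)) NULL else
      sensory_spec(num(l$sensory$stretch_gain),
                   num(l$sensory$to_excitatory),
                   num(l$sensory$to_inhibitory), pop(l$sensory$population)),
    contralateral = if (is.null(l$contralateral)) NULL else
      contralateral_spec(l$contralateral$kind,
                         num(l$contralateral$weight))
  )
}

protocol_to_list <- function(protocol) {
  lapply(seq_len(nrow(protocol)), function(i) as.list(protocol[i, ]))
}

protocol_from_list <- function(l) {
  if (length(l) == 0) return(no_drive())
  tb <- bind_rows(lapply(l, as_tibble))
  drive_protocol(segment = as.integer(tb$segment),
                 strength = as.numeric(tb$strength),
                 onset = as.numeric(tb$onset),
                 duration = as.numeric(tb$duration), side = tb$side)
}
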