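# Shared fixture builders (everything is generated in code; no data files).

# Observations an environment script would emit if the agent executed the
# given policy's actions.
scripted_observations <- function(pol, script) {
  T_ <- length(script$baseline_sequence)
  acts <- unclass(pol)
  lapply(seq_len(T_), function(tau) {
    inc <- if (tau == 1L) NA_character_ else acts[tau - 1L]
    env_step(script, inc, tau)$observation
  })
}

# Minimal hand-built trial record for exercising the detectors without
# running the engine.
fake_record <- function(truth, p_voice, incoming = NULL) {
  T_ <- length(truth)
  if (is.null(incoming)) incoming <- rep("listen", T_ - 1L)
  marg <- rbind(voice = p_voice, no_voice = 1 - p_voice)
  structure(list(
    config = list(n_steps = T_),
    observations = lapply(seq_len(T_), function(i)
      observation(truth[i],
                  if (i > 1L && incoming[i - 1L] == "speak")
                    "speech_movement" else "none")),
    executed_actions = incoming,
    marginal_auditory = marg,
    marginal_speech = rbind(speaking = rep(0, T_),
                            not_speaking = rep(1, T_))
  ), class = "avh_trial")
}
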