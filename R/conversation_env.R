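# The generative process: a scripted conversational partner that produces
# alternating sounds and silences, overridden by the agent's own speech. The
# environment is deliberately ignorant of the agent's beliefs -- it reacts
# only to executed actions, preserving the separation between the generative
# process and the agent's generative model.

#' Define an environment script
#'
#' @param baseline length-`T` sequence of true auditory outcomes the partner
#'   would produce if the agent never spoke; either a character vector over
#'   `"sound"`/`"silence"` or a compact string over `"x"` (sound) / `"-"`
#'   (silence). The default alternation `"-x-x-"` places silences at the
#'   first, third and fifth steps of a five-step trial.
#' @param speech_override logical; if `TRUE` (default) the agent speaking on
#'   the transition into a step forces `sound` at that step (one hears one's
#'   own voice).
#' @return an `avh_script` object.
#' @examples
#' environment_script("-x-x-")
#' @export
environment_script <- function(baseline = "-x-x-", speech_override = TRUE) {
  if (length(baseline) == 1L && !baseline %in% AUD_OUTCOMES) {
    chars <- strsplit(baseline, "")[[1]]
    if (!all(chars %in% c("-", "x")))
      stop_invalid("compact scripts may only contain '-' and 'x': '%s'",
                   baseline)
    baseline <- ifelse(chars == "x", "sound", "silence")
  }
  if (!all(baseline %in% AUD_OUTCOMES))
    stop_invalid("baseline outcomes must be 'sound' or 'silence'")
  structure(list(baseline_sequence = baseline,
                 speech_override = isTRUE(speech_override)),
            class = "avh_script")
}

#' @export
print.avh_script <- function(x, ...) {
  cat("<script>",
      paste(ifelse(x$baseline_sequence == "sound", "x", "-"), collapse = ""),
      if (x$speech_override) "(speech overrides)" else "", "\n")
  invisible(x)
}

#' Advance the environment by one step
#'
#' Emits the observation for time `time` given the action the agent executed
#' on the transition into this step. Speaking generates sound (when the
#' override is on) and a speech-movement proprioceptive outcome, and flags
#' sensory attenuation for the agent's inference at this step.
#'
#' @param script an [environment_script()].
#' @param executed_action `"listen"`, `"speak"`, or `NA`/`NULL` at the first
#'   step (no incoming action).
#' @param time time step in `1..length(baseline)`.
#' @return list with elements `observation` (an [observation()]) and
#'   `attenuation` (logical: the agent spoke into this step).
#' @export
env_step <- function(script, executed_action, time) {
  n <- length(script$baseline_sequence)
  if (!is.numeric(time) || time < 1 || time > n)
    stop_invalid("time %s out of range 1..%d", format(time), n)
  spoke <- !is.null(executed_action) && !is.na(executed_action) &&
    executed_action == "speak"
  aud <- if (spoke && script$speech_override) "sound"
         else script$baseline_sequence[time]
  pro <- if (spoke) "speech_movement" else "none"
  list(observation = observation(aud, pro), attenuation = spoke)
}
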