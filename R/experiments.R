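# Trial simulation, hallucination scoring, and the three precision/policy
# manipulations (likelihood-precision sweep, policy-precision contrast,
# policy-space lesion).

#' Policy-catalog fixtures
#'
#' Reconstructions of the policy spaces used in the simulated experiments,
#' over four transitions (`L` = listen, `S` = speak):
#'
#' * `"F4"`: `LLLL, LSLS, SLSL, SLLS` -- a space whose best explanations of
#'   the alternating environment prescribe listening into the silent steps,
#'   used for the likelihood- and policy-precision manipulations.
#' * `"F6_full"`: `LLLL, SSLL, SLSL, SLLS, LSLS, LLSS` -- the six-policy
#'   space of the lesion experiment.
#' * `"F6_lesioned"`: `F6_full` minus the monologue-then-listen policy
#'   `SSLL`, the policy space after "deleting" the agent's preferred
#'   explanation.
#'
#' @param name one of `"F4"`, `"F6_full"`, `"F6_lesioned"`.
#' @return list of [policy()] objects.
#' @export
policy_fixture <- function(name = c("F4", "F6_full", "F6_lesioned")) {
  name <- match.arg(name)
  strings <- switch(name,
    F4 = c("LLLL", "LSLS", "SLSL", "SLLS"),
    F6_full = c("LLLL", "SSLL", "SLSL", "SLLS", "LSLS", "LLSS"),
    F6_lesioned = c("LLLL", "SLSL", "SLLS", "LSLS", "LLSS"))
  lapply(strings, policy)
}

#' Default hallucination / false-negative belief threshold
#'
#' A step counts as hallucinated (or as a speech-detection error) when the
#' relevant marginal belief exceeds this probability. The default 0.75
#' separates the firm false percepts of the low-precision regime (beliefs
#' near 1) from the merely ambiguous beliefs of the intermediate regime
#' (beliefs around 0.55-0.70), which present as perceptual confusion rather
#' than frank hallucination.
#' @keywords internal
DEFAULT_THRESHOLD <- 0.75

#' Simulate one conversation trial
#'
#' Runs the full perception-action loop: at each step the environment emits
#' an observation; per-policy state beliefs, free energy `F` and expected
#' free energy `G` are updated for every policy consistent with the actions
#' executed so far; the policy posterior and Bayesian-model-averaged marginal
#' beliefs are recorded; and (before the final step) the next action is
#' selected and executed.
#'
#' @param model an [generative_model()].
#' @param script an [environment_script()]; its length must equal the model
#'   horizon.
#' @param threshold belief threshold used to flag hallucinations and
#'   false negatives in the returned record.
#' @return an `avh_trial` record: observations, executed actions, attenuation
#'   flags, final marginal beliefs (2 x T matrices), per-step policy
#'   posteriors, per-step `F`/`G`, plus `hallucination_steps` and
#'   `false_negative_steps`.
#' @examples
#' rec <- run_trial(generative_model(zeta = 0.3))
#' rec$hallucination_steps
#' @export
run_trial <- function(model, script = environment_script(),
                      threshold = DEFAULT_THRESHOLD) {
  T_ <- model$n_steps
  if (length(script$baseline_sequence) != T_)
    stop_invalid("script length %d does not match model horizon %d",
                 length(script$baseline_sequence), T_)
  catalog <- model$policy_catalog
  n_pi <- length(catalog)
  pol_names <- vapply(catalog, format, "")

  observations <- vector("list", T_)
  executed <- character(0)
  attenuation <- logical(T_)
  q_pi_history <- matrix(NA_real_, T_, n_pi,
                         dimnames = list(NULL, pol_names))
  F_history <- matrix(NA_real_, T_, n_pi, dimnames = list(NULL, pol_names))
  G_history <- matrix(NA_real_, T_, n_pi, dimnames = list(NULL, pol_names))
  beliefs_by_policy <- vector("list", n_pi)
  marginals <- NULL
  q_pi <- NULL

  for (t in seq_len(T_)) {
    incoming <- if (t == 1L) NA_character_ else executed[t - 1L]
    step <- env_step(script, incoming, t)
    observations[[t]] <- step$observation
    attenuation[t] <- step$attenuation

    mask <- vapply(catalog, function(p)
      t == 1L || identical(unclass(p)[seq_len(t - 1L)], executed), TRUE)

    F_vec <- rep(NA_real_, n_pi)
    G_vec <- rep(NA_real_, n_pi)
    for (i in which(mask)) {
      b <- update_state_beliefs(model, catalog[[i]], observations, t,
                                attenuation = attenuation)
      beliefs_by_policy[[i]] <- b
      F_vec[i] <- compute_policy_free_energy(model, catalog[[i]], b,
                                             observations, t,
                                             attenuation = attenuation)
      G_vec[i] <- compute_expected_free_energy(model, catalog[[i]], b, t)
    }
    q_pi <- policy_posterior(F_vec, G_vec, model$gamma_log, mask)
    marginals <- marginal_state_beliefs(beliefs_by_policy, q_pi)

    q_pi_history[t, ] <- q_pi
    F_history[t, ] <- F_vec
    G_history[t, ] <- G_vec
    if (t < T_)
      executed[t] <- select_action(q_pi, catalog, t)
  }

  record <- structure(list(
    config = list(n_steps = T_, zeta = model$zeta,
                  gamma_log = model$gamma_log,
                  auditory_likelihood_base = model$auditory_likelihood_base,
                  floor = model$floor,
                  policy_catalog = pol_names,
                  baseline = script$baseline_sequence,
                  speech_override = script$speech_override,
                  threshold = threshold),
    observations = observations,
    executed_actions = executed,
    attenuation = attenuation,
    marginal_auditory = marginals$auditory,
    marginal_speech = marginals$speech,
    policy_posterior = q_pi_history,
    free_energy = F_history,
    expected_free_energy = G_history
  ), class = "avh_trial")
  record$hallucination_steps <- detect_hallucinations(record, threshold)
  record$false_negative_steps <- detect_false_negatives(record, threshold)
  record
}

#' @export
print.avh_trial <- function(x, ...) {
  truth <- vapply(x$observations, `[[`, "", "auditory")
  cat(sprintf("<avh_trial> T = %d, zeta = %g, gamma_log = %g\n",
              x$config$n_steps, x$config$zeta, x$config$gamma_log))
  cat("  outcomes:  ", paste(ifelse(truth == "sound", "x", "-"),
                             collapse = " "), "\n")
  cat("  actions:   ", paste(ifelse(x$executed_actions == "listen",
                                    "L", "S"), collapse = "  "), "\n")
  cat("  P(voice):  ",
      paste(sprintf("%.3f", x$marginal_auditory["voice", ]), collapse = " "),
      "\n")
  cat("  hallucinations at:",
      if (length(x$hallucination_steps))
        paste(x$hallucination_steps, collapse = ", ") else "none", "\n")
  invisible(x)
}

trial_truth <- function(record)
  vapply(record$observations, `[[`, "", "auditory")

# Action executed on the transition *into* each step (NA at step 1).
incoming_actions <- function(record)
  c(NA_character_, record$executed_actions)

#' Detect hallucination steps
#'
#' A hallucination is a false positive percept: the marginal belief in
#' "voice present" exceeds `threshold` (strictly) at a step whose true
#' auditory outcome is silence and into which the agent did not speak.
#'
#' @param record an `avh_trial` from [run_trial()].
#' @param threshold probability in `[0.5, 1)`.
#' @return integer vector of flagged time steps (possibly empty).
#' @export
detect_hallucinations <- function(record, threshold = DEFAULT_THRESHOLD) {
  check_threshold(threshold)
  truth <- trial_truth(record)
  inc <- incoming_actions(record)
  belief_voice <- record$marginal_auditory["voice", ]
  which(belief_voice > threshold & truth == "silence" &
          (is.na(inc) | inc != "speak"))
}

#' Detect false-negative (speech-detection error) steps
#'
#' The mirror image of a hallucination: the marginal belief in "no voice"
#' exceeds `threshold` at a step whose true outcome is sound. Steps whose
#' sound was self-generated (the agent spoke into them) are included by
#' default -- ceasing to hear one's own voice is a reportable speech
#' detection error -- but can be excluded.
#'
#' @inheritParams detect_hallucinations
#' @param include_self_generated keep steps where the sound was produced by
#'   the agent's own speech (default `TRUE`).
#' @return integer vector of flagged time steps.
#' @export
detect_false_negatives <- function(record, threshold = DEFAULT_THRESHOLD,
                                   include_self_generated = TRUE) {
  check_threshold(threshold)
  truth <- trial_truth(record)
  inc <- incoming_actions(record)
  belief_novoice <- record$marginal_auditory["no_voice", ]
  flag <- belief_novoice > threshold & truth == "sound"
  if (!include_self_generated)
    flag <- flag & (is.na(inc) | inc != "speak")
  which(flag)
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0.5 || threshold >= 1)
    stop_invalid("`threshold` must lie in [0.5, 1)")
}

#' Run a preset in-silico experiment
#'
#' Reproduces one of the three manipulations:
#'
#' * `fig4_zeta_sweep`: fixture `F4` at `zeta` in `{0.7, 0.525, 0.3}`,
#'   baseline policy precision (`gamma_log = 0`).
#' * `fig5_gamma`: fixture `F4` at `zeta` in `{0.7, 0.525}` crossed with the
#'   low/high policy-precision presets (`gamma_log = -4` and `+4`).
#' * `fig6_lesion`: fixtures `F6_full` and `F6_lesioned` at `zeta` in
#'   `{0.7, 0.525, 0.3}`.
#'
#' @param name experiment name.
#' @param overrides named list overriding model/script settings shared by all
#'   cells: any of `zeta`, `gamma_log`, `auditory_likelihood_base`,
#'   `baseline`, `speech_override`, `threshold`, `n_steps`,
#'   `policy_catalog`. Overriding a swept parameter fixes it in every cell.
#' @return list with `records` (named list of `avh_trial`s, one per
#'   condition) and `summary` (data frame with one row per condition:
#'   experiment, condition, zeta, gamma_log, catalog, hallucination and
#'   false-negative steps as comma-separated strings, and their counts).
#' @examples
#' ex <- run_experiment("fig4_zeta_sweep")
#' ex$summary
#' @export
run_experiment <- function(name = c("fig4_zeta_sweep", "fig5_gamma",
                                    "fig6_lesion"),
                           overrides = list()) {
  if (length(name) == 1L && !name %in% c("fig4_zeta_sweep", "fig5_gamma",
                                         "fig6_lesion"))
    stop_invalid(
      "unknown experiment '%s'; valid: fig4_zeta_sweep, fig5_gamma, fig6_lesion",
      name)
  name <- match.arg(name)

  grid <- switch(name,
    fig4_zeta_sweep = data.frame(zeta = c(0.7, 0.525, 0.3), gamma_log = 0,
                                 catalog = "F4",
                                 stringsAsFactors = FALSE),
    fig5_gamma = expand.grid(zeta = c(0.7, 0.525),
                             gamma_log = c(low_gamma = -4, high_gamma = 4),
                             catalog = "F4",
                             stringsAsFactors = FALSE),
    fig6_lesion = expand.grid(zeta = c(0.7, 0.525, 0.3), gamma_log = 0,
                              catalog = c("F6_full", "F6_lesioned"),
                              stringsAsFactors = FALSE))

  get_over <- function(key, default) {
    if (!is.null(overrides[[key]])) overrides[[key]] else default
  }
  threshold <- get_over("threshold", DEFAULT_THRESHOLD)
  script <- environment_script(get_over("baseline", "-x-x-"),
                               get_over("speech_override", TRUE))

  records <- list()
  rows <- list()
  for (k in seq_len(nrow(grid))) {
    zeta <- get_over("zeta", grid$zeta[k])
    gamma_log <- get_over("gamma_log", grid$gamma_log[k])
    catalog_name <- grid$catalog[k]
    catalog <- if (!is.null(overrides$policy_catalog))
      lapply(overrides$policy_catalog, policy)
    else policy_fixture(catalog_name)
    model <- generative_model(
      n_steps = get_over("n_steps", length(script$baseline_sequence)),
      zeta = zeta,
      auditory_likelihood_base = get_over("auditory_likelihood_base",
                                          exp(-30)),
      gamma_log = gamma_log,
      policy_catalog = catalog)
    rec <- run_trial(model, script, threshold = threshold)
    condition <- sprintf("%s_zeta%g_gamma%g", catalog_name, zeta, gamma_log)
    records[[condition]] <- rec
    rows[[k]] <- data.frame(
      experiment = name, condition = condition, zeta = zeta,
      gamma_log = gamma_log, catalog = catalog_name,
      hallucination_steps = paste(rec$hallucination_steps, collapse = ","),
      n_hallucinations = length(rec$hallucination_steps),
      false_negative_steps = paste(rec$false_negative_steps, collapse = ","),
      n_false_negatives = length(rec$false_negative_steps),
      stringsAsFactors = FALSE)
  }
  list(records = records, summary = do.call(rbind, rows))
}
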