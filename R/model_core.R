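# Construction and validation of the agent's generative model: a two-factor,
# two-modality partially observed Markov decision process of a turn-taking
# conversation.
#
# State factors (two levels each, informative level first):
#   auditory: voice / no_voice   ("I am listening to a voice" or not)
#   speech:   speaking / not_speaking
# Outcome modalities:
#   auditory:       sound / silence
#   proprioceptive: speech_movement / none
# Actions (oppositional -- one per transition): listen / speak.

#' @name avhsim-labels
#' @title Canonical label sets
#' @description Label vectors used throughout the package. The first level of
#' every pair is the "positive" one (voice present, sound, speaking,
#' speech movement); the second its negation.
#' @keywords internal
NULL

AUD_STATES <- c("voice", "no_voice")
AUD_OUTCOMES <- c("sound", "silence")
SPK_STATES <- c("speaking", "not_speaking")
PRO_OUTCOMES <- c("speech_movement", "none")
ACTIONS <- c("listen", "speak")
STATE_FACTORS <- c("auditory", "speech")

#' Log-domain auditory likelihood
#'
#' The auditory likelihood is the column-normalized elementwise power
#' `(I + kappa)^zeta`, where `kappa` is a small imprecision constant and
#' `zeta` the likelihood precision. Working directly in log space keeps the
#' mapping exact for arbitrarily large `zeta` (where the probabilities
#' themselves underflow).
#'
#' @param zeta likelihood precision, `>= 0`.
#' @param base imprecision constant `kappa` in `(0, 1]`.
#' @return 2x2 matrix of column-normalized log probabilities,
#'   `log P(o | s)`, states in columns.
#' @keywords internal
auditory_likelihood_log <- function(zeta, base) {
  if (!is.numeric(zeta) || length(zeta) != 1L || is.na(zeta) || zeta < 0)
    stop_invalid("`zeta` must be a single non-negative number, got %s",
                 format(zeta))
  if (!is.numeric(base) || length(base) != 1L || is.na(base) ||
      base <= 0 || base > 1)
    stop_invalid("`base` must lie in (0, 1], got %s", format(base))
  on_diag <- zeta * log1p(base)
  off_diag <- zeta * log(base)
  z <- logsumexp(c(on_diag, off_diag))
  m <- matrix(c(on_diag, off_diag, off_diag, on_diag) - z, nrow = 2)
  dimnames(m) <- list(AUD_OUTCOMES, AUD_STATES)
  m
}

#' Build the auditory likelihood matrix
#'
#' Constructs the state-to-outcome mapping for the auditory modality,
#' `P(o^a | s^a)`. Without attenuation this is the column-normalized
#' elementwise power `(I + base)^zeta`: the diagonal holds
#' `(1 + base)^zeta / Z` and the off-diagonal `base^zeta / Z` with `Z` the
#' column sum. Increasing `zeta` sharpens the mapping towards the identity
#' (high-fidelity hearing); `zeta = 0` flattens it to uniform. During overt
#' speech the agent applies sensory attenuation, replacing the mapping by the
#' uniform matrix so that auditory evidence carries no information about the
#' listening state.
#'
#' @param zeta likelihood precision, a non-negative scalar.
#' @param base imprecision constant in `(0, 1]`; the default `exp(-30)`
#'   produces, together with the `exp(-16)` floor used for deterministic
#'   transition priors, the precision regimes in which sensory evidence
#'   dominates (`zeta = 0.7`), balances (`zeta = 0.525`) or is dominated by
#'   (`zeta = 0.3`) policy-derived state priors.
#' @param attenuated logical; if `TRUE` return the uniform (fully attenuated)
#'   matrix regardless of `zeta` and `base`.
#' @return 2x2 column-stochastic matrix with outcomes in rows
#'   (`sound`, `silence`) and states in columns (`voice`, `no_voice`).
#' @examples
#' build_auditory_likelihood(0.7)                  # near-identity mapping
#' build_auditory_likelihood(0.7, base = exp(-3))  # diagonal ~ 0.894
#' build_auditory_likelihood(2, attenuated = TRUE) # uniform
#' @export
build_auditory_likelihood <- function(zeta, base = exp(-30),
                                      attenuated = FALSE) {
  if (isTRUE(attenuated)) {
    # validate parameters even when unused, so bad configs fail early
    if (is.numeric(zeta) && length(zeta) == 1L && !is.na(zeta) && zeta < 0)
      stop_invalid("`zeta` must be non-negative")
    m <- matrix(0.5, 2, 2, dimnames = list(AUD_OUTCOMES, AUD_STATES))
    return(m)
  }
  exp(auditory_likelihood_log(zeta, base))
}

#' Build the proprioceptive likelihood matrix
#'
#' Proprioception reports the speaking state faithfully: the likelihood is the
#' identity matrix (speaking maps to speech movement with probability 1).
#' A tiny floor may be requested for callers that need strictly positive
#' entries; the inference engine instead floors exact zeros in the log domain.
#'
#' @param floor optional probability floor added to zero entries before
#'   renormalization; default 0 (exact identity).
#' @return 2x2 column-stochastic matrix, rows `speech_movement`/`none`,
#'   columns `speaking`/`not_speaking`.
#' @export
build_proprioceptive_likelihood <- function(floor = 0) {
  if (floor < 0 || floor >= 1) stop_invalid("`floor` must lie in [0, 1)")
  m <- norm_cols(diag(2) + floor)
  dimnames(m) <- list(PRO_OUTCOMES, SPK_STATES)
  m
}

#' Build action-conditioned transition matrices
#'
#' Transitions are deterministic consequences of the chosen action, reflecting
#' the oppositional turn-taking semantics: choosing to `speak` drives the
#' speech factor into `speaking` and -- because taking one's turn silences the
#' interlocutor -- the auditory factor into `no_voice`; choosing to `listen`
#' drives the speech factor into `not_speaking` and the auditory factor into
#' `voice` (listening is the bundle of things one does *expecting* to hear a
#' voice, so the policy itself is a source of the prior "a voice is there").
#' Columns are one-hot up to the floor `eps`, which stands in for exact zeros
#' so that log-domain messages stay finite.
#'
#' @param action `"listen"` or `"speak"`.
#' @param eps floor replacing exact zeros; default `exp(-16)`.
#' @return named list with 2x2 column-stochastic matrices `auditory` and
#'   `speech` (columns indexed by previous state).
#' @export
build_transition <- function(action, eps = exp(-16)) {
  if (!is.character(action) || length(action) != 1L ||
      !(action %in% ACTIONS))
    stop_invalid("unknown action '%s' (must be one of: %s)",
                 paste(action, collapse = ","), paste(ACTIONS, collapse = ", "))
  one_hot <- function(i) {
    col <- c(eps, eps)
    col[i] <- 1
    col / sum(col)
  }
  to <- function(i, states) {
    m <- cbind(one_hot(i), one_hot(i))
    rownames(m) <- states
    colnames(m) <- states
    m
  }
  if (action == "speak") {
    list(auditory = to(2L, AUD_STATES), speech = to(1L, SPK_STATES))
  } else {
    list(auditory = to(1L, AUD_STATES), speech = to(2L, SPK_STATES))
  }
}

#' Define a policy
#'
#' A policy is a fixed sequence of actions, one per transition, so a trial of
#' `T` time steps uses policies of length `T - 1`. Policies may be given as a
#' character vector of action labels or as a compact string over the alphabet
#' `L` (listen) / `S` (speak), e.g. `"SLSL"`.
#'
#' @param actions character vector of `"listen"`/`"speak"` labels, or a single
#'   compact string such as `"LLSS"`.
#' @return an `avh_policy` object (character vector of action labels).
#' @examples
#' policy("SLSL")
#' policy(c("listen", "speak"))
#' @export
policy <- function(actions) {
  if (length(actions) == 1L && !actions %in% ACTIONS) {
    letters_ <- strsplit(actions, "")[[1]]
    if (!all(letters_ %in% c("L", "S")))
      stop_invalid("compact policy strings may only contain 'L' and 'S': '%s'",
                   actions)
    actions <- ifelse(letters_ == "L", "listen", "speak")
  }
  if (!all(actions %in% ACTIONS))
    stop_invalid("policy actions must be 'listen' or 'speak'")
  structure(as.character(actions), class = "avh_policy")
}

#' @export
format.avh_policy <- function(x, ...) {
  paste(ifelse(unclass(x) == "listen", "L", "S"), collapse = "")
}

#' @export
print.avh_policy <- function(x, ...) {
  cat("<policy>", format(x), "\n")
  invisible(x)
}

#' Construct an observation
#'
#' One time step's outcome pair. Both modalities must be present.
#'
#' @param auditory `"sound"` or `"silence"`.
#' @param proprioceptive `"speech_movement"` or `"none"`.
#' @return an `avh_observation` object.
#' @export
observation <- function(auditory, proprioceptive) {
  if (!(auditory %in% AUD_OUTCOMES))
    stop_invalid("auditory outcome must be one of: %s",
                 paste(AUD_OUTCOMES, collapse = ", "))
  if (!(proprioceptive %in% PRO_OUTCOMES))
    stop_invalid("proprioceptive outcome must be one of: %s",
                 paste(PRO_OUTCOMES, collapse = ", "))
  structure(list(auditory = auditory, proprioceptive = proprioceptive),
            class = "avh_observation")
}

#' Construct the agent's generative model
#'
#' Bundles the components of the conversing agent's model: likelihood
#' precision `zeta` over the auditory mapping, log policy precision
#' `gamma_log`, deterministic action-conditioned transitions, flat outcome
#' preferences, uniform initial-state beliefs and a policy catalog.
#'
#' @param n_steps trial horizon `T` (observations at `1..T`; policies carry
#'   `T - 1` actions).
#' @param zeta auditory likelihood precision (non-negative scalar).
#' @param auditory_likelihood_base imprecision constant for the auditory
#'   likelihood; see [build_auditory_likelihood()].
#' @param gamma_log natural log of the policy precision `gamma`.
#' @param policy_catalog list of [policy()] objects (or compact strings).
#' @param preferences optional named list of log-preference vectors over
#'   outcomes, elements `auditory` and `proprioceptive`; default flat.
#' @param initial_beliefs optional named list of initial-state distributions,
#'   elements `auditory` and `speech`; default uniform.
#' @param floor probability standing in for exact zeros of deterministic
#'   mappings when logs are taken; default `exp(-16)`.
#' @return an `avh_model` object.
#' @examples
#' m <- generative_model(zeta = 0.3)
#' validate_model(m)
#' @export
generative_model <- function(n_steps = 5L,
                             zeta = 0.7,
                             auditory_likelihood_base = exp(-30),
                             gamma_log = 0,
                             policy_catalog = policy_fixture("F4"),
                             preferences = NULL,
                             initial_beliefs = NULL,
                             floor = exp(-16)) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop_invalid("`n_steps` must be at least 1")
  # validates zeta/base as a side effect
  invisible(auditory_likelihood_log(zeta, auditory_likelihood_base))
  if (!is.numeric(gamma_log) || length(gamma_log) != 1L || is.na(gamma_log))
    stop_invalid("`gamma_log` must be a single real number")
  policy_catalog <- lapply(policy_catalog, function(p)
    if (inherits(p, "avh_policy")) p else policy(p))
  if (is.null(preferences))
    preferences <- list(auditory = log(c(0.5, 0.5)),
                        proprioceptive = log(c(0.5, 0.5)))
  if (is.null(initial_beliefs))
    initial_beliefs <- list(auditory = c(0.5, 0.5), speech = c(0.5, 0.5))
  model <- structure(list(
    n_steps = n_steps,
    zeta = zeta,
    auditory_likelihood_base = auditory_likelihood_base,
    gamma_log = gamma_log,
    transition_model = list(listen = build_transition("listen", floor),
                            speak = build_transition("speak", floor)),
    preferences = preferences,
    initial_beliefs = initial_beliefs,
    policy_catalog = policy_catalog,
    floor = floor
  ), class = "avh_model")
  viol <- validate_model(model)
  if (length(viol))
    stop_invalid("invalid generative model:\n  - %s",
                 paste(viol, collapse = "\n  - "))
  model
}

#' @export
print.avh_model <- function(x, ...) {
  cat(sprintf(
    "<avh_model> T = %d, zeta = %g, gamma_log = %g, %d policies (%s)\n",
    x$n_steps, x$zeta, x$gamma_log, length(x$policy_catalog),
    paste(vapply(x$policy_catalog, format, ""), collapse = " ")))
  invisible(x)
}

#' Validate a generative model
#'
#' Checks the structural invariants of an [generative_model()] object and
#' returns a character vector describing every violation (empty when the
#' model is valid). Violations are returned, not raised, so callers can
#' report them all at once.
#'
#' @param model an `avh_model` (or a hand-built list with the same fields).
#' @return character vector of violation descriptions.
#' @export
validate_model <- function(model) {
  viol <- character(0)
  tol <- 1e-10
  for (a in names(model$transition_model)) {
    for (f in names(model$transition_model[[a]])) {
      m <- model$transition_model[[a]][[f]]
      if (any(abs(colSums(m) - 1) > tol))
        viol <- c(viol, sprintf(
          "transition_model$%s$%s: columns must sum to 1 (tol %g)", a, f, tol))
    }
  }
  for (f in names(model$initial_beliefs)) {
    d <- model$initial_beliefs[[f]]
    if (abs(sum(d) - 1) > tol || any(d < 0))
      viol <- c(viol, sprintf("initial_beliefs$%s: not a distribution", f))
  }
  if (!length(model$policy_catalog)) {
    viol <- c(viol, "policy_catalog: must be non-empty")
  } else {
    len <- vapply(model$policy_catalog, length, 0L)
    bad <- which(len != model$n_steps - 1L)
    if (length(bad))
      viol <- c(viol, sprintf(
        "policy_catalog: policy %s has %d actions, expected n_steps - 1 = %d",
        paste(bad, collapse = ","), len[bad][1], model$n_steps - 1L))
  }
  if (!is.null(model$zeta) && model$zeta < 0)
    viol <- c(viol, "zeta: must be non-negative")
  viol
}
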