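# Variational inference for the conversing agent: per-policy state estimation
# by mean-field message passing, policy-conditioned free energy F, expected
# free energy G, the precision-weighted policy posterior, Bayesian model
# averaging of state beliefs, and action selection.

# -- internal log-domain components ------------------------------------------

# Log auditory likelihood at time tau, honouring sensory attenuation.
log_aud_likelihood <- function(model, attenuated) {
  if (attenuated)
    matrix(log(0.5), 2, 2, dimnames = list(AUD_OUTCOMES, AUD_STATES))
  else
    auditory_likelihood_log(model$zeta, model$auditory_likelihood_base)
}

log_pro_likelihood <- function(model) {
  log_floored(build_proprioceptive_likelihood(), model$floor)
}

# Attenuation schedule implied by a policy: the likelihood at time tau is
# attenuated iff the action taken on the transition into tau was "speak".
# tau = 1 has no incoming action and is never attenuated.
policy_attenuation <- function(policy, n_steps) {
  c(FALSE, unclass(policy) == "speak")[seq_len(n_steps)]
}

obs_index <- function(observations, modality) {
  labels <- if (modality == "auditory") AUD_OUTCOMES else PRO_OUTCOMES
  vapply(observations, function(o) match(o[[modality]], labels), 0L)
}

# -- state estimation --------------------------------------------------------

#' Update per-policy state beliefs by mean-field message passing
#'
#' Runs the fixed-point iteration of the mean-field belief updates for one
#' policy. Each factor's belief at time `tau` is the normalized exponential of
#' the sum of (i) the log-likelihood message of the observation at `tau`
#' (observed steps only, using the attenuation-aware likelihood), (ii) the
#' forward message `log(B q_{tau-1})` through the policy's transition, and
#' (iii) the backward message `log(B' q_{tau+1})`. Future steps carry no
#' likelihood message, so beliefs beyond `current_time` are pure policy
#' rollouts. Sweeps continue until the largest belief change drops below
#' `tol` or `max_iter` sweeps have run (non-convergence yields a warning,
#' never an error).
#'
#' @param model an [generative_model()].
#' @param policy an [policy()] with `n_steps - 1` actions.
#' @param observations list of [observation()]s for times `1..current_time`.
#' @param current_time last observed time step.
#' @param attenuation logical vector, `attenuation[tau]` marks sensory
#'   attenuation of the auditory likelihood at `tau`; defaults to the
#'   schedule implied by the policy's own actions.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   maximum absolute belief change.
#' @return list with 2 x `n_steps` belief matrices `auditory` and `speech`
#'   (columns are time steps), plus `iterations` and `converged`.
#' @export
update_state_beliefs <- function(model, policy, observations, current_time,
                                 attenuation = NULL,
                                 max_iter = 16L, tol = 1e-6) {
  T_ <- model$n_steps
  stopifnot(current_time >= 1L, current_time <= T_,
            length(observations) >= current_time)
  acts <- unclass(policy)
  if (is.null(attenuation)) attenuation <- policy_attenuation(policy, T_)

  logB <- lapply(model$transition_model, function(tm)
    lapply(tm, log_floored, floor = model$floor))
  B <- model$transition_model
  logD <- lapply(model$initial_beliefs, log_floored, floor = model$floor)

  logA_pro <- log_pro_likelihood(model)
  logA_aud <- lapply(seq_len(current_time), function(tau)
    log_aud_likelihood(model, attenuation[tau]))
  oa <- obs_index(observations[seq_len(current_time)], "auditory")
  op <- obs_index(observations[seq_len(current_time)], "proprioceptive")

  q <- list(auditory = matrix(0.5, 2, T_), speech = matrix(0.5, 2, T_))
  rownames(q$auditory) <- AUD_STATES
  rownames(q$speech) <- SPK_STATES

  lik_msg <- function(factor, tau) {
    if (tau > current_time) return(c(0, 0))
    if (factor == "auditory") logA_aud[[tau]][oa[tau], ]
    else logA_pro[op[tau], ]
  }

  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (factor in STATE_FACTORS) {
      for (tau in seq_len(T_)) {
        v <- lik_msg(factor, tau)
        if (tau == 1L) {
          v <- v + logD[[factor]]
        } else {
          v <- v + log(B[[acts[tau - 1L]]][[factor]] %*%
                         q[[factor]][, tau - 1L])[, 1L]
        }
        if (tau < T_) {
          v <- v + log(t(B[[acts[tau]]][[factor]]) %*%
                         q[[factor]][, tau + 1L])[, 1L]
        }
        new_q <- softmax_log(v)
        delta <- max(delta, max(abs(new_q - q[[factor]][, tau])))
        q[[factor]][, tau] <- new_q
      }
    }
    iterations <- it
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf(
      "mean-field updates did not converge in %d sweeps (policy %s)",
      max_iter, format(policy)), call. = FALSE)
  list(auditory = q$auditory, speech = q$speech,
       iterations = iterations, converged = converged)
}

# -- free energies -----------------------------------------------------------

#' Policy-conditioned variational free energy
#'
#' Evaluates `F(pi) = E_Q[log Q(s|pi) - log P(o, s|pi)]` over the observed
#' time steps, with the generative density factorized into initial beliefs
#' `D`, the policy's transitions `B`, and attenuation-aware likelihoods.
#' `F(pi)` upper-bounds the negative log evidence for the policy and is tight
#' when the beliefs equal the exact posterior.
#'
#' @inheritParams update_state_beliefs
#' @param beliefs output of [update_state_beliefs()] for this policy.
#' @return scalar free energy (nats).
#' @export
compute_policy_free_energy <- function(model, policy, beliefs, observations,
                                       current_time, attenuation = NULL) {
  T_ <- model$n_steps
  acts <- unclass(policy)
  if (is.null(attenuation)) attenuation <- policy_attenuation(policy, T_)
  logB <- lapply(model$transition_model, function(tm)
    lapply(tm, log_floored, floor = model$floor))
  logD <- lapply(model$initial_beliefs, log_floored, floor = model$floor)
  logA_pro <- log_pro_likelihood(model)
  oa <- obs_index(observations[seq_len(current_time)], "auditory")
  op <- obs_index(observations[seq_len(current_time)], "proprioceptive")

  F_ <- 0
  for (factor in STATE_FACTORS) {
    qf <- beliefs[[factor]]
    for (tau in seq_len(current_time)) {
      qt <- qf[, tau]
      F_ <- F_ + sum(xlogx(qt))                       # entropy term E[ln Q]
      if (tau == 1L) {
        F_ <- F_ - sum(qt * logD[[factor]])
      } else {
        lB <- logB[[acts[tau - 1L]]][[factor]]
        F_ <- F_ - sum(qt * (lB %*% qf[, tau - 1L]))  # E[ln B]
      }
      lik <- if (factor == "auditory")
        log_aud_likelihood(model, attenuation[tau])[oa[tau], ]
      else logA_pro[op[tau], ]
      F_ <- F_ - sum(qt * lik)                        # E[ln A[o_tau, ]]
    }
  }
  F_
}

#' Expected free energy of a policy
#'
#' Scores the future (unobserved) segment of a policy as the sum over future
#' steps and modalities of risk plus ambiguity: with predicted outcome
#' distribution `o = A s`, risk is `o . (log o - C)` (divergence of predicted
#' outcomes from log preferences `C`) and ambiguity is `s . H`, where `H_j`
#' is the entropy of column `j` of the (attenuation-aware) likelihood. With
#' flat preferences -- the default -- policy value is purely epistemic.
#'
#' @inheritParams compute_policy_free_energy
#' @return scalar expected free energy (nats).
#' @export
compute_expected_free_energy <- function(model, policy, beliefs,
                                         current_time) {
  T_ <- model$n_steps
  if (current_time >= T_) return(0)
  atten <- policy_attenuation(policy, T_)
  A_pro <- build_proprioceptive_likelihood()
  C <- model$preferences
  G <- 0
  for (tau in (current_time + 1L):T_) {
    A_aud <- build_auditory_likelihood(model$zeta,
                                       model$auditory_likelihood_base,
                                       attenuated = atten[tau])
    for (modality in c("auditory", "proprioceptive")) {
      A <- if (modality == "auditory") A_aud else A_pro
      s <- beliefs[[if (modality == "auditory") "auditory" else
        "speech"]][, tau]
      o <- as.numeric(A %*% s)
      risk <- sum(xlogx(o)) - sum(o * C[[modality]])
      H <- apply(A, 2, entropy)
      G <- G + risk + sum(s * H)
    }
  }
  G
}

# -- policy posterior and model averaging ------------------------------------

#' Posterior distribution over policies
#'
#' Combines accumulated evidence and prospective value:
#' `Q(pi) = softmax(-F(pi) - gamma * G(pi))` over the policies flagged
#' consistent with the actions executed so far, with
#' `gamma = exp(gamma_log)`. Inconsistent (masked) policies receive exactly
#' zero mass; masking implements conditioning on observed behavior.
#'
#' @param F_vector,G_vector free energies and expected free energies aligned
#'   with the policy catalog (masked entries may be `NA`).
#' @param gamma_log log policy precision.
#' @param consistency_mask logical vector flagging policies consistent with
#'   executed actions; default all `TRUE`.
#' @return numeric probability vector over the catalog.
#' @export
policy_posterior <- function(F_vector, G_vector, gamma_log,
                             consistency_mask = NULL) {
  n <- length(F_vector)
  if (is.null(consistency_mask)) consistency_mask <- rep(TRUE, n)
  if (!any(consistency_mask))
    stop_invalid("all policies are masked: no viable explanation of behavior")
  gamma <- exp(gamma_log)
  x <- rep(-Inf, n)
  x[consistency_mask] <- -F_vector[consistency_mask] -
    gamma * G_vector[consistency_mask]
  softmax_log(x)
}

#' Bayesian model averaging of state beliefs
#'
#' Marginal state beliefs are the policy-posterior-weighted average of the
#' per-policy conditionals: `Q(s_tau) = sum_pi Q(s_tau | pi) Q(pi)`.
#'
#' @param per_policy_states list (one element per policy) of belief lists as
#'   returned by [update_state_beliefs()]; entries for zero-mass policies may
#'   be `NULL`.
#' @param policy_posterior probability vector over the same policies.
#' @return list of 2 x T marginal belief matrices `auditory` and `speech`.
#' @export
marginal_state_beliefs <- function(per_policy_states, policy_posterior) {
  stopifnot(length(per_policy_states) == length(policy_posterior))
  active <- which(policy_posterior > 0)
  if (!length(active)) stop_invalid("policy posterior has no mass")
  out <- list()
  for (factor in STATE_FACTORS) {
    acc <- 0
    for (i in active)
      acc <- acc + policy_posterior[i] * per_policy_states[[i]][[factor]]
    out[[factor]] <- norm_cols(acc)
  }
  out
}

#' Select the next action
#'
#' Aggregates posterior policy mass by the action each policy prescribes at
#' the current transition and returns the action with the larger mass. Ties
#' (within `tie_tol`) resolve deterministically in favour of `listen`; with
#' only two actions the seed argument is kept for interface stability and
#' never consulted, so runs are reproducible by construction.
#'
#' @param policy_posterior probability vector over `policy_catalog`.
#' @param policy_catalog list of [policy()] objects.
#' @param current_time the transition index (action taken between
#'   `current_time` and `current_time + 1`); must be `< n_steps`.
#' @param tie_break_seed unused placeholder for deterministic tie-breaking
#'   beyond the listen-first rule.
#' @param tie_tol absolute mass difference treated as a tie.
#' @return `"listen"` or `"speak"`.
#' @export
select_action <- function(policy_posterior, policy_catalog, current_time,
                          tie_break_seed = NULL, tie_tol = 1e-9) {
  prescribed <- vapply(policy_catalog,
                       function(p) unclass(p)[current_time], "")
  mass <- c(listen = sum(policy_posterior[prescribed == "listen"]),
            speak = sum(policy_posterior[prescribed == "speak"]))
  if (abs(mass["listen"] - mass["speak"]) <= tie_tol) return("listen")
  names(mass)[which.max(mass)]
}
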