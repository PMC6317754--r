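# Exact brute-force references for the variational engine. The oracles
# enumerate every hidden-state trajectory under the same floored matrices the
# engine uses, so comparisons isolate the factorization error of the
# mean-field scheme (which is zero here: the two factors are conditionally
# independent given a policy).

#' Exact state posterior by enumeration
#'
#' Enumerates every state trajectory over the observed horizon for one
#' policy, scores it under `D x prod(B) x prod(A)` (attenuation-aware
#' likelihoods on observed steps), and normalizes. The two state factors are
#' independent given the policy, so enumeration runs per factor and the
#' joint is their product; the enumeration refuses problems with more than
#' `1e5` trajectories.
#'
#' @inheritParams update_state_beliefs
#' @return an `EnumerationResult` list: per-factor trajectory posteriors
#'   (`joint`), exact per-time marginals (`marginals`, 2 x t matrices),
#'   per-factor and total log evidence.
#' @export
exact_state_posterior <- function(model, policy, observations,
                                  attenuation = NULL) {
  t_obs <- length(observations)
  stopifnot(t_obs >= 1L)
  n_traj <- 2^t_obs
  if (2 * n_traj > 1e5)
    stop_invalid("state space too large to enumerate: %g trajectories",
                 2 * n_traj)
  acts <- unclass(policy)
  if (is.null(attenuation)) attenuation <- policy_attenuation(policy, t_obs)

  logD <- lapply(model$initial_beliefs, log_floored, floor = model$floor)
  logB <- lapply(model$transition_model, function(tm)
    lapply(tm, log_floored, floor = model$floor))
  logA_pro <- log_pro_likelihood(model)
  logA_aud <- lapply(seq_len(t_obs), function(tau)
    log_aud_likelihood(model, attenuation[tau]))
  oa <- obs_index(observations, "auditory")
  op <- obs_index(observations, "proprioceptive")

  grid <- as.matrix(expand.grid(rep(list(1:2), t_obs)))

  enumerate_factor <- function(factor) {
    states <- if (factor == "auditory") AUD_STATES else SPK_STATES
    logw <- apply(grid, 1, function(s) {
      w <- logD[[factor]][s[1]]
      if (t_obs > 1L) for (tau in 2:t_obs)
        w <- w + logB[[acts[tau - 1L]]][[factor]][s[tau], s[tau - 1L]]
      for (tau in seq_len(t_obs)) {
        w <- w + if (factor == "auditory") logA_aud[[tau]][oa[tau], s[tau]]
        else logA_pro[op[tau], s[tau]]
      }
      w
    })
    log_ev <- logsumexp(logw)
    post <- exp(logw - log_ev)
    marg <- matrix(0, 2, t_obs, dimnames = list(states, NULL))
    for (tau in seq_len(t_obs))
      for (i in 1:2)
        marg[i, tau] <- sum(post[grid[, tau] == i])
    list(posterior = post, marginals = marg, log_evidence = log_ev)
  }

  aud <- enumerate_factor("auditory")
  spk <- enumerate_factor("speech")
  structure(list(
    joint = list(auditory = aud$posterior, speech = spk$posterior),
    marginals = list(auditory = aud$marginals, speech = spk$marginals),
    log_evidence_by_factor = c(auditory = aud$log_evidence,
                               speech = spk$log_evidence),
    log_evidence = aud$log_evidence + spk$log_evidence
  ), class = "EnumerationResult")
}

#' Exact policy posterior
#'
#' Replaces the variational `-F(pi)` with the exact log evidence of each
#' policy (from [exact_state_posterior()]) and applies the same
#' precision-weighted softmax and consistency masking as the engine:
#' `Q(pi) = softmax(log_evidence(pi) - gamma * G(pi))`.
#'
#' @inheritParams update_state_beliefs
#' @param gamma_log log policy precision.
#' @param G_vector optional expected-free-energy vector aligned with the
#'   catalog; defaults to zeros (evidence-only posterior).
#' @param consistency_mask logical vector over the catalog; masked policies
#'   get exactly zero mass.
#' @return probability vector over the model's policy catalog.
#' @export
exact_policy_posterior <- function(model, observations, gamma_log,
                                   G_vector = NULL,
                                   consistency_mask = NULL) {
  catalog <- model$policy_catalog
  n <- length(catalog)
  if (is.null(G_vector)) G_vector <- rep(0, n)
  if (is.null(consistency_mask)) consistency_mask <- rep(TRUE, n)
  if (!any(consistency_mask))
    stop_invalid("all policies are masked: no viable explanation of behavior")
  log_ev <- vapply(catalog, function(p)
    exact_state_posterior(model, p, observations)$log_evidence, 0)
  x <- rep(-Inf, n)
  gamma <- exp(gamma_log)
  x[consistency_mask] <- log_ev[consistency_mask] -
    gamma * G_vector[consistency_mask]
  softmax_log(x)
}
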