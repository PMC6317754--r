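test_that("precise likelihoods invert observations exactly", {
  # near-identity mapping (zeta = 5, kappa = e^-30): a single observation
  # pins the state
  m <- generative_model(n_steps = 1, zeta = 5, policy_catalog = list(policy("")))
  b <- update_state_beliefs(m, m$policy_catalog[[1]],
                            list(observation("sound", "none")), 1)
  expect_gt(b$auditory["voice", 1], 1 - 1e-9)
  expect_gt(b$speech["not_speaking", 1], 1 - 1e-6)
  expect_true(b$converged)
})

test_that("a flat (attenuated) auditory likelihood carries no information", {
  m <- generative_model(n_steps = 1, policy_catalog = list(policy("")))
  for (out in c("sound", "silence")) {
    b <- update_state_beliefs(m, m$policy_catalog[[1]],
                              list(observation(out, "none")), 1,
                              attenuation = TRUE)
    expect_equal(unname(b$auditory[, 1]), c(0.5, 0.5), tolerance = 1e-10)
  }
})

test_that("variational beliefs match exact enumeration on a two-step trial", {
  m <- generative_model(n_steps = 2, zeta = 0.7,
                        auditory_likelihood_base = exp(-3),
                        policy_catalog = list(policy("L")))
  pol <- m$policy_catalog[[1]]
  obs <- scripted_observations(pol, environment_script("-x"))
  b <- update_state_beliefs(m, pol, obs, 2)
  ex <- exact_state_posterior(m, pol, obs)
  expect_lt(max(abs(b$auditory - ex$marginals$auditory)), 1e-6)
  expect_lt(max(abs(b$speech - ex$marginals$speech)), 1e-6)
})

test_that("free energy upper-bounds negative log evidence and is tight at the posterior", {
  script <- environment_script("-x")
  for (zeta in c(0.3, 0.7, 5)) {
    m <- generative_model(n_steps = 2, zeta = zeta,
                          policy_catalog = list(policy("L"), policy("S")))
    for (pol in m$policy_catalog) {
      obs <- scripted_observations(pol, script)
      b <- update_state_beliefs(m, pol, obs, 2)
      F_ <- compute_policy_free_energy(m, pol, b, obs, 2)
      ex <- exact_state_posterior(m, pol, obs)
      expect_gte(F_, -ex$log_evidence - 1e-10)
      # converged mean-field beliefs are the exact posterior here, so the
      # bound is tight
      expect_equal(F_, -ex$log_evidence, tolerance = 1e-6)
      # deliberately wrong beliefs loosen the bound but never violate it
      b_bad <- b
      b_bad$auditory[] <- 0.5
      F_bad <- compute_policy_free_energy(m, pol, b_bad, obs, 2)
      expect_gte(F_bad, -ex$log_evidence - 1e-10)
    }
  }
})

test_that("expected free energy decomposes into risk and ambiguity", {
  # fully imprecise mapping: every future step contributes log 2 of auditory
  # ambiguity (risk vanishes for uniform predicted outcomes) plus log 2 of
  # proprioceptive risk under flat normalized log-preferences
  m0 <- generative_model(n_steps = 2, zeta = 0,
                         policy_catalog = list(policy("L")))
  pol <- m0$policy_catalog[[1]]
  obs <- list(observation("silence", "none"))
  b <- update_state_beliefs(m0, pol, obs, 1)
  G0 <- compute_expected_free_energy(m0, pol, b, 1)
  expect_equal(G0, 2 * log(2), tolerance = 1e-4)

  # near-identity mapping: auditory ambiguity collapses towards zero and the
  # risk term replaces it -- total per-step G is bounded by 2 log 2
  m1 <- generative_model(n_steps = 2, zeta = 5,
                         policy_catalog = list(policy("L")))
  b1 <- update_state_beliefs(m1, pol, obs, 1)
  G1 <- compute_expected_free_energy(m1, pol, b1, 1)
  A <- build_auditory_likelihood(5, exp(-30))
  expect_lt(sum(apply(A, 2, function(p) -sum(p[p > 0] * log(p[p > 0])))),
            1e-6)
  expect_equal(G1, 2 * log(2), tolerance = 1e-4)
  expect_equal(compute_expected_free_energy(m1, pol, b1, 2), 0)
})

test_that("policy posterior applies the precision-weighted softmax with masking", {
  expect_equal(policy_posterior(c(1, 1), c(2, 2), 0), c(0.5, 0.5))
  # direct softmax arithmetic: gamma = 1, F = 0, G = (1, 2)
  expect_equal(policy_posterior(c(0, 0), c(1, 2), 0),
               c(exp(-1), exp(-2)) / (exp(-1) + exp(-2)), tolerance = 1e-12)
  expect_equal(policy_posterior(c(0, 0), c(1, 2), 0)[1], 0.7310586,
               tolerance = 1e-6)
  # zero-precision limit ignores G entirely
  expect_equal(policy_posterior(c(0, 0, 0), c(5, 1, 9), -Inf),
               rep(1 / 3, 3))
  # masked policies get exactly zero mass
  q <- policy_posterior(c(0, 0, 0), c(0, 0, 0), 0, c(TRUE, FALSE, TRUE))
  expect_identical(q[2], 0)
  expect_equal(sum(q), 1)
  expect_error(policy_posterior(0, 0, 0, FALSE), "masked")
})

test_that("softmax computations are shift invariant (log-sum-exp stability)", {
  F_ <- c(1000, 1001, 999.5)
  G_ <- c(3, 1, 2)
  expect_equal(policy_posterior(F_, G_, 1.5),
               policy_posterior(F_ - 1000, G_, 1.5), tolerance = 1e-12)
  expect_equal(policy_posterior(F_, G_ + 50, 1.5),
               policy_posterior(F_, G_, 1.5), tolerance = 1e-12)
})

test_that("marginal beliefs are the policy-weighted mixture", {
  one_hot <- function(i, T_ = 1) {
    m <- matrix(0, 2, T_)
    m[i, ] <- 1
    m
  }
  pps <- list(list(auditory = one_hot(1), speech = one_hot(2)),
              list(auditory = one_hot(2), speech = one_hot(2)))
  # degenerate mixture
  marg <- marginal_state_beliefs(pps, c(1, 0))
  expect_equal(unname(marg$auditory[, 1]), c(1, 0))
  # hand-computed weighted average
  marg <- marginal_state_beliefs(pps, c(0.75, 0.25))
  expect_equal(unname(marg$auditory[, 1]), c(0.75, 0.25))
  expect_equal(sum(marg$auditory[, 1]), 1, tolerance = 1e-10)
  expect_equal(sum(marg$speech[, 1]), 1, tolerance = 1e-10)
})

test_that("action selection aggregates mass with a listen-first tie break", {
  catalog <- list(policy("LL"), policy("SL"), policy("SS"))
  expect_identical(select_action(c(0, 1, 0), catalog, 1), "speak")
  expect_identical(select_action(c(0.6, 0.3, 0.1), catalog, 1), "listen")
  expect_identical(select_action(c(0.5, 0.25, 0.25), catalog, 1), "listen")
  # at the second transition SL prescribes listen
  expect_identical(select_action(c(0.1, 0.5, 0.4), catalog, 2), "listen")
})
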