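test_that("policy-catalog fixtures have the documented composition", {
  f4 <- policy_fixture("F4")
  full <- policy_fixture("F6_full")
  les <- policy_fixture("F6_lesioned")
  expect_length(f4, 4)
  expect_length(full, 6)
  expect_length(les, 5)
  expect_setdiff <- setdiff(vapply(full, format, ""),
                            vapply(les, format, ""))
  expect_identical(expect_setdiff, "SSLL")
  expect_true(all(vapply(f4, length, 0L) == 4))
})

test_that("hallucination detection respects truth, action and strict threshold", {
  truth <- c("silence", "sound", "silence", "sound", "silence")
  # confident correct beliefs: no false positives
  rec <- fake_record(truth, p_voice = c(0, 1, 0, 1, 0))
  expect_length(detect_hallucinations(rec), 0)
  # confident voice belief during silence flags only the silent steps
  rec <- fake_record(truth, p_voice = c(0.2, 1, 0.99, 1, 0.99))
  expect_identical(detect_hallucinations(rec, 0.75), c(3L, 5L))
  # boundary: belief exactly at threshold is excluded (strict inequality)
  rec <- fake_record(truth, p_voice = c(0, 1, 0.5, 1, 0))
  expect_length(detect_hallucinations(rec, 0.5), 0)
  # a step spoken into is never a hallucination even if belief is high
  rec <- fake_record(truth, p_voice = c(0, 1, 0.99, 1, 0),
                     incoming = c("listen", "speak", "listen", "listen"))
  expect_length(detect_hallucinations(rec, 0.75), 0)
  expect_error(detect_hallucinations(rec, 0.3), "threshold")
})

test_that("false-negative detection mirrors hallucinations with self-speech control", {
  truth <- c("silence", "sound", "sound", "sound", "silence")
  rec <- fake_record(truth, p_voice = c(0, 1, 0.01, 1, 0),
                     incoming = c("listen", "speak", "listen", "listen"))
  # step 3 was self-generated sound the agent stopped hearing
  expect_identical(detect_false_negatives(rec, 0.75), 3L)
  expect_length(detect_false_negatives(rec, 0.75,
                                       include_self_generated = FALSE), 0)
  # flat beliefs at a sound step are not flagged
  rec <- fake_record(truth, p_voice = c(0, 0.5, 0.5, 0.5, 0))
  expect_length(detect_false_negatives(rec, 0.5), 0)
})

test_that("a one-step trial degenerates to likelihood-weighted initial beliefs", {
  m <- generative_model(n_steps = 1, zeta = 0.7,
                        policy_catalog = list(policy("")))
  rec <- run_trial(m, environment_script("-"))
  expect_length(rec$executed_actions, 0)
  # flat D x symmetric likelihood row for "silence"
  A <- build_auditory_likelihood(0.7)
  expect_equal(unname(rec$marginal_auditory["no_voice", 1]),
               unname(A["silence", "no_voice"]), tolerance = 1e-6)
})

test_that("trial records have coherent shapes and flag sets", {
  rec <- run_trial(generative_model(zeta = 0.3))
  T_ <- rec$config$n_steps
  expect_length(rec$observations, T_)
  expect_length(rec$executed_actions, T_ - 1)
  expect_identical(dim(rec$marginal_auditory), c(2L, T_))
  expect_identical(dim(rec$policy_posterior),
                   c(T_, length(rec$config$policy_catalog)))
  expect_true(all(abs(colSums(rec$marginal_auditory) - 1) < 1e-8))
  expect_true(all(abs(rowSums(rec$policy_posterior) - 1) < 1e-8))
  truth <- vapply(rec$observations, `[[`, "", "auditory")
  expect_true(all(truth[rec$hallucination_steps] == "silence"))
})

test_that("hallucination burden grows as likelihood precision falls (lesioned space)", {
  counts <- vapply(c(0.7, 0.525, 0.3), function(z) {
    m <- generative_model(zeta = z,
                          policy_catalog = policy_fixture("F6_lesioned"))
    length(run_trial(m)$hallucination_steps)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 0L)
  expect_gt(counts[3], 0L)
})

test_that("experiment presets produce the expected grids and reject bad names", {
  ex <- run_experiment("fig4_zeta_sweep")
  expect_length(ex$records, 3)
  expect_identical(ex$summary$zeta, c(0.7, 0.525, 0.3))
  ex5 <- run_experiment("fig5_gamma")
  expect_identical(nrow(ex5$summary), 4L)
  expect_setequal(unique(ex5$summary$gamma_log), c(-4, 4))
  ex6 <- run_experiment("fig6_lesion", overrides = list(zeta = 0.7))
  expect_true(all(ex6$summary$zeta == 0.7))
  expect_error(run_experiment("fig9"), "fig4_zeta_sweep")
})
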