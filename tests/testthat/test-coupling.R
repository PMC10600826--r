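# compact end of the pipeline: cohort -> fit -> decode -> table
small_pipeline_table <- function(seed = 17) {
  cfg <- cohort_config(n_subjects = 12, n_networks = 1, n_voxels = 50,
                       task = task_config(n_trials = 60))
  coh <- generate_cohort(cfg, seed = seed)
  fit <- fit_hierarchical_em(coh$trials, model_spec(TRUE, TRUE), seed = 1)
  dec <- list(loso_decode(coh$sessions[[1]]))
  list(cohort = coh, fit = fit, decode = dec,
       table = assemble_trial_table(coh, fit, dec))
}

test_that("assemble_trial_table replays fitted values exactly", {
  pp <- small_pipeline_table()
  tab <- pp$table
  expect_equal(nrow(tab), 12 * 60)
  # V replay oracle: recompute one subject by hand from the fitted params
  est <- pp$fit$estimates
  sid <- est$subject[5]
  p <- agent_params(est$alpha_pos[5], est$alpha_neg[5], est$beta[5])
  tr <- pp$cohort$trials[pp$cohort$trials$subject == sid, ]
  V <- rep(0, 3); v_hand <- numeric(nrow(tr))
  for (t in seq_len(nrow(tr))) {
    v_hand[t] <- V[tr$arm[t] + 1]
    V <- rw_update(V, tr$arm[t], tr$outcome[t], p, pp$fit$spec)
  }
  expect_equal(tab$v_raw[tab$subject == sid], v_hand, tolerance = 1e-10)
  # standardization contract
  for (cn in c("V", "age", "iq", "motion", "internalizing")) {
    expect_lt(abs(mean(tab[[cn]])), 1e-8)
    expect_equal(sd(tab[[cn]]), 1, tolerance = 1e-8)
  }
  # a subject missing from the decode output is dropped with a message
  dec2 <- pp$decode
  dec2[[1]]$summary <- dec2[[1]]$summary[-3, ]
  dec2[[1]]$distances[[3]] <- NULL
  expect_message(tab2 <- assemble_trial_table(pp$cohort, pp$fit, dec2),
                 "excluded")
  expect_equal(length(unique(tab2$subject)), 11)
})

test_that("planted positive coupling is detected by the LMEM", {
  tab <- planted_table(n_subjects = 20, seed = 3, k0 = 1)
  fit <- fit_coupling_lmem(tab, 1)
  v <- fit$terms[fit$terms$term == "V", ]
  expect_gt(v$estimate, 0)
  expect_lt(v$p, 0.0063)
  expect_equal(fit$n_obs, 20 * 90)
  expect_error(fit_coupling_lmem(tab[tab$subject %in%
                                       unique(tab$subject)[1:5], ], 1),
               ">= 10 subjects")
})

test_that("coupling inference is equivariant under distance rescaling", {
  tab <- planted_table(n_subjects = 14, seed = 9, k0 = 0.5)
  tab2 <- tab
  tab2$distance <- tab2$distance * 3.7
  f1 <- fit_coupling_lmem(tab, 1)$terms
  f2 <- fit_coupling_lmem(tab2, 1)$terms
  v1 <- f1[f1$term == "V", ]; v2 <- f2[f2$term == "V", ]
  expect_equal(v2$estimate / v1$estimate, 3.7, tolerance = 1e-6)
  expect_equal(v1$stat, v2$stat, tolerance = 1e-6)
})

test_that("duplicating sites leaves the V estimate essentially unchanged", {
  tab <- planted_table(n_subjects = 16, seed = 12, k0 = 0.8)
  dup <- tab
  dup$site <- paste0(dup$site, "_copy")
  dup$subject <- paste0(dup$subject, "_copy")
  both <- rbind(tab, dup)
  v1 <- fit_coupling_lmem(tab, 1)$terms
  v2 <- fit_coupling_lmem(both, 1)$terms
  expect_equal(v2[v2$term == "V", "estimate"],
               v1[v1$term == "V", "estimate"], tolerance = 0.02)
})

test_that("moderation models include the planned terms and guards", {
  tab <- planted_table(n_subjects = 14, seed = 21, k0 = 1, k1 = -0.5)
  fit <- fit_moderation_lmem(tab, 1, "internalizing")
  expect_true("V:internalizing" %in% fit$terms$term)
  expect_match(fit$formula, "log_ctq") # clinical moderator keeps CTQ
  expect_match(fit$formula, "0 \\+ V \\| subject")
  fitb <- fit_moderation_lmem(tab, 1, "log_beta")
  expect_false(grepl("log_ctq", fitb$formula))
  tabc <- tab
  tabc$internalizing <- 0
  expect_error(fit_moderation_lmem(tabc, 1, "internalizing"),
               "inestimable")
  expect_error(fit_moderation_lmem(tab, 1, "nope"), "not found")
})

test_that("bonferroni_adjust reproduces the corrected alpha", {
  adj <- bonferroni_adjust(rep(0.5, 8), 8)
  expect_equal(adj$alpha_corrected, 0.00625)
  expect_equal(round(adj$alpha_corrected, 4), 0.0063)
  expect_false(any(adj$flags))
  expect_equal(bonferroni_adjust(0.03, 1)$alpha_corrected, 0.05)
  expect_true(bonferroni_adjust(c(0.001, 0.01), 8)$flags[1])
  expect_false(bonferroni_adjust(c(0.001, 0.01), 8)$flags[2])
  expect_error(bonferroni_adjust(0.5, 0), "m must be")
})
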