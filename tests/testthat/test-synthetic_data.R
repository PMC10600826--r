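test_that("covariates carry the planted latent structure", {
  cfg <- cohort_config()
  cov <- sample_covariates(cfg, seed = 1)
  expect_equal(nrow(cov), 60)
  expect_true(all(cov$ctq > 0))
  # balanced sites
  expect_lte(diff(range(table(cov$site))), 1)
  # internalizing is strongly rank-correlated with the latent factor
  expect_gt(cor(cov$internalizing, cov$S, method = "spearman"), 0.7)
  # log CTQ moderately correlated with S across seeds
  r <- vapply(1:100, function(s)
    with(sample_covariates(cfg, s), cor(log_ctq, S)), numeric(1))
  expect_gt(mean(r), 0.3)
  expect_lt(mean(r), 0.5)
  expect_gte(mean(r > 0.2 & r < 0.6), 0.85)
})

test_that("agent parameters follow the symptom-beta link", {
  cfg <- cohort_config()
  cov <- sample_covariates(cfg, seed = 2)
  # b1 < 0: negative sample correlation in nearly all seeds
  neg <- vapply(1:200, function(s) {
    agents <- sample_agent_params(cov, cfg, seed = s)
    cor(cov$S, log(sapply(agents, `[[`, "beta"))) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
  # b1 = 0: correlation centered on zero
  cfg0 <- cohort_config(b1 = 0)
  r0 <- vapply(1:100, function(s) {
    agents <- sample_agent_params(cov, cfg0, seed = s)
    cor(cov$S, log(sapply(agents, `[[`, "beta")))
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.05)
  # positivity by construction of the log link
  agents <- sample_agent_params(cov, cfg, seed = 3)
  expect_true(all(sapply(agents, `[[`, "beta") > 0))
  expect_true(all(sapply(agents, `[[`, "alpha_pos") > 0 &
                  sapply(agents, `[[`, "alpha_pos") < 1))
})

test_that("neural sessions embed the planted signal geometry", {
  set.seed(9)
  w <- rnorm(120); w <- w - mean(w); w <- w / sqrt(sum(w^2))
  tr <- data.frame(win = rep(c(TRUE, FALSE), 45))
  v <- runif(90, -1, 1)
  # noiseless limit: outcome rows separable by the sign of the projection
  s0 <- generate_neural_session(tr, v, w, kappa = 1, snr = 2,
                                noise_sd = 1e-9, seed = 4)
  proj <- as.numeric(s0$outcome %*% w)
  expect_true(all((proj > 0) == tr$win))
  # zero coupling: choice projections uncorrelated with V in expectation
  r0 <- vapply(1:30, function(s) {
    sn <- generate_neural_session(tr, v, w, kappa = 0, snr = 2, seed = s)
    cor(as.numeric(sn$choice %*% w), v)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.1)
  # default SNR: regression of choice projection on V recovers kappa
  sl <- vapply(1:50, function(s) {
    sn <- generate_neural_session(tr, v, w, kappa = 1.3, snr = 2, seed = s)
    unname(coef(lm(as.numeric(sn$choice %*% w) ~ v))[2])
  }, numeric(1))
  expect_lt(abs(mean(sl) - 1.3), 0.1)
  expect_error(generate_neural_session(tr, v[-1], w, 1), "length")
})

test_that("generate_cohort is reproducible and complete", {
  cfg <- cohort_config(n_subjects = 6, n_networks = 2, n_voxels = 30)
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$sessions[[2]][[3]]$choice, c2$sessions[[2]][[3]]$choice)
  expect_false(identical(c1$trials,
                         generate_cohort(cfg, seed = 6)$trials))
  # 90 rows per subject, every subject x network present
  expect_equal(unname(table(c1$trials$subject)), rep(90L, 6),
               ignore_attr = TRUE)
  expect_length(c1$sessions, 2)
  expect_length(c1$sessions[[1]], 6)
  expect_equal(dim(c1$sessions[[1]][[1]]$outcome), c(90, 30))
  # manifest records every seed stream
  expect_named(c1$manifest$stage_seeds,
               c("covariates", "agents", "patterns", "behavior", "neural"))
  expect_length(c1$manifest$behavior_seeds, 6)
  # behavior-only generation matches the full cohort's behavior
  cb <- generate_cohort(cfg, seed = 5, include_neural = FALSE)
  expect_identical(cb$trials, c1$trials)
  expect_null(cb$sessions)
})

test_that("striatum is the only network with symptom-linked coupling", {
  cfg <- cohort_config(n_subjects = 40, n_networks = 3,
                       striatum_network = 2)
  coh <- generate_cohort(cfg, seed = 8, include_neural = FALSE)
  zS <- as.numeric(scale(coh$covariates$S))
  r <- cor(coh$kappa, zS)
  expect_lt(r[2], -0.5)
  expect_lt(max(abs(r[c(1, 3)])), 0.45)
})

test_that("small cohorts export to long CSV", {
  cfg <- cohort_config(n_subjects = 3, n_networks = 1, n_voxels = 5,
                       task = task_config(n_trials = 6, block_length = 2))
  coh <- generate_cohort(cfg, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_sessions_csv(coh, 1, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 3 * 2 * 6 * 5)
  expect_setequal(unique(d$phase), c("outcome", "choice"))
})
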