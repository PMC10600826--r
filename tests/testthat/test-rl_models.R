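test_that("rw_update follows the factorial update rules", {
  p <- agent_params(0.5, 0.5, 1)
  expect_equal(rw_update(c(0, 0, 0), 0, 1, p, model_spec(FALSE, FALSE)),
               c(0.5, 0, 0))
  expect_equal(rw_update(c(0, 0, 0), 0, 1, p, model_spec(TRUE, FALSE)),
               c(0.5, -0.5, -0.5))
  # null learning freezes values under every variant
  p0 <- agent_params(0, 0, 1)
  for (s in all_model_specs())
    expect_equal(rw_update(c(0.3, -0.2, 0.1), 1, -1, p0, s),
                 c(0.3, -0.2, 0.1))
  # risk sensitivity gates the rate on the prediction-error sign
  pr <- agent_params(0.6, 0.1, 1)
  rsp <- model_spec(FALSE, TRUE)
  expect_equal(rw_update(c(0, 0, 0), 0, 1, pr, rsp), c(0.6, 0, 0))
  expect_equal(rw_update(c(0, 0, 0), 0, -1, pr, rsp), c(-0.1, 0, 0))
  expect_error(rw_update(c(NA, 0, 0), 0, 1, p, rsp), "non-finite")
})

test_that("softmax_probs is a stable normalized softmax", {
  expect_equal(softmax_probs(c(5, -2, 1), 0), rep(1 / 3, 3))
  expect_equal(softmax_probs(c(0.4, 0.4, 0.4), 7), rep(1 / 3, 3))
  # direct evaluation of the formula
  expect_equal(softmax_probs(c(1, 0, 0), 2),
               exp(2 * c(1, 0, 0)) / sum(exp(2 * c(1, 0, 0))))
  expect_equal(round(softmax_probs(c(1, 0, 0), 2), 3),
               c(0.787, 0.107, 0.107))
  expect_error(softmax_probs(c(1, 0), -1), "beta")
  # properties over random draws: sums to 1, shift-invariant, no overflow
  set.seed(3)
  for (i in 1:25) {
    V <- rnorm(3, sd = 10)
    b <- rexp(1, 1 / 5)
    pr <- softmax_probs(V, b)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_equal(pr, softmax_probs(V + 123.4, b), tolerance = 1e-12)
    expect_true(all(is.finite(softmax_probs(V * 100, b))))
  }
})

test_that("negloglik matches closed forms and the straight-line oracle", {
  tr <- simulate_agent(agent_params(0.3, 0.3, 3), model_spec(), seed = 2)
  expect_equal(negloglik(agent_params(0.5, 0.5, 0), model_spec(), tr),
               90 * log(3), tolerance = 1e-10)
  set.seed(10)
  for (i in 1:5) {
    spec <- all_model_specs()[[sample.int(4, 1)]]
    p <- agent_params(runif(1, .05, .95), runif(1, .05, .95), rexp(1, 0.3))
    sim <- simulate_agent(p, spec, seed = 100 + i)
    expect_equal(negloglik(p, spec, sim),
                 oracle_nll(sim$arm, sim$outcome, p$alpha_pos, p$alpha_neg,
                            p$beta, spec$counterfactual,
                            spec$risk_sensitive),
                 tolerance = 1e-10)
    # compiled and reference engines agree
    expect_equal(negloglik(p, spec, sim),
                 negloglik(p, spec, sim, engine = "r"), tolerance = 1e-12)
  }
  bad <- tr[c(2, 1, 3:90), ]
  expect_error(negloglik(agent_params(.3, .3, 1), model_spec(), bad),
               "time-ordered")
})

test_that("negloglik is bounded and locally continuous", {
  tr <- simulate_agent(agent_params(0.4, 0.2, 4), model_spec(TRUE, TRUE),
                       seed = 6)
  p <- agent_params(0.4, 0.2, 4)
  nll <- negloglik(p, model_spec(TRUE, TRUE), tr)
  expect_gte(nll, 0)
  # small parameter perturbations move the NLL by a small amount
  for (eps in c(1e-6, -1e-6)) {
    p2 <- agent_params(0.4 + eps, 0.2, 4 + eps)
    expect_lt(abs(negloglik(p2, model_spec(TRUE, TRUE), tr) - nll), 1e-3)
  }
})

test_that("replay_values reproduces the generating value sequence", {
  p <- agent_params(0.35, 0.15, 5)
  s <- model_spec(TRUE, TRUE)
  tr <- simulate_agent(p, s, seed = 21)
  rp <- replay_values(p, s, tr)
  expect_equal(rp$v_chosen, tr$v_chosen, tolerance = 1e-12)
  expect_equal(dim(rp$V), c(90, 3))
})

test_that("nested variants coincide when parameters are tied", {
  p <- agent_params(0.3, 0.3, 4)
  a <- simulate_agent(p, model_spec(TRUE, TRUE), seed = 8)
  b <- simulate_agent(p, model_spec(TRUE, FALSE), seed = 8)
  expect_identical(a, b)
})

test_that("exploitative agents prefer the rich arm", {
  # high beta: fraction of 0.8-arm choices exceeds 1/3 in nearly all runs
  hits <- vapply(1:200, function(seed) {
    tr <- simulate_agent(agent_params(0.3, 0.3, 10), model_spec(),
                         seed = seed)
    mean(tr$p_arm == 0.8) > 1 / 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
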