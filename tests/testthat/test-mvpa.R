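test_that("center_rows removes per-trial means and nothing else", {
  expect_equal(center_rows(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  m <- matrix(rnorm(1800), 9, 200)
  cm <- center_rows(m)
  expect_lt(max(abs(rowMeans(cm))), 1e-12)
  expect_equal(center_rows(cm), cm)
  expect_equal(dim(cm), dim(m))
  expect_error(center_rows(matrix(numeric(0), 0, 3)), "matrix")
  expect_error(center_rows(matrix(1, 3, 1)), "2 columns")
})

test_that("rbf_kernel matches the explicit distance formula", {
  set.seed(2)
  a <- matrix(rnorm(24), 8, 3)
  b <- matrix(rnorm(15), 5, 3)
  K <- rbf_kernel(a, b, gamma = 0.7)
  D <- as.matrix(dist(rbind(a, b)))[1:8, 9:13]
  expect_equal(K, exp(-0.7 * D^2), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(diag(rbf_kernel(a, gamma = 1)), rep(1, 8))
})

test_that("the SMO solver reproduces libsvm decision values", {
  # frozen oracle: scikit-learn SVC (libsvm), C = 1, gamma = 0.3, tol 1e-10,
  # on this exact dataset; decision values on the 5-point probe grid
  set.seed(42)
  X <- matrix(round(rnorm(60), 6), 20, 3)
  y <- rep(c(1, -1), 10)
  dec <- train_reward_decoder(X, y, cost = 1, gamma = 0.3, eps = 1e-6)
  probe <- matrix(round(seq(-1, 1, length.out = 15), 6), 5, 3, byrow = TRUE)
  oracle <- c(-0.59950657, -0.45838187, 0.07689589, 0.65133208, 0.88489974)
  expect_equal(predict(dec, probe), oracle, tolerance = 1e-3)
})

test_that("the decoder separates separable data and rejects one class", {
  set.seed(7)
  X <- rbind(matrix(rnorm(60, -2), 15), matrix(rnorm(60, 2), 15))
  y <- rep(c(-1, 1), each = 15)
  d <- train_reward_decoder(X, y)
  expect_equal(mean(sign(predict(d, X)) == y), 1)
  expect_error(train_reward_decoder(X, rep(1, 30)), "single outcome class")
})

test_that("LOSO decoding is near-perfect on clean planted data", {
  sessions <- tiny_sessions(n_subjects = 4, n_trials = 30, n_voxels = 40,
                            snr = 3, noise_sd = 1e-3, seed = 3)
  res <- loso_decode(sessions)
  expect_equal(res$summary$accuracy, rep(1, 4))
  expect_equal(res$summary$accuracy,
               (res$summary$sensitivity + res$summary$specificity) / 2)
  expect_length(res$distances[[1]], 30)
  expect_error(loso_decode(sessions[1:2]), ">= 3 subjects")
})

test_that("balanced accuracy always equals mean of sensitivity/specificity", {
  sessions <- tiny_sessions(n_subjects = 5, n_trials = 24, n_voxels = 30,
                            snr = 1, noise_sd = 1.5, seed = 11)
  res <- loso_decode(sessions)
  expect_equal(res$summary$accuracy,
               (res$summary$sensitivity + res$summary$specificity) / 2)
  expect_true(all(res$summary$sensitivity >= 0 &
                  res$summary$sensitivity <= 1))
  expect_true(all(res$summary$specificity >= 0 &
                  res$summary$specificity <= 1))
})

test_that("choice-phase data never leak into training", {
  s1 <- tiny_sessions(n_subjects = 4, n_trials = 20, n_voxels = 25, seed = 5)
  s2 <- s1
  s2[[1]]$choice <- s2[[1]]$choice * 100 + 3
  r1 <- loso_decode(s1)
  r2 <- loso_decode(s2)
  # training/evaluation untouched: summaries identical everywhere
  expect_identical(r1$summary, r2$summary)
  # other subjects' distances identical; only subject 1's change
  for (i in 2:4) expect_identical(r1$distances[[i]], r2$distances[[i]])
  expect_false(identical(r1$distances[[1]], r2$distances[[1]]))
})

test_that("distances are invariant to constant shifts of a trial row", {
  s1 <- tiny_sessions(n_subjects = 3, n_trials = 15, n_voxels = 20, seed = 6)
  s2 <- s1
  s2[[2]]$choice <- s2[[2]]$choice + 7.5 # same constant added to every voxel
  r1 <- loso_decode(s1)
  r2 <- loso_decode(s2)
  expect_equal(r1$distances[[2]], r2$distances[[2]], tolerance = 1e-10)
})

test_that("planted coupling shows up in the held-out distances", {
  sessions <- tiny_sessions(n_subjects = 6, n_trials = 60, n_voxels = 60,
                            snr = 2, kappa = 1.5, seed = 12)
  res <- loso_decode(sessions)
  # distances should track the planted pattern's activation at choice
  w <- attr(sessions, "w")
  for (i in seq_along(sessions)) {
    proj <- as.numeric(center_rows(sessions[[i]]$choice) %*% w)
    expect_gt(cor(res$distances[[i]], proj), 0.5)
  }
})

test_that("decoding_report summarizes networks with bootstrap CIs", {
  good <- tiny_sessions(n_subjects = 5, n_trials = 30, n_voxels = 40,
                        snr = 2.5, noise_sd = 0.5, seed = 13)
  null <- tiny_sessions(n_subjects = 5, n_trials = 30, n_voxels = 40,
                        snr = 1e-6, noise_sd = 1, seed = 14)
  rep_tab <- decoding_report(list(loso_decode(good), loso_decode(null)),
                             n_boot = 500, seed = 1)
  expect_equal(nrow(rep_tab), 2)
  expect_true(rep_tab$above_chance[1])
  expect_false(rep_tab$above_chance[2])
  expect_true(all(rep_tab$ci_lo <= rep_tab$accuracy &
                  rep_tab$accuracy <= rep_tab$ci_hi))
})
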