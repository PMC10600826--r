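#' Population prior over unconstrained parameters
#'
#' Diagonal Gaussian over the unconstrained parameter space of a model
#' variant (logit learning rates, log inverse temperature).
#'
#' @param mean,var numeric vectors of equal length; `var > 0`.
#' @return a `population_prior`.
#' @export
population_prior <- function(mean, var) {
  if (length(mean) != length(var) || any(var <= 0))
    stop("prior mean/var length mismatch or non-positive variance",
         call. = FALSE)
  structure(list(mean = as.numeric(mean), var = as.numeric(var)),
            class = "population_prior")
}

default_prior <- function(spec) {
  k <- n_params(spec)
  population_prior(rep(0, k), rep(6.25, k)) # sd 2.5 covers plausible range
}

# penalized objective: NLL + negative log Gaussian prior (constant
# dropped); closure over pre-extracted vectors so the optimizer hits the
# compiled hot path directly
map_objective_fn <- function(spec, trials, prior, n_arms) {
  chosen <- as.integer(trials$arm)
  r <- as.numeric(trials$outcome)
  function(theta)
    rw_map_obj_cpp(theta, chosen, r, as.integer(n_arms),
                   spec$counterfactual, spec$risk_sensitive,
                   prior$mean, prior$var)
}

# central-difference Hessian; h in unconstrained space
numeric_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < k) for (j in seq.int(i + 1, k)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# PD-safeguarded inverse: eigenvalues floored at 1e-6
safe_inverse <- function(H, floor = 1e-6) {
  e <- eigen(0.5 * (H + t(H)), symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% diag(1 / vals, length(vals)) %*% t(e$vectors)
}

#' MAP fit of one subject under a population prior
#'
#' Minimizes the penalized negative log likelihood in unconstrained space
#' with multi-start BFGS and returns the best restart, with a Laplace
#' (numeric-Hessian) curvature at the optimum.
#'
#' @param trials single-subject time-ordered trial table.
#' @param spec [model_spec()].
#' @param prior [population_prior()] over the unconstrained parameters.
#' @param restarts number of optimizer starts (drawn from the prior; the
#'   prior mean is always one of them).
#' @param seed integer seed for start-point draws.
#' @param n_arms number of arms.
#' @param start optional matrix of extra start points (rows).
#' @return a `subject_fit`: MAP estimate in both spaces, penalized and
#'   unpenalized NLL at the MAP, Hessian and Laplace covariance, AIC at the
#'   MAP-parameter NLL (see [fit_hierarchical_em()] for the near-ML AIC used
#'   in model comparison).
#' @export
fit_subject_map <- function(trials, spec, prior = default_prior(spec),
                            restarts = 10L, seed = 1L, n_arms = 3L,
                            start = NULL) {
  if (length(unique(trials$arm)) < 2)
    warning("subject made <2 distinct choices; fit may be degenerate")
  k <- n_params(spec)
  if (length(prior$mean) != k)
    stop("prior dimension does not match model spec", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng())
  starts <- rbind(prior$mean,
                  if (restarts > 1)
                    matrix(stats::rnorm((restarts - 1) * k, prior$mean,
                                        sqrt(prior$var)),
                           ncol = k, byrow = TRUE),
                  start)
  f <- map_objective_fn(spec, trials, prior, n_arms)
  best <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], f, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimizer restarts failed for subject ",
         trials$subject[1], call. = FALSE)
  theta <- best$par
  H <- numeric_hessian(f, theta)
  Sigma <- safe_inverse(H)
  params <- from_unconstrained(theta, spec)
  nll <- negloglik(params, spec, trials, n_arms)
  # Laplace approximation to the marginal likelihood of this subject's data
  # under the prior (used to monitor the EM objective)
  ev_vals <- pmax(eigen(0.5 * (H + t(H)), symmetric = TRUE,
                        only.values = TRUE)$values, 1e-6)
  log_evidence <- -best$value - 0.5 * sum(log(2 * pi * prior$var)) +
    0.5 * k * log(2 * pi) - 0.5 * sum(log(ev_vals))
  structure(list(subject = trials$subject[1], spec = spec,
                 log_evidence = log_evidence,
                 theta = stats::setNames(theta, param_names(spec)),
                 params = params, penalized = best$value, nll = nll,
                 hessian = H, laplace_cov = Sigma,
                 aic = 2 * k + 2 * nll, n_restart_failures = n_fail),
            class = "subject_fit")
}

#' Hierarchical empirical-Bayes EM fit of a cohort
#'
#' Approximates hierarchical Bayesian inference with Laplace-EM: the E step
#' computes each subject's MAP and Laplace covariance under the current
#' diagonal Gaussian population prior; the M step re-estimates the prior
#' mean and variance from the approximate posteriors. After convergence each
#' subject is refit under the converged prior with its variance inflated
#' x100 (effectively flat) to obtain a near-ML estimate, from which the AIC
#' is computed (AIC is defined for ML fits).
#'
#' @param trials cohort trial table (column `subject` distinguishes
#'   subjects; each subject time-ordered).
#' @param spec [model_spec()].
#' @param max_iter,tol EM stopping rule: stop when the largest absolute
#'   change in prior mean and prior standard deviation falls below `tol`.
#' @param seed integer seed (restart draws).
#' @param restarts optimizer restarts on the first EM iteration; later
#'   iterations warm-start from the previous MAP with 2 fresh draws.
#' @param n_arms number of arms.
#' @return a `cohort_fit`: converged prior, per-subject fits (`$fits`), a
#'   tidy `$estimates` data.frame (subject, alpha_pos, alpha_neg, beta,
#'   log_beta, nll, nll_ml, aic), summed AIC, and the EM trace.
#' @export
fit_hierarchical_em <- function(trials, spec, max_iter = 40L, tol = 5e-3,
                                seed = 1L, restarts = 5L, n_arms = 3L) {
  subjects <- unique(trials$subject)
  if (length(subjects) < 5)
    stop("hierarchical fit needs >= 5 subjects", call. = FALSE)
  k <- n_params(spec)
  by_subj <- split(trials, trials$subject)[as.character(subjects)]
  prior <- default_prior(spec)
  seeds <- derive_seeds(seed, paste0("em_subject_", subjects))
  trace <- list()
  fits <- vector("list", length(subjects))
  prev_theta <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # stochastic multi-start on the first pass only; later passes warm-start
    # deterministically (previous MAP + prior mean) so the EM iteration map
    # is a fixed function of the prior and can actually converge
    nr <- if (iter == 1L) restarts else 1L
    for (i in seq_along(subjects)) {
      fits[[i]] <- fit_subject_map(
        by_subj[[i]], spec, prior, restarts = nr,
        seed = seeds[i], n_arms = n_arms,
        start = if (!is.null(prev_theta)) prev_theta[i, , drop = FALSE])
    }
    theta <- do.call(rbind, lapply(fits, `[[`, "theta"))
    vcovs <- do.call(rbind, lapply(fits, function(f) diag(f$laplace_cov)))
    mu <- colMeans(theta)
    v <- pmax(colMeans(sweep(theta, 2, mu)^2) + colMeans(vcovs), 1e-4)
    change <- max(abs(mu - prior$mean), abs(sqrt(v) - sqrt(prior$var)))
    trace[[iter]] <- data.frame(
      iter = iter, change = change,
      evidence = sum(vapply(fits, `[[`, numeric(1), "log_evidence")),
      t(stats::setNames(mu, param_names(spec))))
    new_prior <- population_prior(mu, v)
    prev_theta <- theta
    prior <- new_prior
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations for ",
            spec_label(spec), "; returning last iterate")
  # near-ML refit with deflated (inflated-variance) prior for AIC
  flat <- population_prior(prior$mean, prior$var * 100)
  nll_ml <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    fml <- fit_subject_map(by_subj[[i]], spec, flat, restarts = 1L,
                           seed = seeds[i], n_arms = n_arms,
                           start = prev_theta[i, , drop = FALSE])
    nll_ml[i] <- fml$nll
    fits[[i]]$nll_ml <- fml$nll
    fits[[i]]$aic <- 2 * k + 2 * fml$nll
  }
  estimates <- data.frame(
    subject = subjects,
    alpha_pos = vapply(fits, function(f) f$params$alpha_pos, numeric(1)),
    alpha_neg = vapply(fits, function(f) f$params$alpha_neg, numeric(1)),
    beta = vapply(fits, function(f) f$params$beta, numeric(1)),
    log_beta = vapply(fits, function(f) log(f$params$beta), numeric(1)),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    nll_ml = nll_ml,
    aic = 2 * k + 2 * nll_ml,
    stringsAsFactors = FALSE)
  structure(list(spec = spec, prior = prior, fits = fits,
                 estimates = estimates, aic_sum = sum(estimates$aic),
                 converged = converged,
                 trace = do.call(rbind, trace)),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat("<cohort_fit>", spec_label(x$spec), "-", nrow(x$estimates),
      "subjects, summed AIC", round(x$aic_sum, 1),
      if (!x$converged) "(EM not converged)" else "", "\n")
  invisible(x)
}

#' Compare fitted model variants by summed AIC
#'
#' @param fits list of `cohort_fit`s for the same cohort (same subject set).
#' @return data.frame ranked by summed AIC (ties broken toward fewer
#'   parameters): `spec, k, aic_sum, delta_aic, winner`.
#' @export
compare_models <- function(fits) {
  subj_sets <- lapply(fits, function(f) sort(as.character(f$estimates$subject)))
  if (!all(vapply(subj_sets, identical, logical(1), subj_sets[[1]])))
    stop("model fits cover different subject sets", call. = FALSE)
  tab <- data.frame(
    spec = vapply(fits, function(f) spec_label(f$spec), character(1)),
    k = vapply(fits, function(f) n_params(f$spec), integer(1)),
    aic_sum = vapply(fits, `[[`, numeric(1), "aic_sum"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic_sum, tab$k), ]
  tab$delta_aic <- tab$aic_sum - tab$aic_sum[1]
  tab$winner <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}
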