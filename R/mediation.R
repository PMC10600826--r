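#' Subject-level coupling slopes
#'
#' Collapses trial-level coupling to one number per subject: the ordinary
#' least-squares slope of that subject's choice-phase hyperplane distances
#' on their (fitted-model) expected-value series. This is the mediator M in
#' the mediation model. Subjects whose V series has zero variance (e.g. a
#' frozen learner) get a missing slope and are logged.
#'
#' @param table output of [assemble_trial_table()] (or any long table with
#'   `subject`, `distance` and `v_raw` columns).
#' @param network 1-based network index to subset on (use the striatum
#'   network for the headline model).
#' @param min_trials minimum trials per subject.
#' @return data.frame `subject, slope, n_trials`.
#' @export
subject_coupling_slopes <- function(table, network = NULL,
                                    min_trials = 10L) {
  d <- if (!is.null(network))
    table[table$network == network, , drop = FALSE] else table
  out <- lapply(split(d, d$subject), function(s) {
    if (nrow(s) < min_trials)
      stop("subject ", s$subject[1], " has < ", min_trials, " trials",
           call. = FALSE)
    vv <- stats::var(s$v_raw)
    slope <- if (!is.finite(vv) || vv == 0) {
      message("subject ", s$subject[1],
              ": zero variance in V; slope recorded as NA")
      NA_real_
    } else stats::cov(s$distance, s$v_raw) / vv
    data.frame(subject = s$subject[1], slope = slope, n_trials = nrow(s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(unique(d$subject), res$subject), , drop = FALSE]
}

# least-squares coefficient of the first predictor column after intercept
ols_coef <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  fit$coefficients[2]
}

#' Percentile-bootstrap mediation
#'
#' Tests the indirect path X -> M -> Y with subject-level resampling.
#' Point estimates come from two least-squares fits: `M ~ X + covariates`
#' (path a) and `Y ~ X + M + covariates` (paths b and c'); the total effect
#' c is from `Y ~ X + covariates`, and c = c' + ab holds exactly for these
#' linear fits. Each bootstrap resample (subjects drawn with replacement)
#' refits a and b; the indirect effect ab gets a percentile CI and a
#' two-sided bootstrap p = 2 min(Pr(ab <= 0), Pr(ab >= 0)) (point mass at 0
#' counted on both sides; p capped at 1).
#'
#' @param X exposure (e.g. standardized internalizing).
#' @param M mediator (e.g. striatum coupling slope).
#' @param Y outcome (e.g. fitted log beta).
#' @param covariates optional numeric matrix / data.frame of adjustment
#'   variables (e.g. log CTQ).
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @param conf CI level.
#' @return a `mediation_result` with paths `a, b, c, c_prime, ab`,
#'   percentile `ci`, bootstrap `p`, `n`, `n_boot`, `seed`, and the number
#'   of redrawn degenerate resamples.
#' @export
mediation_bootstrap <- function(X, M, Y, covariates = NULL,
                                n_boot = 50000L, seed = 1L, conf = 0.95) {
  cc <- stats::complete.cases(X, M, Y,
                              if (!is.null(covariates)) covariates)
  X <- X[cc]; M <- M[cc]; Y <- Y[cc]
  Cov <- if (!is.null(covariates))
    as.matrix(as.data.frame(covariates))[cc, , drop = FALSE]
  n <- length(X)
  if (n < 20) stop("mediation needs >= 20 complete cases", call. = FALSE)
  Xa <- cbind(X, Cov)
  a <- ols_coef(M, Xa)
  bfit <- stats::lm.fit(cbind(1, M, X, Cov), Y)
  b <- bfit$coefficients[2]; c_prime <- bfit$coefficients[3]
  c_total <- ols_coef(Y, Xa)
  rng <- local_rng(seed)
  on.exit(rng())
  ab <- numeric(n_boot)
  redraws <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (stats::sd(X[idx]) > 0 && stats::sd(M[idx]) > 0) break
      redraws <- redraws + 1L
    }
    Xa_i <- cbind(X[idx], if (!is.null(Cov)) Cov[idx, , drop = FALSE])
    a_i <- ols_coef(M[idx], Xa_i)
    b_i <- stats::lm.fit(cbind(1, M[idx], Xa_i), Y[idx])$coefficients[2]
    ab[i] <- a_i * b_i
  }
  a2 <- (1 - conf) / 2
  ci <- stats::quantile(ab, c(a2, 1 - a2), names = FALSE)
  p <- min(1, 2 * min(mean(ab <= 0), mean(ab >= 0)))
  structure(list(a = unname(a), b = unname(b), c = unname(c_total),
                 c_prime = unname(c_prime), ab = unname(a * b),
                 ci = ci, conf = conf, p = p, n = n,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 boot_mean = mean(ab), boot_sd = stats::sd(ab),
                 degenerate_redraws = redraws),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>\n",
      sprintf("  a = %.4f, b = %.4f, c = %.4f, c' = %.4f\n",
              x$a, x$b, x$c, x$c_prime),
      sprintf("  indirect ab = %.4f, %d%% percentile CI [%.4f, %.4f]\n",
              x$ab, round(100 * x$conf), x$ci[1], x$ci[2]),
      sprintf("  bootstrap p = %.4g (%d iterations, seed %d, n = %d)\n",
              x$p, x$n_boot, x$seed, x$n))
  invisible(x)
}

#' One-page text report of a mediation model
#' @param x a `mediation_result`.
#' @param path output file.
#' @export
write_mediation_report <- function(x, path) {
  lines <- c(
    "Mediation model: X -> M -> Y (percentile bootstrap over subjects)",
    sprintf("n = %d complete cases; %d bootstrap iterations; seed %d",
            x$n, x$n_boot, x$seed),
    sprintf("path a  (X -> M)        : % .4f", x$a),
    sprintf("path b  (M -> Y | X)    : % .4f", x$b),
    sprintf("path c  (total X -> Y)  : % .4f", x$c),
    sprintf("path c' (direct X -> Y) : % .4f", x$c_prime),
    sprintf("indirect ab             : % .4f", x$ab),
    sprintf("%d%% percentile CI       : [% .4f, % .4f]",
            round(100 * x$conf), x$ci[1], x$ci[2]),
    sprintf("two-sided bootstrap p   : %.4g", x$p))
  writeLines(lines, path)
  invisible(path)
}
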