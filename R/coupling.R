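#' Assemble the trial-level coupling table
#'
#' Joins, per network, the choice-phase hyperplane distances with the
#' trial-level expected value of the chosen arm replayed from the *fitted*
#' model parameters (not the generating truth), plus subject covariates and
#' each subject's LOSO decoding accuracy. Continuous predictors (V, age,
#' IQ, motion, decoding accuracy, and any moderators) are standardized
#' cohort-wide; the distance outcome is left on its native scale.
#'
#' @param cohort a `bandit_cohort` (for trials and covariates).
#' @param fit a `cohort_fit` of the chosen model variant.
#' @param decode_results list of `decode_result`s, one per network.
#' @return long data.frame: `subject, site, network, trial, distance, V,
#'   v_raw, age, iq, motion, decode_acc, internalizing, depression,
#'   anxiety, somatic, log_ctq, log_beta` (predictors standardized; `*_raw`
#'   kept for reference).
#' @export
assemble_trial_table <- function(cohort, fit, decode_results) {
  cov <- cohort$covariates
  est <- fit$estimates
  miss <- setdiff(cov$subject, est$subject)
  if (length(miss))
    stop("subjects missing from model fit: ", paste(miss, collapse = ", "),
         call. = FALSE)
  by_subj <- split(cohort$trials, cohort$trials$subject)
  v_fit <- lapply(cov$subject, function(sid) {
    i <- match(sid, est$subject)
    p <- agent_params(est$alpha_pos[i], est$alpha_neg[i], est$beta[i])
    replay_values(p, fit$spec, by_subj[[sid]],
                  cohort$config$task$n_arms)$v_chosen
  })
  names(v_fit) <- cov$subject
  rows <- list()
  for (k in seq_along(decode_results)) {
    dr <- decode_results[[k]]
    for (sid in cov$subject) {
      if (!sid %in% dr$summary$subject || is.null(dr$distances[[sid]])) {
        message("subject ", sid, " has no decode output for network ", k,
                "; excluded")
        next
      }
      d <- dr$distances[[sid]]
      v <- v_fit[[sid]]
      if (length(d) != length(v))
        stop("distance/value length mismatch for subject ", sid,
             " network ", k, call. = FALSE)
      ci <- match(sid, cov$subject)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, site = cov$site[ci], network = k,
        trial = seq_along(d) - 1L, distance = d, v_raw = v,
        age = cov$age[ci], iq = cov$iq[ci], motion = cov$motion[ci],
        decode_acc = dr$summary$accuracy[match(sid, dr$summary$subject)],
        internalizing = cov$internalizing[ci],
        depression = cov$depression[ci], anxiety = cov$anxiety[ci],
        somatic = cov$somatic[ci], log_ctq = cov$log_ctq[ci],
        log_beta = est$log_beta[match(sid, est$subject)],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  z <- function(x) as.numeric(scale(x))
  tab$V <- z(tab$v_raw)
  for (col in c("age", "iq", "motion", "decode_acc", "internalizing",
                "depression", "anxiety", "somatic", "log_ctq", "log_beta"))
    tab[[col]] <- z(tab[[col]])
  tab
}

# shared fitting core for coupling/moderation LMEMs
fit_lmem <- function(data, formula_str, fallback_str) {
  fit <- tryCatch(
    lme4::lmer(stats::as.formula(formula_str), data = data, REML = TRUE),
    error = function(e) NULL, warning = function(w) NULL)
  simplified <- FALSE
  if (is.null(fit)) {
    fit <- lme4::lmer(stats::as.formula(fallback_str), data = data,
                      REML = TRUE)
    simplified <- TRUE
  }
  co <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], stat = co[, "t value"],
                      p = 2 * stats::pnorm(-abs(co[, "t value"])),
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fit = fit, terms = terms, varcor = vc, simplified = simplified)
}

#' Trial-level coupling model for one network
#'
#' Fits `distance ~ V + age + iq + motion + decode_acc` with random
#' intercepts for site and subject nested within site, by REML. Fixed
#' effects are tested with the large-sample normal approximation (the
#' models have thousands of trial-level observations). On convergence
#' failure the random structure is simplified to subject-only and flagged.
#'
#' @param table output of [assemble_trial_table()].
#' @param network 1-based network index.
#' @return a `coupling_fit`: `$terms` (term, estimate, se, stat, p),
#'   `$varcor`, `$n_obs`, `$network`, `$formula`, `$simplified`.
#' @export
fit_coupling_lmem <- function(table, network) {
  d <- table[table$network == network, , drop = FALSE]
  check_lmem_inputs(d)
  f <- "distance ~ V + age + iq + motion + decode_acc + (1 | site/subject)"
  fb <- "distance ~ V + age + iq + motion + decode_acc + (1 | subject)"
  res <- fit_lmem(d, f, fb)
  structure(list(network = network, terms = res$terms,
                 varcor = res$varcor, n_obs = nrow(d),
                 formula = if (res$simplified) fb else f,
                 simplified = res$simplified),
            class = "coupling_fit")
}

#' Moderation of coupling by a subject-level variable
#'
#' Same model as [fit_coupling_lmem()] plus the moderator main effect and
#' its interaction with V. When the moderator is a clinical symptom scale
#' (`internalizing`, `depression`, `anxiety`, `somatic`), log CTQ is
#' retained as a trauma-severity covariate.
#'
#' By default the moderation model adds an (uncorrelated) random V slope
#' per subject: a subject-level moderator of a trial-level slope must be
#' tested against between-subject slope variance, otherwise chance
#' correlation between true slope heterogeneity and the moderator is
#' evaluated at trial-level degrees of freedom and the test is badly
#' anti-conservative (see the methods vignette). Set `random_slope = FALSE`
#' for the intercepts-only variant.
#'
#' @param table output of [assemble_trial_table()].
#' @param network 1-based network index.
#' @param moderator column name of the (subject-level) moderator.
#' @param random_slope include a per-subject random slope for V.
#' @return a `coupling_fit` whose `$terms` include the `V:moderator`
#'   interaction.
#' @export
fit_moderation_lmem <- function(table, network, moderator,
                                random_slope = TRUE) {
  d <- table[table$network == network, , drop = FALSE]
  check_lmem_inputs(d)
  if (!moderator %in% names(d))
    stop("moderator column not found: ", moderator, call. = FALSE)
  if (stats::sd(d[[moderator]]) == 0 || !is.finite(stats::sd(d[[moderator]])))
    stop("moderator is constant; interaction is inestimable", call. = FALSE)
  clinical <- moderator %in% c("internalizing", "depression", "anxiety",
                               "somatic")
  covs <- paste(c("age", "iq", "motion", "decode_acc",
                  if (clinical) "log_ctq"), collapse = " + ")
  re <- if (random_slope) "(1 | site/subject) + (0 + V | subject)"
        else "(1 | site/subject)"
  re_fb <- if (random_slope) "(1 | subject) + (0 + V | subject)"
           else "(1 | subject)"
  f <- sprintf("distance ~ V * %s + %s + %s", moderator, covs, re)
  fb <- sprintf("distance ~ V * %s + %s + %s", moderator, covs, re_fb)
  res <- fit_lmem(d, f, fb)
  structure(list(network = network, moderator = moderator,
                 terms = res$terms, varcor = res$varcor, n_obs = nrow(d),
                 formula = if (res$simplified) fb else f,
                 simplified = res$simplified),
            class = "coupling_fit")
}

check_lmem_inputs <- function(d) {
  if (length(unique(d$subject)) < 10)
    stop("coupling models need >= 10 subjects", call. = FALSE)
  if (length(unique(d$site)) < 2)
    stop("coupling models need >= 2 sites", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat("<coupling_fit> network", x$network,
      if (!is.null(x$moderator)) paste0("(moderator ", x$moderator, ")"),
      "n_obs", x$n_obs, if (x$simplified) "[simplified RE]", "\n")
  print(x$terms, digits = 3)
  invisible(x)
}

#' Bonferroni correction across networks
#'
#' @param p vector of p-values (one per test in the family).
#' @param m family size (defaults to `length(p)`).
#' @param alpha family-wise alpha.
#' @return list with `alpha_corrected` (= `alpha / m`) and logical `flags`
#'   marking p-values below it.
#' @export
bonferroni_adjust <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  a <- alpha / m
  list(alpha_corrected = a, flags = !is.na(p) & p < a)
}

#' Extract one term across a list of coupling fits
#' @param fits list of `coupling_fit`s.
#' @param term term label (e.g. `"V"` or `"V:internalizing"`).
#' @return data.frame with one row per fit.
#' @export
coupling_term_table <- function(fits, term = "V") {
  do.call(rbind, lapply(fits, function(f) {
    r <- f$terms[f$terms$term == term, , drop = FALSE]
    if (nrow(r) == 0) stop("term not found: ", term, call. = FALSE)
    cbind(network = f$network, r)
  }))
}
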