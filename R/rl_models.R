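#' Rescorla-Wagner model variant
#'
#' The model family is a 2x2 factorial: counterfactual updating of unchosen
#' arms (A+) crossed with risk-sensitive asymmetric learning rates (RS+).
#' Under A+ every unchosen arm is updated toward the inverse of the received
#' outcome; under RS+ positive and negative prediction errors use separate
#' learning rates.
#'
#' @param counterfactual update unchosen arms toward the inverse outcome?
#' @param risk_sensitive separate learning rates by prediction-error sign?
#' @return a `model_spec`.
#' @export
model_spec <- function(counterfactual = FALSE, risk_sensitive = FALSE) {
  structure(list(counterfactual = isTRUE(counterfactual),
                 risk_sensitive = isTRUE(risk_sensitive)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", spec_label(x), "\n"); invisible(x)
}

#' All four model variants
#' @return named list of the four `model_spec`s (A-RS-, A+RS-, A-RS+, A+RS+).
#' @export
all_model_specs <- function() {
  specs <- list(model_spec(FALSE, FALSE), model_spec(TRUE, FALSE),
                model_spec(FALSE, TRUE), model_spec(TRUE, TRUE))
  names(specs) <- vapply(specs, spec_label, character(1))
  specs
}

#' @rdname model_spec
#' @param spec a `model_spec`.
#' @export
spec_label <- function(spec) {
  paste0(if (spec$counterfactual) "A+" else "A-",
         if (spec$risk_sensitive) "RS+" else "RS-")
}

#' Number of free parameters of a variant
#' @param spec a `model_spec`.
#' @return 2 for RS- (alpha, beta), 3 for RS+ (alpha+, alpha-, beta).
#' @export
n_params <- function(spec) if (spec$risk_sensitive) 3L else 2L

#' Agent parameters
#'
#' Learning rates live in (0,1) and the softmax inverse temperature is
#' non-negative. Under RS- only `alpha_pos` is used (pass `alpha_neg` equal
#' to it or leave default).
#'
#' @param alpha_pos learning rate for positive prediction errors.
#' @param alpha_neg learning rate for negative prediction errors.
#' @param beta softmax inverse temperature (>= 0).
#' @return an `agent_params`.
#' @export
agent_params <- function(alpha_pos, alpha_neg = alpha_pos, beta) {
  if (!is.finite(alpha_pos) || alpha_pos < 0 || alpha_pos > 1 ||
      !is.finite(alpha_neg) || alpha_neg < 0 || alpha_neg > 1)
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("beta must be finite and >= 0", call. = FALSE)
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta),
            class = "agent_params")
}

#' One Rescorla-Wagner update
#'
#' delta = r - V\[chosen\]; the effective learning rate is `alpha_pos` for
#' delta > 0 and `alpha_neg` for delta < 0 under RS+ (always `alpha_pos`
#' under RS-); delta = 0 leaves the value untouched under either rate. Under
#' A+ each unchosen arm u moves toward the inverse outcome with its own
#' prediction error delta_u = (-r) - V\[u\] and the same sign-gated rate
#' rule.
#'
#' This pure-R step is the canonical definition; the compiled likelihood in
#' [negloglik()] must agree with it (tested).
#'
#' @param V numeric value vector, one entry per arm.
#' @param chosen 0-based index of the chosen arm.
#' @param r coded outcome.
#' @param params [agent_params()].
#' @param spec [model_spec()].
#' @return updated value vector.
#' @export
rw_update <- function(V, chosen, r, params, spec) {
  if (!all(is.finite(V)) || !is.finite(r))
    stop("non-finite values in rw_update", call. = FALSE)
  a <- chosen + 1L
  delta <- r - V[a]
  if (delta != 0) {
    ae <- if (spec$risk_sensitive && delta < 0) params$alpha_neg else params$alpha_pos
    V[a] <- V[a] + ae * delta
  }
  if (spec$counterfactual) {
    for (u in seq_along(V)[-a]) {
      du <- (-r) - V[u]
      if (du == 0) next
      au <- if (spec$risk_sensitive && du < 0) params$alpha_neg else params$alpha_pos
      V[u] <- V[u] + au * du
    }
  }
  V
}

#' Softmax choice probabilities
#'
#' p_i = exp(beta V_i) / sum_j exp(beta V_j), computed with max subtraction
#' for numerical stability. beta = 0 gives the uniform policy.
#'
#' @param V value vector.
#' @param beta inverse temperature (>= 0).
#' @return probability vector summing to 1.
#' @export
softmax_probs <- function(V, beta) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  z <- beta * V
  e <- exp(z - max(z))
  e / sum(e)
}

#' Negative log likelihood of a choice sequence
#'
#' Runs values forward from V = 0 over a single subject's time-ordered
#' trials, accumulating -log softmax probability of each observed choice
#' before applying the update for that trial's outcome.
#'
#' @param params [agent_params()].
#' @param spec [model_spec()].
#' @param trials single-subject trial table with 0-based `trial`, `arm` and
#'   coded `outcome` columns, time-ordered.
#' @param n_arms number of arms.
#' @param engine `"cpp"` (fast path used in fitting) or `"r"` (reference
#'   path built on [rw_update()]/[softmax_probs()]).
#' @return finite non-negative scalar.
#' @export
negloglik <- function(params, spec, trials, n_arms = 3L,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(unique(trials$subject)) > 1)
    stop("negloglik expects trials from a single subject", call. = FALSE)
  if (is.unsorted(trials$trial, strictly = TRUE))
    stop("trials must be strictly time-ordered", call. = FALSE)
  if (engine == "cpp")
    return(rw_nll_cpp(as.integer(trials$arm), as.numeric(trials$outcome),
                      as.integer(n_arms), params$alpha_pos, params$alpha_neg,
                      params$beta, spec$counterfactual, spec$risk_sensitive))
  V <- rep(0, n_arms)
  nll <- 0
  for (t in seq_len(nrow(trials))) {
    p <- softmax_probs(V, params$beta)
    nll <- nll - log(p[trials$arm[t] + 1L])
    V <- rw_update(V, trials$arm[t], trials$outcome[t], params, spec)
  }
  nll
}

#' Replay fitted values over an observed sequence
#'
#' Returns the pre-update expected value of every arm at each trial (row t
#' holds the expectations in force when choice t was made), plus the value
#' of the chosen arm — the trial-level `V` regressor used by the coupling
#' models.
#'
#' @inheritParams negloglik
#' @return list with `V` (trials x arms matrix) and `v_chosen` (vector).
#' @export
replay_values <- function(params, spec, trials, n_arms = 3L) {
  if (is.unsorted(trials$trial, strictly = TRUE))
    stop("trials must be strictly time-ordered", call. = FALSE)
  V <- rw_values_cpp(as.integer(trials$arm), as.numeric(trials$outcome),
                     as.integer(n_arms), params$alpha_pos, params$alpha_neg,
                     spec$counterfactual, spec$risk_sensitive)
  list(V = V, v_chosen = V[cbind(seq_len(nrow(V)), trials$arm + 1L)])
}

#' Simulate one agent on the task
#'
#' Generative counterpart of [negloglik()]; delegates to [run_session()] so
#' that simulation and likelihood share the single [rw_update()] rule.
#'
#' @inheritParams run_session
#' @export
simulate_agent <- function(params, spec, config = task_config(), seed = 1L,
                           subject = "s01", schedule = NULL) {
  run_session(params, spec, config, seed, subject, schedule)
}

# --- parameter transforms between constrained and unconstrained space -----
# alpha ~ logistic(theta); beta = exp(theta). RS- ties alpha_neg to
# alpha_pos and drops its coordinate.
to_unconstrained <- function(params, spec) {
  qlogis_ <- function(p) log(p / (1 - p))
  if (spec$risk_sensitive)
    c(qlogis_(params$alpha_pos), qlogis_(params$alpha_neg), log(params$beta))
  else c(qlogis_(params$alpha_pos), log(params$beta))
}

from_unconstrained <- function(theta, spec) {
  plogis_ <- function(x) 1 / (1 + exp(-x))
  if (spec$risk_sensitive)
    agent_params(plogis_(theta[1]), plogis_(theta[2]), exp(theta[3]))
  else agent_params(plogis_(theta[1]), plogis_(theta[1]), exp(theta[2]))
}

param_names <- function(spec) {
  if (spec$risk_sensitive) c("logit_alpha_pos", "logit_alpha_neg", "log_beta")
  else c("logit_alpha", "log_beta")
}
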