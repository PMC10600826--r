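#' Center each row of a trial x voxel matrix
#'
#' Removes each trial's mean activation so the decoder cannot exploit
#' overall activation differences across trials.
#'
#' @param x numeric matrix with >= 2 columns.
#' @return matrix of the same shape with zero row means.
#' @export
center_rows <- function(x) {
  if (!is.matrix(x) || nrow(x) == 0 || ncol(x) < 2)
    stop("center_rows needs a matrix with >= 1 row and >= 2 columns",
         call. = FALSE)
  x - rowMeans(x)
}

#' Radial-basis-function kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||x_i - y_j||^2)` computed via BLAS-backed cross
#' products.
#'
#' @param x,y numeric matrices with matching column counts (`y` defaults to
#'   `x`).
#' @param gamma kernel width parameter.
#' @return `nrow(x) x nrow(y)` kernel matrix.
#' @export
rbf_kernel <- function(x, y = x, gamma) {
  rbf_finish_cpp(tcrossprod(x, y), rowSums(x^2), rowSums(y^2), gamma)
}

# default kernel width: reciprocal of (feature count x pooled feature
# variance), the conventional "scale" heuristic
default_gamma <- function(x) 1 / (ncol(x) * mean(apply(x, 2, stats::var)))

#' Train the reward decoder
#'
#' Soft-margin support vector classifier with a Gaussian kernel, trained on
#' stacked row-centered outcome-phase trials. Labels are +1 (win) / -1
#' (loss), so positive decision values are on the reward side by
#' construction.
#'
#' @param x training matrix (rows are already row-centered trials).
#' @param y logical or +/-1 labels (TRUE/+1 = win).
#' @param cost soft-margin cost parameter.
#' @param gamma kernel width; default is the scale heuristic of the
#'   training set.
#' @param eps SMO stopping tolerance.
#' @return a `reward_decoder` with support-vector coefficients, offset and
#'   kernel parameters.
#' @export
train_reward_decoder <- function(x, y, cost = 1, gamma = NULL, eps = 1e-3) {
  y <- if (is.logical(y)) ifelse(y, 1, -1) else as.numeric(y)
  if (length(unique(y)) < 2)
    stop("training data contain a single outcome class", call. = FALSE)
  if (is.null(gamma)) gamma <- default_gamma(x)
  K <- rbf_kernel(x, gamma = gamma)
  fit <- smo_train_cpp(K, seq_len(nrow(x)) - 1L, y, cost, eps,
                       max_iter = 200L * nrow(x))
  sv <- which(fit$coef != 0)
  structure(list(sv_x = x[sv, , drop = FALSE], coef = fit$coef[sv],
                 rho = fit$rho, gamma = gamma, cost = cost,
                 iterations = fit$iterations, converged = fit$converged),
            class = "reward_decoder")
}

#' Decision values (hyperplane distances) of the decoder
#'
#' @param object a `reward_decoder`.
#' @param newdata matrix of row-centered trials.
#' @param ... unused.
#' @return signed decision values; positive = reward side.
#' @export
predict.reward_decoder <- function(object, newdata, ...) {
  k <- rbf_kernel(newdata, object$sv_x, object$gamma)
  as.numeric(k %*% object$coef - object$rho)
}

# sensitivity/specificity of sign(decision) against logical win labels;
# single-class subjects yield NA for the undefined rate
sens_spec <- function(decision, win) {
  pred_win <- decision > 0
  sens <- if (any(win)) mean(pred_win[win]) else NA_real_
  spec <- if (any(!win)) mean(!pred_win[!win]) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Leave-one-subject-out reward decoding for one network
#'
#' For each held-out subject an RBF-SVM is trained on all other subjects'
#' row-centered outcome-phase trials, evaluated on the held-out subject's
#' outcome trials (sensitivity, specificity, balanced accuracy = their
#' mean), and then applied to the held-out subject's row-centered
#' choice-phase trials to yield signed hyperplane distances — the degree to
#' which the trained reward pattern is active at choice time.
#'
#' The full cross-subject kernel matrix is computed once and shared across
#' folds; the kernel width is the scale heuristic of the pooled outcome
#' data (a fixed hyperparameter, not tuned per fold).
#'
#' @param sessions named list of `neural_session`s (one per subject) for a
#'   single network.
#' @param cost soft-margin cost.
#' @param gamma kernel width override.
#' @param eps SMO tolerance.
#' @return a `decode_result`: `$summary` data.frame (subject, sensitivity,
#'   specificity, accuracy) and `$distances` named list of per-trial
#'   choice-phase distances.
#' @export
loso_decode <- function(sessions, cost = 1, gamma = NULL, eps = 1e-3) {
  ns <- length(sessions)
  if (ns < 3) stop("LOSO decoding needs >= 3 subjects", call. = FALSE)
  subjects <- names(sessions)
  if (is.null(subjects)) subjects <- sprintf("s%03d", seq_len(ns))
  out_list <- lapply(sessions, function(s) center_rows(s$outcome))
  n_rows <- vapply(out_list, nrow, integer(1))
  X <- do.call(rbind, out_list)
  y <- unlist(lapply(sessions, function(s) ifelse(s$win, 1, -1)),
              use.names = FALSE)
  subj_of_row <- rep(seq_len(ns), n_rows)
  if (is.null(gamma)) gamma <- default_gamma(X)
  K <- rbf_kernel(X, gamma = gamma)
  summary <- data.frame(subject = subjects, sensitivity = NA_real_,
                        specificity = NA_real_, accuracy = NA_real_,
                        stringsAsFactors = FALSE)
  distances <- vector("list", ns); names(distances) <- subjects
  for (i in seq_len(ns)) {
    train <- which(subj_of_row != i)
    test <- which(subj_of_row == i)
    ytr <- y[train]
    if (length(unique(ytr)) < 2)
      stop("training fold contains a single outcome class", call. = FALSE)
    fit <- smo_train_cpp(K, train - 1L, ytr, cost, eps,
                         max_iter = 200L * length(train))
    keep <- fit$coef != 0
    dec_out <- svm_decision_precomp_cpp(K, test - 1L, train[keep] - 1L,
                                        fit$coef[keep], fit$rho)
    ss <- sens_spec(dec_out, sessions[[i]]$win)
    summary$sensitivity[i] <- ss[["sensitivity"]]
    summary$specificity[i] <- ss[["specificity"]]
    summary$accuracy[i] <- mean(ss) # NA if either rate is undefined
    if (anyNA(ss))
      message("subject ", subjects[i],
              ": single outcome class; balanced accuracy recorded as NA")
    ch <- center_rows(sessions[[i]]$choice)
    kc <- rbf_kernel(ch, X[train[keep], , drop = FALSE], gamma)
    distances[[i]] <- as.numeric(kc %*% fit$coef[keep] - fit$rho)
  }
  structure(list(summary = summary, distances = distances, gamma = gamma,
                 cost = cost), class = "decode_result")
}

#' Decoding summary across networks
#'
#' Mean balanced accuracy per network with a subject-level bootstrap CI and
#' an above-chance flag (CI lower bound > 0.5).
#'
#' @param results list of `decode_result`s, one per network.
#' @param n_boot bootstrap resamples over subjects.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per network: `network, n_subjects,
#'   accuracy, ci_lo, ci_hi, above_chance`.
#' @export
decoding_report <- function(results, n_boot = 2000L, conf = 0.95,
                            seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  a2 <- (1 - conf) / 2
  rows <- lapply(seq_along(results), function(k) {
    acc <- results[[k]]$summary$accuracy
    acc <- acc[is.finite(acc)]
    boot <- replicate(n_boot,
                      mean(acc[sample.int(length(acc), replace = TRUE)]))
    ci <- stats::quantile(boot, c(a2, 1 - a2), names = FALSE)
    data.frame(network = k, n_subjects = length(acc), accuracy = mean(acc),
               ci_lo = ci[1], ci_hi = ci[2], above_chance = ci[1] > 0.5)
  })
  do.call(rbind, rows)
}
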