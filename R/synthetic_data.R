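#' Synthetic cohort configuration
#'
#' The generator plants exactly the structure the downstream analysis
#' assumes: a latent internalizing factor S drives the CBCL scales and
#' (negatively) the softmax inverse temperature; each of `n_networks`
#' carries a common unit-norm reward pattern direction w; outcome-phase
#' rows carry a decodable +/- reward signal of amplitude `snr`; choice-phase
#' rows reactivate the pattern in proportion to the generating agent's
#' expected value of the chosen arm, with subject coupling strength
#' kappa_i = k0 + k1 z(S_i) + eta in the designated striatum network
#' (k1 < 0) and kappa_i = k0 + eta elsewhere.
#'
#' Defaults describe a mid-sized two-site adolescent cohort: 60 subjects,
#' 8 networks of 200 voxels, strongly decodable outcome patterns (snr 2,
#' noise sd 1), moderate coupling (k0 = 1), internalizing-coupling slope
#' k1 = -0.4 in the striatum only, and log beta = b0 + b1 z(S) + eps with
#' b0 = 1.5, b1 = -0.5, eps sd 0.3. Behavior is generated from the A+RS+
#' variant with mean learning rates 0.5 (positive) and 0.1 (negative); the
#' strong positive/negative asymmetry is what makes the generating variant
#' identifiable against its 2-parameter nested alternative at 90 trials
#' per subject (see the methods vignette).
#'
#' @param n_subjects,n_sites,n_networks,n_voxels cohort dimensions.
#' @param striatum_network 1-based index of the network with planted
#'   internalizing-dependent coupling.
#' @param snr outcome-pattern amplitude along w (noise has unit sd).
#' @param k0,k1,kappa_sd coupling intercept, internalizing slope (striatum
#'   network only) and subject-level residual sd.
#' @param b0,b1,beta_sd mean log inverse temperature, internalizing slope,
#'   residual sd.
#' @param mu_logit_alpha_pos,mu_logit_alpha_neg,alpha_sd learning-rate
#'   population (logit scale).
#' @param gen_spec generating [model_spec()].
#' @param motion_noise_slope multiplicative effect of standardized head
#'   motion on a subject's voxel noise sd (`exp(slope * z(motion))`).
#' @param task [task_config()].
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60L, n_sites = 2L, n_networks = 8L,
                          n_voxels = 200L, striatum_network = 1L,
                          snr = 2, k0 = 1, k1 = -0.4, kappa_sd = 0.25,
                          b0 = 1.5, b1 = -0.5, beta_sd = 0.3,
                          mu_logit_alpha_pos = stats::qlogis(0.5),
                          mu_logit_alpha_neg = stats::qlogis(0.1),
                          alpha_sd = 0.4,
                          gen_spec = model_spec(TRUE, TRUE),
                          motion_noise_slope = 0.1,
                          task = task_config()) {
  if (striatum_network > n_networks)
    stop("striatum_network must be <= n_networks", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sites = as.integer(n_sites),
                 n_networks = as.integer(n_networks),
                 n_voxels = as.integer(n_voxels),
                 striatum_network = as.integer(striatum_network),
                 snr = snr, k0 = k0, k1 = k1, kappa_sd = kappa_sd,
                 b0 = b0, b1 = b1, beta_sd = beta_sd,
                 mu_logit_alpha_pos = mu_logit_alpha_pos,
                 mu_logit_alpha_neg = mu_logit_alpha_neg,
                 alpha_sd = alpha_sd, gen_spec = gen_spec,
                 motion_noise_slope = motion_noise_slope, task = task),
            class = "cohort_config")
}

#' Sample subject covariates
#'
#' A latent internalizing score S ~ N(0,1) is the shared factor behind the
#' CBCL internalizing total and its depression/anxiety/somatic subscales
#' (loadings 0.9 and 0.7). Log CTQ correlates moderately with S (r = 0.4)
#' but has no direct path to the neural coupling, mirroring the null for
#' trauma severity. Sites are assigned in balanced round-robin; age, IQ and
#' head motion are nuisance covariates with no planted effect.
#'
#' @param config [cohort_config()].
#' @param seed integer seed.
#' @return data.frame, one row per subject: `subject, site, age, iq,
#'   motion, ctq, log_ctq, internalizing, depression, anxiety, somatic, S`.
#' @export
sample_covariates <- function(config = cohort_config(), seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  n <- config$n_subjects
  S <- stats::rnorm(n)
  load1 <- 0.9; load2 <- 0.7
  mk <- function(l) l * S + sqrt(1 - l^2) * stats::rnorm(n)
  z_log_ctq <- 0.4 * S + sqrt(1 - 0.16) * stats::rnorm(n)
  log_ctq <- 3.3 + 0.3 * z_log_ctq
  data.frame(
    subject = sprintf("s%03d", seq_len(n)),
    site = sprintf("site%d", (seq_len(n) - 1L) %% config$n_sites + 1L),
    age = round(stats::runif(n, 11, 17), 1),
    iq = round(stats::rnorm(n, 100, 15)),
    motion = exp(stats::rnorm(n, log(0.15), 0.4)),
    ctq = exp(log_ctq), log_ctq = log_ctq,
    internalizing = 50 + 10 * mk(load1),
    depression = 50 + 10 * mk(load2),
    anxiety = 50 + 10 * mk(load2),
    somatic = 50 + 10 * mk(load2),
    S = S, stringsAsFactors = FALSE)
}

#' Sample agent parameters tied to internalizing
#'
#' log beta_i = b0 + b1 z(S_i) + eps (eps sd `beta_sd`), so higher
#' internalizing means lower inverse temperature (more random exploration)
#' when b1 < 0. Learning rates are Gaussian in logit space, independent of
#' S.
#'
#' @param covariates output of [sample_covariates()].
#' @param config [cohort_config()].
#' @param seed integer seed.
#' @return list of [agent_params()], one per subject, with the latent
#'   kappa-free truth recorded in attributes `log_beta`.
#' @export
sample_agent_params <- function(covariates, config = cohort_config(),
                                seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  n <- nrow(covariates)
  zS <- as.numeric(scale(covariates$S))
  log_beta <- config$b0 + config$b1 * zS + stats::rnorm(n, 0, config$beta_sd)
  la_pos <- stats::rnorm(n, config$mu_logit_alpha_pos, config$alpha_sd)
  la_neg <- stats::rnorm(n, config$mu_logit_alpha_neg, config$alpha_sd)
  lapply(seq_len(n), function(i)
    agent_params(stats::plogis(la_pos[i]), stats::plogis(la_neg[i]),
                 exp(log_beta[i])))
}

#' Generate one subject x network neural session
#'
#' Outcome-phase rows: `snr * z_r * w + noise`, z_r = +1 win / -1 loss.
#' Choice-phase rows: `kappa * v_chosen(t) * w + noise`. Noise is iid
#' Gaussian with per-subject sd `exp(motion_noise_slope * z_motion)`. The
#' pattern direction `w` is unit norm and mean-centered, so row-centering
#' does not remove the signal.
#'
#' @param trials the subject's trial table (needs `win`).
#' @param v_chosen the generating agent's pre-choice expected value of the
#'   chosen arm, one per trial.
#' @param w unit-norm pattern direction (length `n_voxels`).
#' @param kappa subject coupling strength for this network.
#' @param snr outcome signal amplitude.
#' @param noise_sd voxel noise standard deviation.
#' @param seed integer seed.
#' @return a `neural_session`: list with `outcome`, `choice` (trial x voxel
#'   matrices), `win` labels, and the planted `kappa`.
#' @export
generate_neural_session <- function(trials, v_chosen, w, kappa, snr = 2,
                                    noise_sd = 1, seed = 1L) {
  n <- nrow(trials)
  if (length(v_chosen) != n)
    stop("v_chosen length does not match trial count", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng())
  p <- length(w)
  z_r <- ifelse(trials$win, 1, -1)
  outcome <- tcrossprod(snr * z_r, w) +
    matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  choice <- tcrossprod(kappa * v_chosen, w) +
    matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  structure(list(outcome = outcome, choice = choice, win = trials$win,
                 kappa = kappa), class = "neural_session")
}

# centered unit-norm pattern direction (orthogonal to the constant vector,
# so per-trial mean-centering preserves the signal)
make_pattern_direction <- function(p) {
  w <- stats::rnorm(p)
  w <- w - mean(w)
  w / sqrt(sum(w^2))
}

#' Generate a full synthetic cohort
#'
#' One call produces everything the pipeline consumes: covariates, agent
#' parameters, behavioral trial tables (simulated from the generating model
#' variant), and per-network neural sessions with planted decodable reward
#' patterns and value-proportional choice reactivation. All sub-seeds are
#' derived from `seed` and recorded in `$manifest`.
#'
#' @param config [cohort_config()].
#' @param seed master integer seed.
#' @param include_neural generate the neural sessions? Set `FALSE` for
#'   behavior-only cohorts (e.g. model-recovery studies); covariates,
#'   agents, trials and planted couplings are identical either way because
#'   all seed streams are drawn up front.
#' @return a `bandit_cohort`: `covariates`, `agents` (list), `trials`
#'   (long data.frame), `sessions` (`sessions[[network]][[subject]]`),
#'   `networks` (list with pattern direction `w` and planted `kappa` per
#'   subject), `kappa` (subject x network matrix), `manifest`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            include_neural = TRUE) {
  n <- config$n_subjects
  seeds <- derive_seeds(seed, c("covariates", "agents", "patterns",
                                "behavior", "neural"))
  covariates <- sample_covariates(config, seeds[["covariates"]])
  agents <- sample_agent_params(covariates, config, seeds[["agents"]])

  rng <- local_rng(seeds[["patterns"]])
  W <- replicate(config$n_networks, make_pattern_direction(config$n_voxels),
                 simplify = FALSE)
  zS <- as.numeric(scale(covariates$S))
  kappa <- sapply(seq_len(config$n_networks), function(k) {
    slope <- if (k == config$striatum_network) config$k1 else 0
    config$k0 + slope * zS + stats::rnorm(n, 0, config$kappa_sd)
  })
  rng()

  behavior_seeds <- derive_seeds(seeds[["behavior"]], covariates$subject)
  trials_list <- lapply(seq_len(n), function(i)
    run_session(agents[[i]], config$gen_spec, config$task,
                seed = behavior_seeds[i], subject = covariates$subject[i]))
  trials <- do.call(rbind, trials_list)

  z_motion <- as.numeric(scale(log(covariates$motion)))
  noise_sd <- exp(config$motion_noise_slope * z_motion)
  neural_seeds <- matrix(derive_seeds(seeds[["neural"]],
                                      paste0(rep(covariates$subject,
                                                 config$n_networks),
                                             "_net",
                                             rep(seq_len(config$n_networks),
                                                 each = n))),
                         nrow = n)
  sessions <- if (!include_neural) NULL else
    lapply(seq_len(config$n_networks), function(k)
    stats::setNames(lapply(seq_len(n), function(i)
      generate_neural_session(trials_list[[i]], trials_list[[i]]$v_chosen,
                              W[[k]], kappa[i, k], config$snr, noise_sd[i],
                              seed = neural_seeds[i, k])),
      covariates$subject))
  structure(list(
    config = config, covariates = covariates, agents = agents,
    trials = trials, sessions = sessions,
    networks = lapply(seq_len(config$n_networks), function(k)
      list(id = k, w = W[[k]], striatum = k == config$striatum_network)),
    kappa = kappa,
    manifest = list(master_seed = as.integer(seed),
                    stage_seeds = as.list(seeds),
                    behavior_seeds = as.list(behavior_seeds),
                    n_subjects = n, n_networks = config$n_networks,
                    gen_spec = spec_label(config$gen_spec))),
    class = "bandit_cohort")
}

#' @export
print.bandit_cohort <- function(x, ...) {
  cat("<bandit_cohort>", x$config$n_subjects, "subjects,",
      x$config$n_networks, "networks x", x$config$n_voxels, "voxels,",
      nrow(x$trials), "trial rows\n")
  invisible(x)
}

#' Export a small cohort's neural data as long-format CSV
#'
#' Convenience writer for inspection and text-only fixtures; intended for
#' small cohorts only (the long format is trials x voxels per phase).
#' @param cohort a `bandit_cohort`.
#' @param network 1-based network index.
#' @param path output CSV path.
#' @export
write_sessions_csv <- function(cohort, network, path) {
  sess <- cohort$sessions[[network]]
  rows <- lapply(names(sess), function(sid) {
    s <- sess[[sid]]
    do.call(rbind, lapply(c("outcome", "choice"), function(phase) {
      m <- s[[phase]]
      data.frame(subject = sid, network = network, phase = phase,
                 trial = rep(seq_len(nrow(m)) - 1L, ncol(m)),
                 voxel = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
                 value = as.vector(m), stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
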