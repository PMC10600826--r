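# Independent straight-line oracle for the RW/softmax likelihood: literal
# transcription of the model equations, sharing no code with the package
# implementation. Deliberately naive.
oracle_nll <- function(arm, outcome, alpha_pos, alpha_neg, beta,
                       counterfactual, risk_sensitive, n_arms = 3) {
  V <- c(0, 0, 0)[seq_len(n_arms)]
  total <- 0
  for (t in seq_along(arm)) {
    a <- arm[t] + 1
    num <- exp(beta * V[a])
    den <- 0
    for (j in 1:n_arms) den <- den + exp(beta * V[j])
    total <- total - log(num / den)
    r <- outcome[t]
    delta <- r - V[a]
    if (risk_sensitive) {
      if (delta > 0) V[a] <- V[a] + alpha_pos * delta
      if (delta < 0) V[a] <- V[a] + alpha_neg * delta
    } else {
      V[a] <- V[a] + alpha_pos * delta
    }
    if (counterfactual) {
      for (u in 1:n_arms) {
        if (u == a) next
        du <- (-r) - V[u]
        if (risk_sensitive) {
          if (du > 0) V[u] <- V[u] + alpha_pos * du
          if (du < 0) V[u] <- V[u] + alpha_neg * du
        } else {
          V[u] <- V[u] + alpha_pos * du
        }
      }
    }
  }
  total
}

# hand-built schedule with arbitrary (possibly degenerate) probabilities,
# bypassing task_config validation, for boundary-case tests
manual_schedule <- function(prob_rows, block_length = nrow(prob_rows)) {
  config <- task_config()
  config$n_trials <- nrow(prob_rows)
  config$block_length <- as.integer(block_length)
  structure(list(probs = prob_rows,
                 block = rep(seq_len(nrow(prob_rows) / block_length) - 1L,
                             each = block_length),
                 perms = matrix(1:3, 1), config = config, seed = 0L),
            class = "schedule")
}

# small neural cohort for decoding tests: n subjects sharing one pattern
# direction; kappa constant unless given
tiny_sessions <- function(n_subjects = 6, n_trials = 40, n_voxels = 60,
                          snr = 2, noise_sd = 1, kappa = 1, seed = 1) {
  set.seed(seed)
  w <- rnorm(n_voxels); w <- w - mean(w); w <- w / sqrt(sum(w^2))
  kappa <- rep(kappa, length.out = n_subjects)
  sessions <- lapply(seq_len(n_subjects), function(i) {
    win <- runif(n_trials) < 0.5
    if (all(win)) win[1] <- FALSE
    if (!any(win)) win[1] <- TRUE
    v <- runif(n_trials, -1, 1)
    tr <- data.frame(win = win)
    generate_neural_session(tr, v, w, kappa[i], snr = snr,
                            noise_sd = noise_sd,
                            seed = 1000 + i)
  })
  names(sessions) <- sprintf("s%03d", seq_len(n_subjects))
  attr(sessions, "w") <- w
  sessions
}

# long-format planted coupling table (bypasses the decoder): distances are
# kappa_i * V + unit noise, which is exactly the linear model the LMEMs
# test; used for power/calibration studies where running the SVM per
# replicate would be pointless
planted_table <- function(n_subjects = 20, seed = 1, k0 = 1, k1 = 0,
                          kappa_sd = 0.25, n_networks = 1,
                          striatum = 1, n_trials = 90) {
  cfg <- cohort_config(n_subjects = n_subjects,
                       task = task_config(n_trials = n_trials))
  coh <- generate_cohort(cfg, seed = seed, include_neural = FALSE)
  cov <- coh$covariates
  set.seed(seed + 77)
  zS <- as.numeric(scale(cov$S))
  tabs <- lapply(seq_len(n_networks), function(k) {
    slope <- if (k == striatum) k1 else 0
    kap <- k0 + slope * zS + rnorm(n_subjects, 0, kappa_sd)
    do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      tr <- coh$trials[coh$trials$subject == cov$subject[i], ]
      data.frame(subject = cov$subject[i], site = cov$site[i], network = k,
                 trial = tr$trial,
                 distance = kap[i] * tr$v_chosen + rnorm(nrow(tr)),
                 v_raw = tr$v_chosen, age = cov$age[i], iq = cov$iq[i],
                 motion = cov$motion[i], decode_acc = rnorm(1, 0.95, 0.01),
                 internalizing = cov$internalizing[i],
                 depression = cov$depression[i], anxiety = cov$anxiety[i],
                 somatic = cov$somatic[i], log_ctq = cov$log_ctq[i],
                 log_beta = log(coh$agents[[i]]$beta),
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, tabs)
  tab$V <- as.numeric(scale(tab$v_raw))
  for (cn in c("age", "iq", "motion", "decode_acc", "internalizing",
               "depression", "anxiety", "somatic", "log_ctq", "log_beta"))
    tab[[cn]] <- as.numeric(scale(tab[[cn]]))
  tab
}
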