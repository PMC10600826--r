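#' Three-arm bandit task configuration
#'
#' Describes the social reward bandit: three arms paying a fixed stake with
#' arm-specific reward probabilities \{0.8, 0.5, 0.2\} that are re-assigned
#' to arms every 30 trials over a 90-trial session. A win nets +$10 and a
#' loss nets -$10; for learning, outcomes are coded symmetrically as
#' `outcome_coding` (default +1 win / -1 loss) so that initial values of 0
#' are a neutral prior.
#'
#' @param n_arms number of arms.
#' @param n_trials trials per session; must be divisible by `block_length`.
#' @param block_length trials per probability block.
#' @param prob_set reward probabilities, one per arm, each in (0, 1).
#' @param win_payoff,loss_payoff net monetary payoffs (bookkeeping only).
#' @param outcome_coding length-2 numeric `c(win, loss)` used as the reward
#'   signal `r` in the learning rule.
#' @return a `task_config` list.
#' @export
task_config <- function(n_arms = 3L, n_trials = 90L, block_length = 30L,
                        prob_set = c(0.8, 0.5, 0.2),
                        win_payoff = 10, loss_payoff = -10,
                        outcome_coding = c(win = 1, loss = -1)) {
  n_arms <- as.integer(n_arms)
  n_trials <- as.integer(n_trials)
  block_length <- as.integer(block_length)
  if (n_trials %% block_length != 0L)
    stop("n_trials (", n_trials, ") must be divisible by block_length (",
         block_length, ")", call. = FALSE)
  if (length(prob_set) != n_arms)
    stop("prob_set must have exactly n_arms entries", call. = FALSE)
  if (any(prob_set <= 0 | prob_set >= 1))
    stop("reward probabilities must lie in (0, 1)", call. = FALSE)
  if (length(outcome_coding) != 2L)
    stop("outcome_coding must be c(win, loss)", call. = FALSE)
  structure(list(n_arms = n_arms, n_trials = n_trials,
                 block_length = block_length, prob_set = prob_set,
                 win_payoff = win_payoff, loss_payoff = loss_payoff,
                 outcome_coding = c(win = outcome_coding[[1]],
                                    loss = outcome_coding[[2]])),
            class = "task_config")
}

#' Draw a block-permuted reward schedule
#'
#' Each block of `block_length` trials assigns the probability set to arms as
#' a uniformly drawn permutation, constrained to differ from the previous
#' block's assignment so that every block transition is a detectable change.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return a `schedule` object: `probs` is an `n_trials x n_arms` matrix of
#'   per-trial reward probabilities, `block` the 0-based block index per
#'   trial, `perms` the per-block permutations (rows index blocks).
#' @export
make_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  n_blocks <- config$n_trials %/% config$block_length
  perms <- matrix(NA_integer_, n_blocks, config$n_arms)
  prev <- NULL
  rng <- local_rng(seed)
  for (b in seq_len(n_blocks)) {
    repeat {
      p <- sample.int(config$n_arms)
      if (is.null(prev) || any(p != prev)) break
    }
    perms[b, ] <- p
    prev <- p
  }
  rng()
  block <- rep(seq_len(n_blocks) - 1L, each = config$block_length)
  probs <- config$prob_set[t(perms[block + 1L, , drop = FALSE])]
  probs <- matrix(probs, ncol = config$n_arms, byrow = TRUE)
  structure(list(probs = probs, block = block, perms = perms,
                 config = config, seed = as.integer(seed)),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat("<schedule>", nrow(x$probs), "trials,",
      nrow(x$perms), "blocks of", x$config$block_length, "\n")
  invisible(x)
}

#' Sample one bandit outcome
#'
#' Bernoulli draw at the scheduled probability of `arm` on `trial`, mapped
#' through the task's outcome coding.
#'
#' @param schedule a [make_schedule()] result.
#' @param trial 0-based trial index.
#' @param arm 0-based arm index.
#' @return the coded outcome (+1 win / -1 loss by default), with attribute
#'   `win`.
#' @export
sample_outcome <- function(schedule, trial, arm) {
  stopifnot(inherits(schedule, "schedule"))
  n <- nrow(schedule$probs)
  if (trial < 0 || trial >= n) stop("trial index out of range", call. = FALSE)
  if (arm < 0 || arm >= ncol(schedule$probs))
    stop("arm index out of range", call. = FALSE)
  p <- schedule$probs[trial + 1L, arm + 1L]
  win <- stats::runif(1) < p
  coding <- schedule$config$outcome_coding
  structure(if (win) coding[["win"]] else coding[["loss"]], win = win)
}

#' Run one agent-environment session
#'
#' Plays an RW agent through a full schedule: on each trial the agent's
#' softmax policy over its current values selects an arm, the environment
#' returns a coded outcome, and the agent's values are updated in place via
#' [rw_update()]. The generating model's own pre-choice expectation of the
#' chosen arm is recorded per trial (used later to plant neural coupling).
#'
#' @param params an [agent_params()].
#' @param spec a [model_spec()].
#' @param config a [task_config()].
#' @param seed integer seed controlling schedule, choices and outcomes.
#' @param subject subject identifier stored in the output.
#' @param schedule optional pre-built schedule (its config wins).
#' @return data.frame with one row per trial: `subject, trial, block, arm,
#'   outcome, win, p_arm, v_chosen` (0-based `trial` and `arm`).
#' @export
run_session <- function(params, spec, config = task_config(), seed = 1L,
                        subject = "s01", schedule = NULL) {
  stopifnot(inherits(params, "agent_params"), inherits(spec, "model_spec"))
  rng <- local_rng(seed)
  on.exit(rng())
  if (is.null(schedule)) {
    schedule <- make_schedule(config, seed = sample.int(.Machine$integer.max, 1))
  } else config <- schedule$config
  n <- config$n_trials
  V <- rep(0, config$n_arms)
  arm <- integer(n); outcome <- numeric(n); win <- logical(n)
  p_arm <- numeric(n); v_chosen <- numeric(n)
  coding <- config$outcome_coding
  for (t in seq_len(n)) {
    pr <- softmax_probs(V, params$beta)
    a <- sample.int(config$n_arms, 1L, prob = pr)
    p <- schedule$probs[t, a]
    w <- stats::runif(1) < p
    r <- if (w) coding[["win"]] else coding[["loss"]]
    arm[t] <- a - 1L; outcome[t] <- r; win[t] <- w
    p_arm[t] <- p; v_chosen[t] <- V[a]
    V <- rw_update(V, a - 1L, r, params, spec)
  }
  data.frame(subject = subject, trial = seq_len(n) - 1L,
             block = schedule$block, arm = arm, outcome = outcome,
             win = win, p_arm = p_arm, v_chosen = v_chosen,
             stringsAsFactors = FALSE)
}

#' Write / read trial tables
#'
#' Plain-CSV round trip for the long trial table produced by [run_session()]
#' or [generate_cohort()].
#' @param trials trial table (data.frame).
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Scoped RNG: seeds the global stream, returns a restorer. Keeps every
# stochastic entry point deterministic-by-seed without clobbering the
# caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

# Derive a named sub-seed stream from a master seed; stable small integers.
derive_seeds <- function(master, names) {
  rng <- local_rng(master)
  on.exit(rng())
  s <- sample.int(2147483646L, length(names))
  names(s) <- names
  s
}
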