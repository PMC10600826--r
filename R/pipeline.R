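#' Pipeline run configuration
#'
#' Bundles the cohort configuration with analysis settings and stage
#' toggles. Serializes losslessly to JSON via [save_run_config()] /
#' [load_run_config()]; every stochastic stage derives its seed from the
#' master seed by a named stream.
#'
#' @param cohort a [cohort_config()].
#' @param seed master integer seed.
#' @param fit_specs model variants to fit (list of [model_spec()]).
#' @param moderators moderator columns for the moderation stage.
#' @param n_boot mediation bootstrap iterations.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "fit", "decode", "couple", "mediate", "report")`.
#' @param svm_cost,alpha SVM cost parameter; family-wise alpha.
#' @return a `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), seed = 1L,
                       fit_specs = all_model_specs(),
                       moderators = c("log_beta", "internalizing"),
                       n_boot = 50000L,
                       stages = c("simulate", "fit", "decode", "couple",
                                  "mediate", "report"),
                       svm_cost = 1, alpha = 0.05) {
  structure(list(cohort = cohort, seed = as.integer(seed),
                 fit_specs = fit_specs, moderators = moderators,
                 n_boot = as.integer(n_boot), stages = stages,
                 svm_cost = svm_cost, alpha = alpha),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  x <- config
  x$cohort$task <- unclass(x$cohort$task)
  x$cohort$gen_spec <- unclass(x$cohort$gen_spec)
  x$cohort <- unclass(x$cohort)
  x$fit_specs <- lapply(x$fit_specs, unclass)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  task <- do.call(task_config, c(
    x$cohort$task[c("n_arms", "n_trials", "block_length", "prob_set",
                    "win_payoff", "loss_payoff")],
    list(outcome_coding = unlist(x$cohort$task$outcome_coding))))
  gen_spec <- model_spec(x$cohort$gen_spec$counterfactual,
                         x$cohort$gen_spec$risk_sensitive)
  ch <- x$cohort
  ch$task <- NULL; ch$gen_spec <- NULL
  cohort <- do.call(cohort_config,
                    c(ch, list(task = task, gen_spec = gen_spec)))
  fit_specs <- lapply(x$fit_specs, function(s)
    model_spec(s$counterfactual, s$risk_sensitive))
  names(fit_specs) <- vapply(fit_specs, spec_label, character(1))
  run_config(cohort = cohort, seed = x$seed, fit_specs = fit_specs,
             moderators = x$moderators, n_boot = x$n_boot,
             stages = x$stages, svm_cost = x$svm_cost, alpha = x$alpha)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' simulate -> fit -> decode -> couple -> mediate -> report, writing each
#' stage's tabular outputs (CSV) and structured outputs (JSON) under
#' `outdir`, plus a manifest with the config snapshot, stage seeds and
#' MD5 checksums of every output file. Re-running with the same config and
#' seed reproduces the checksums. Stages not listed in `config$stages` are
#' skipped (downstream stages requiring them will be skipped too).
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the run directory path; side effect: files.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  seeds <- derive_seeds(config$seed,
                        c("simulate", "fit", "decode", "mediate"))
  save_run_config(config, file.path(outdir, "config.json"))
  t0 <- Sys.time()
  cohort <- NULL; fits <- NULL; best <- NULL; decodes <- NULL; table <- NULL

  if ("simulate" %in% stages) {
    log_stage("simulate", "generating cohort of",
              config$cohort$n_subjects, "subjects")
    cohort <- generate_cohort(config$cohort, seeds[["simulate"]])
    write_trials(cohort$trials, file.path(outdir, "trials.csv"))
    utils::write.csv(cohort$covariates,
                     file.path(outdir, "covariates.csv"), row.names = FALSE)
    jsonlite::write_json(cohort$manifest,
                         file.path(outdir, "simulate_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("fit" %in% stages && !is.null(cohort)) {
    fits <- list()
    for (nm in names(config$fit_specs)) {
      log_stage("fit", nm)
      fits[[nm]] <- fit_hierarchical_em(cohort$trials,
                                        config$fit_specs[[nm]],
                                        seed = seeds[["fit"]])
    }
    comparison <- compare_models(fits)
    utils::write.csv(comparison, file.path(outdir, "model_comparison.csv"),
                     row.names = FALSE)
    best <- fits[[comparison$spec[1]]]
    est <- best$estimates
    est$spec <- spec_label(best$spec)
    utils::write.csv(est, file.path(outdir, "subject_fits.csv"),
                     row.names = FALSE)
  }

  if ("decode" %in% stages && !is.null(cohort)) {
    decodes <- vector("list", config$cohort$n_networks)
    for (k in seq_len(config$cohort$n_networks)) {
      log_stage("decode", "network", k)
      decodes[[k]] <- loso_decode(cohort$sessions[[k]],
                                  cost = config$svm_cost)
    }
    summ <- do.call(rbind, lapply(seq_along(decodes), function(k)
      cbind(network = k, decodes[[k]]$summary)))
    utils::write.csv(summ, file.path(outdir, "decoding_subjects.csv"),
                     row.names = FALSE)
    rep_tab <- decoding_report(decodes, seed = seeds[["decode"]])
    utils::write.csv(rep_tab, file.path(outdir, "decoding_networks.csv"),
                     row.names = FALSE)
    dist_long <- do.call(rbind, lapply(seq_along(decodes), function(k) {
      dl <- decodes[[k]]$distances
      do.call(rbind, lapply(names(dl), function(sid)
        data.frame(subject = sid, network = k,
                   trial = seq_along(dl[[sid]]) - 1L,
                   distance = dl[[sid]], stringsAsFactors = FALSE)))
    }))
    utils::write.csv(dist_long, file.path(outdir, "distances.csv"),
                     row.names = FALSE)
  }

  if ("couple" %in% stages && !is.null(best) && !is.null(decodes)) {
    log_stage("couple", "assembling trial table")
    table <- assemble_trial_table(cohort, best, decodes)
    nets <- seq_len(config$cohort$n_networks)
    coup <- lapply(nets, function(k) fit_coupling_lmem(table, k))
    vt <- coupling_term_table(coup, "V")
    adj <- bonferroni_adjust(vt$p, config$cohort$n_networks, config$alpha)
    vt$flagged <- adj$flags
    utils::write.csv(vt, file.path(outdir, "coupling.csv"),
                     row.names = FALSE)
    mod_rows <- list()
    for (m in config$moderators) {
      log_stage("couple", "moderator", m)
      mods <- lapply(nets, function(k) fit_moderation_lmem(table, k, m))
      it <- coupling_term_table(mods, paste0("V:", m))
      it$moderator <- m
      it$flagged <- bonferroni_adjust(it$p, config$cohort$n_networks,
                                      config$alpha)$flags
      mod_rows[[m]] <- it
    }
    utils::write.csv(do.call(rbind, mod_rows),
                     file.path(outdir, "moderation.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(formula = coup[[1]]$formula,
           alpha_corrected = adj$alpha_corrected,
           n_networks = config$cohort$n_networks),
      file.path(outdir, "coupling_run.json"), auto_unbox = TRUE,
      digits = NA)
  }

  if ("mediate" %in% stages && !is.null(table)) {
    log_stage("mediate", config$n_boot, "bootstrap iterations")
    slopes <- subject_coupling_slopes(table,
                                      config$cohort$striatum_network)
    cov <- cohort$covariates
    est <- best$estimates
    i <- match(slopes$subject, cov$subject)
    med <- mediation_bootstrap(
      X = as.numeric(scale(cov$internalizing[i])),
      M = slopes$slope,
      Y = est$log_beta[match(slopes$subject, est$subject)],
      covariates = data.frame(log_ctq = cov$log_ctq[i]),
      n_boot = config$n_boot, seed = seeds[["mediate"]])
    utils::write.csv(slopes, file.path(outdir, "coupling_slopes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(med), file.path(outdir, "mediation.json"),
                         auto_unbox = TRUE, digits = NA)
    write_mediation_report(med, file.path(outdir, "mediation_report.txt"))
  }

  files <- setdiff(list.files(outdir), c("manifest.json", "report.txt"))
  manifest <- list(
    created = format(t0), seed = config$seed,
    stage_seeds = as.list(seeds), stages = stages,
    checksums = as.list(tools::md5sum(file.path(outdir, sort(files)))))
  names(manifest$checksums) <- sort(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if ("report" %in% stages) write_report(outdir)
  log_stage("done", "outputs in", outdir)
  invisible(outdir)
}

#' Write a plain-text analysis report for a completed run
#'
#' Tabular analogues of the headline figures: summed AIC per model variant,
#' per-network decoding accuracy, per-network coupling and moderation
#' coefficients with Bonferroni flags, and the mediation paths with CI.
#' Missing stages are marked, not fatal.
#'
#' @param outdir a [run_pipeline()] output directory.
#' @return invisibly, the report path.
#' @export
write_report <- function(outdir) {
  out <- c("== bandit MVPA pipeline report ==", "")
  grab <- function(f) file.path(outdir, f)
  section <- function(title, file, fmt) {
    if (file.exists(grab(file))) c(title, fmt(utils::read.csv(grab(file))), "")
    else c(title, "  [stage missing]", "")
  }
  fmt_tab <- function(d) paste0("  ", utils::capture.output(print(
    d, digits = 4, row.names = FALSE)))
  out <- c(out,
    section("Model comparison (summed AIC):", "model_comparison.csv",
            fmt_tab),
    section("Decoding accuracy per network:", "decoding_networks.csv",
            fmt_tab))
  if (file.exists(grab("coupling_run.json"))) {
    meta <- jsonlite::read_json(grab("coupling_run.json"),
                                simplifyVector = TRUE)
    out <- c(out, sprintf(
      "Coupling (V term), Bonferroni-corrected alpha = %.4f over %d networks:",
      meta$alpha_corrected, meta$n_networks))
    out <- c(out, fmt_tab(utils::read.csv(grab("coupling.csv"))), "")
  } else out <- c(out, "Coupling:", "  [stage missing]", "")
  out <- c(out,
    section("Moderation interactions:", "moderation.csv", fmt_tab))
  if (file.exists(grab("mediation_report.txt"))) {
    out <- c(out, "Mediation:",
             paste0("  ", readLines(grab("mediation_report.txt"))), "")
  } else out <- c(out, "Mediation:", "  [stage missing]", "")
  path <- file.path(outdir, "report.txt")
  writeLines(out, path)
  invisible(path)
}
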