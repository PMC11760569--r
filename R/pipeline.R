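# End-to-end pipeline: preprocess -> fit -> classify -> group -> phenotype
# -> validate, with reproducible artifacts.

#' Pipeline configuration
#'
#' Collects every stage setting in one validated object. Either
#' `colony_table` (a CSV/XLSX path) or `colony` (an in-memory long-format
#' data frame, e.g. from [simulate_colony()]) must be supplied to
#' [run_pipeline()].
#'
#' @param output_dir Directory for artifacts (created if needed).
#' @param colony_table Optional path to the colony table.
#' @param biomarker_table,composition_table Optional paths to post-hoc CSV
#'   tables (columns as produced by [simulate_posthoc_measures()]).
#' @param preprocess A [preprocess_config()].
#' @param n_states Hidden states to fit (default 10).
#' @param n_iters EM iterations per restart (default 1500).
#' @param n_restarts Random EM restarts (default 10).
#' @param seed Master seed for every stochastic stage.
#' @param em_tol EM early-stopping tolerance (relative; 0 disables).
#' @param ending_threshold Ending-state diagonal threshold (default 0.3).
#' @param decode `"posterior"` or `"viterbi"` terminal-state decoding.
#' @param min_n Minimum mice per curve age bin (default 3).
#' @param bin_width Curve age bin width in months (default 1).
#' @param ref_age Percent-change reference age in months (default 12).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            colony_table = NULL,
                            biomarker_table = NULL,
                            composition_table = NULL,
                            preprocess = preprocess_config(),
                            n_states = 10, n_iters = 1500, n_restarts = 10,
                            seed = 1, em_tol = 1e-8,
                            ending_threshold = 0.3,
                            decode = c("posterior", "viterbi"),
                            min_n = 3, bin_width = 1, ref_age = 12) {
  decode <- match.arg(decode)
  if (n_states < 1) stopf("n_states must be >= 1")
  if (n_iters < 1) stopf("n_iters must be >= 1")
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  if (ending_threshold < 0 || ending_threshold >= 1) {
    stopf("ending_threshold must be in [0, 1)")
  }
  if (min_n < 1 || bin_width <= 0 || ref_age < 0) {
    stopf("curve settings out of range (min_n >= 1, bin_width > 0, ref_age >= 0)")
  }
  structure(
    list(output_dir = output_dir, colony_table = colony_table,
         biomarker_table = biomarker_table,
         composition_table = composition_table,
         preprocess = preprocess,
         n_states = as.integer(n_states), n_iters = as.integer(n_iters),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         em_tol = em_tol, ending_threshold = ending_threshold,
         decode = decode, min_n = as.integer(min_n),
         bin_width = bin_width, ref_age = ref_age),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()];
#' `preprocess` may be a nested mapping of [preprocess_config()]
#' arguments.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$preprocess)) y$preprocess <- do.call(preprocess_config, y$preprocess)
  dots <- list(...)
  y[names(dots)] <- dots
  do.call(pipeline_config, y)
}

# Fingerprint the scientific settings only: the artifact location does not
# change what a run computes.
config_fingerprint <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  fnv1a_hash(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE))
}

#' Run the full trajectory-analysis pipeline
#'
#' Stages, in order: load/preprocess the colony table; fit the
#' autoregressive HMM with random restarts; classify ending states from
#' the fitted transition matrix; decode terminal states and group mice
#' into trajectories; compute group curves and percent weight change from
#' the reference age; validate with survival analysis (Kaplan-Meier +
#' log-rank across groups), composition chi-square tests, and - when
#' biomarker/composition tables are supplied - Welch t tests and the
#' adipose index. Every artifact is stamped with the configuration
#' fingerprint and master seed; identical configuration and input
#' reproduce identical artifacts.
#'
#' @param config A `pipeline_config`.
#' @param colony Optional in-memory colony data frame (used when
#'   `config$colony_table` is `NULL`).
#' @return Invisibly, a list of class `pipeline_result`: the fitted model,
#'   classification, grouping, curves, percent changes, validation
#'   results, cohort summary, and `artifacts` (named vector of file
#'   paths).
#' @export
run_pipeline <- function(config, colony = NULL) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a 'pipeline_config'")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_fingerprint(config), seed = config$seed)
  log_path <- file.path(config$output_dir, "run_log.txt")
  log_lines <- character(0)
  logmsg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", "stage", sprintf(fmt, ...))
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  fail <- function(stage, e) {
    writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", stage,
                                    conditionMessage(e))), log_path)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }

  # stage: preprocess
  res <- tryCatch({
    loaded <- if (!is.null(config$colony_table)) {
      load_colony_table(config$colony_table)
    } else if (!is.null(colony)) {
      colony_from_table(colony)
    } else {
      stopf("supply either config$colony_table or an in-memory colony")
    }
    excl <- apply_exclusions(loaded$mice, config$preprocess)
    logmsg("preprocess: %d mice in, %d retained (%d row errors)",
           excl$report$n_input, excl$report$n_retained, nrow(loaded$row_errors))
    excl
  }, error = function(e) fail("preprocess", e))
  cohort <- res$retained
  seqs <- as_observation_sequences(cohort, min_len = config$preprocess$min_points)
  summary <- summarize_cohort(cohort)

  # stage: fit
  fit <- tryCatch({
    f <- fit_with_restarts(seqs, n_states = config$n_states,
                           n_iters = config$n_iters,
                           n_restarts = config$n_restarts,
                           master_seed = config$seed, tol = config$em_tol)
    logmsg("fit: best restart %d, log-likelihood %.2f",
           f$best_restart, max(f$restarts$loglik))
    f
  }, error = function(e) fail("fit", e))

  # stage: classify + group
  traj <- tryCatch({
    cls <- classify_states(fit, threshold = config$ending_threshold)
    asg <- assign_terminal_states(seqs, fit, method = config$decode)
    grp <- group_by_trajectory(asg, cls)
    logmsg("trajectories: %d ending states, %d unassigned of %d",
           length(cls$ending_labels), length(grp$unassigned), grp$n_total)
    list(cls = cls, asg = asg, grp = grp)
  }, error = function(e) fail("trajectories", e))

  # stage: phenotype
  phen <- tryCatch({
    curves <- do.call(rbind, lapply(traj$grp$groups, trajectory_curve,
                                    seqs = seqs, min_n = config$min_n,
                                    bin_width = config$bin_width))
    pct <- vapply(traj$grp$groups, function(g) {
      as.numeric(percent_weight_change(g, seqs, ref_age = config$ref_age,
                                       min_n = config$min_n,
                                       bin_width = config$bin_width))
    }, numeric(1))
    logmsg("phenotype: percent change per group: %s",
           paste(sprintf("%s %.1f%%", names(pct), pct), collapse = ", "))
    list(curves = curves, pct = pct)
  }, error = function(e) fail("phenotype", e))

  # stage: validate
  valid <- tryCatch({
    glab <- stats::setNames(traj$asg$state, traj$asg$mouse_id)
    glab[!(traj$asg$state %in% traj$cls$ending_labels)] <- NA
    surv <- make_survival_records(cohort, groups = glab)
    surv_g <- surv[!is.na(surv$group), , drop = FALSE]
    km_by_group <- lapply(split(surv_g, surv_g$group), km_estimate)
    lr <- if (length(unique(surv_g$group)) >= 2 && sum(surv_g$event) > 0) {
      logrank_test(surv_g)
    } else NULL
    comp_tests <- list()
    mouse_sex <- vapply(cohort, `[[`, character(1), "sex")
    mouse_geno <- vapply(cohort, `[[`, character(1), "genotype")
    names(mouse_sex) <- names(mouse_geno) <- vapply(cohort, `[[`, character(1), "mouse_id")
    assigned <- traj$asg$mouse_id[traj$asg$state %in% traj$cls$ending_labels]
    if (length(unique(glab[assigned])) >= 2) {
      comp_tests$genotype <- contingency_chisq(glab[assigned], mouse_geno[assigned])
      comp_tests$sex <- contingency_chisq(glab[assigned], mouse_sex[assigned])
    }
    bio <- NULL
    if (!is.null(config$biomarker_table)) {
      bio <- utils::read.csv(config$biomarker_table, stringsAsFactors = FALSE)
    }
    comp <- NULL
    if (!is.null(config$composition_table)) {
      comp <- utils::read.csv(config$composition_table, stringsAsFactors = FALSE)
    }
    logmsg("validate: %d survival records (%d events), log-rank %s",
           nrow(surv_g), sum(surv_g$event),
           if (is.null(lr)) "skipped" else sprintf("chisq=%.2f", lr$chisq))
    list(survival = surv, km = km_by_group, logrank = lr,
         composition = comp_tests, biomarkers = bio, body_composition = comp)
  }, error = function(e) fail("validate", e))

  # stage: artifacts
  arts <- tryCatch({
    paths <- c(
      exclusion_csv = file.path(config$output_dir, "exclusion_report.csv"),
      exclusion_json = file.path(config$output_dir, "exclusion_report.json"),
      fit_json = file.path(config$output_dir, "fit.json"),
      transition_csv = file.path(config$output_dir, "transition_matrix.csv"),
      config_json = file.path(config$output_dir, "config.json")
    )
    write_exclusion_report(res$report, paths["exclusion_csv"],
                           paths["exclusion_json"])
    ahmm_fit_to_json(fit, paths["fit_json"])
    write_transition_csv(fit$params, paths["transition_csv"])
    tpaths <- write_trajectory_artifacts(traj$grp, traj$asg, phen$curves,
                                         phen$pct, config$output_dir)
    km_df <- do.call(rbind, lapply(names(valid$km), function(g) {
      cbind(group = g, as.data.frame(valid$km[[g]]))
    }))
    surv_csv <- file.path(config$output_dir, "km_curves.csv")
    utils::write.csv(km_df, surv_csv, row.names = FALSE)
    val_json <- file.path(config$output_dir, "validation.json")
    jsonlite::write_json(
      list(stamp = stamp,
           logrank = if (is.null(valid$logrank)) NULL else
             valid$logrank[c("chisq", "df", "p_value")],
           median_survival = lapply(valid$km, median_survival),
           composition = lapply(valid$composition, function(x)
             x[c("statistic", "df", "p_value")])),
      val_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(c(stamp, unclass(config)), paths["config_json"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(c(sprintf("config_hash=%s seed=%d", stamp$config_hash,
                         stamp$seed), log_lines), log_path)
    c(paths, groups_csv = tpaths[1], curves_csv = tpaths[2],
      trajectory_json = tpaths[3], km_csv = surv_csv,
      validation_json = val_json, run_log = log_path)
  }, error = function(e) fail("artifacts", e))

  invisible(structure(
    list(config = config, stamp = stamp, summary = summary,
         exclusion_report = res$report, fit = fit,
         classification = traj$cls, assignments = traj$asg,
         grouping = traj$grp, curves = phen$curves,
         percent_changes = phen$pct, validation = valid,
         artifacts = arts),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$stamp$seed,
              x$stamp$config_hash))
  cat(sprintf("Cohort: %d mice; %d ending states; %d unassigned\n",
              x$summary$n_mice, length(x$classification$ending_labels),
              length(x$grouping$unassigned)))
  pct <- x$percent_changes
  cat("Percent weight change from reference age:\n")
  for (g in names(pct)) cat(sprintf("  %s: %+.1f%%\n", g, pct[[g]]))
  invisible(x)
}
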