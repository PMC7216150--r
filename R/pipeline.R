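# One-call orchestration: simulate (or load) -> validate -> score ->
# network -> fit -> render, with every intermediate artifact written under a
# run directory and a manifest sufficient to reproduce the run.

#' Run the full analysis pipeline
#'
#' Executes all stages in order on either a synthetic cohort (pass a
#' [synth_config()]) or an on-disk dataset (pass the three CSV paths):
#' validation, scale scoring and reliability, per-school network metrics and
#' ego positions, the Pearson correlation table, the bivariate and
#' multivariate multilevel model batteries for both outcomes, and the
#' rendered report tables. For synthetic runs a planted-versus-recovered
#' comparison of the standardized betas is added. When `out_dir` is given,
#' all artifacts are written there under fixed file names
#' (`results.json`, `table1.csv`, `table2.csv`, `table3.csv`, `scores.csv`,
#' `ego_positions.csv`, `school_summary.csv`, `reliability.json`,
#' `validation.json`, `manifest.json`, plus the input CSVs for synthetic
#' runs). Any stage failure aborts with the stage name; artifacts of the
#' completed stages persist.
#'
#' @param config a [synth_config()] for a synthetic run, or `NULL` when
#'   paths are given.
#' @param roster_path,nominations_path,items_path CSV paths for a real-data
#'   run (all three required together, and mutually exclusive with
#'   `config`).
#' @param out_dir optional output directory.
#' @param centralization_mode degree direction for centralization (see
#'   [net_centralization()]).
#' @param nesting,reml model options passed to [fit_multilevel()].
#' @return An object of class `pipeline_run`: list with `validation`,
#'   `scores`, `reliability`, `positions`, `summaries`, `frame`, `pearson`,
#'   `models` (per outcome), `tables`, `recovery` (synthetic runs only) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = NULL, roster_path = NULL,
                         nominations_path = NULL, items_path = NULL,
                         out_dir = NULL, centralization_mode = "in",
                         nesting = "country_fixed", reml = FALSE) {
  synthetic <- !is.null(config)
  paths_given <- !is.null(roster_path)
  if (synthetic == paths_given) {
    stop("supply exactly one of: a synth_config, or the three CSV paths",
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (synthetic) {
    cohort <- stage("simulate", generate_cohort(config))
    roster <- cohort$roster
    nominations <- cohort$nominations
    items <- cohort$items
  } else {
    roster <- stage("load", read_roster(roster_path))
    nominations <- stage("load", read_nominations(nominations_path, roster))
    items <- stage("load", read_items(items_path, roster))
  }

  validation <- stage("validate", validate_cohort(roster, nominations, items))
  scores <- stage("score", score_scales(items, roster))
  reliability <- stage("score", reliability_report(items, roster))
  positions <- stage("network", cohort_positions(roster, nominations))
  summaries <- stage("network",
                     summarize_schools(roster, nominations, scores,
                                       centralization_mode))
  frame <- stage("fit", build_analysis_frame(roster, scores, positions,
                                             summaries))
  pearson <- stage("fit", pearson_table(frame))
  models <- stage("fit", list(
    burnout = fit_battery(frame, "burnout", nesting = nesting, reml = reml),
    engagement = fit_battery(frame, "engagement", nesting = nesting,
                             reml = reml)))
  tables <- stage("render", render_tables(frame, pearson, models))

  recovery <- NULL
  if (synthetic) {
    recovery <- stage("render", .recovery_table(cohort, models))
  }

  manifest <- list(
    synthetic = synthetic,
    seed = if (synthetic) config$seed else NA,
    centralization_mode = centralization_mode,
    nesting = nesting, reml = reml,
    n_students = nrow(roster), n_schools = nrow(summaries),
    package_version = as.character(utils::packageVersion("peerwell")),
    warnings = list(
      nomination_cleaning = as.list(validation$cleaning$nominations),
      item_cleaning = as.list(validation$cleaning$items))
  )

  run <- structure(list(validation = validation, scores = scores,
                        reliability = reliability, positions = positions,
                        summaries = summaries, frame = frame,
                        pearson = pearson, models = models, tables = tables,
                        recovery = recovery, manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    stage("write", .write_run(run, out_dir,
                              cohort = if (synthetic) cohort else NULL))
  }
  run
}

.recovery_table <- function(cohort, models) {
  rows <- list()
  for (outcome in c("burnout", "engagement")) {
    planted <- unlist(cohort$truth$planted[[outcome]])
    multi <- models[[outcome]]$multivariate
    for (tm in names(planted)) {
      est <- tryCatch(get_beta(multi, tm), error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = outcome, term = tm, planted = unname(planted[tm]),
        recovered = est, error = est - unname(planted[tm]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.model_to_list <- function(res) {
  list(label = res$label, outcome = res$outcome, type = res$type,
       formula = res$formula, n = res$n, n_schools = res$n_schools,
       minus2ll = res$minus2ll, reml = res$reml, nesting = res$nesting,
       coefficients = res$coefficients, vif = as.list(res$vif))
}

.write_run <- function(run, out_dir, cohort = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort)) write_cohort(cohort, out_dir)
  utils::write.csv(run$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$positions, file.path(out_dir, "ego_positions.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$summaries, file.path(out_dir, "school_summary.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$tables$table1, file.path(out_dir, "table1.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$tables$table2, file.path(out_dir, "table2.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$tables$table3, file.path(out_dir, "table3.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(run$reliability, file.path(out_dir, "reliability.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(schools = run$validation$schools,
         participation_rate = run$validation$participation_rate,
         cleaning = run$validation$cleaning,
         item_missingness = as.list(run$validation$item_missingness),
         violations = as.list(run$validation$violations)),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  results <- list(
    manifest = run$manifest,
    pearson = run$pearson,
    models = lapply(run$models, function(b) lapply(b, .model_to_list)),
    recovery = run$recovery
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(format_regression_table(run$tables$table2,
                                   "School burnout: standardized betas"),
           "",
           format_regression_table(run$tables$table3,
                                   "Schoolwork engagement: standardized betas"))
  writeLines(txt, file.path(out_dir, "report.txt"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", x$manifest$n_students, "students,",
      x$manifest$n_schools, "schools",
      if (isTRUE(x$manifest$synthetic)) sprintf("(synthetic, seed %d)",
                                                x$manifest$seed) else "",
      "\n")
  r5 <- x$pearson[x$pearson$covariate == "engagement" &
                    x$pearson$outcome == "burnout", ]
  if (nrow(r5)) cat(sprintf("  r(burnout, engagement) = %.3f\n", r5$r))
  for (out in names(x$models)) {
    m <- x$models[[out]]$multivariate
    cat(sprintf("  %s multivariate: connectedness beta = %.3f, -2LL = %.1f\n",
                out, get_beta(m, "connectedness"), m$minus2ll))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-beta recovery: max |error| = %.3f\n",
                max(abs(x$recovery$error), na.rm = TRUE)))
  }
  invisible(x)
}
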