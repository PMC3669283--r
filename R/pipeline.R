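# End-to-end pipeline: simulate -> extract -> reliability -> compare ->
# correlate -> score -> report, with provenance-stamped outputs and a
# command-line entry point.
#
# Provenance headers carry the package version, seed and a config hash but no
# timestamp, so a re-run under the same config and seed is byte-identical.

PIPELINE_STAGES <- c("simulate", "extract", "reliability", "compare",
                     "correlate", "score", "report")

# polynomial rolling hash over the JSON serialization (provenance only)
.config_hash <- function(config) {
  txt <- jsonlite::toJSON(.config_jsonify(unclass(config)),
                          auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenance <- function(seed, config) {
  c(sprintf("glovekin %s", as.character(packageVersion("glovekin"))),
    sprintf("seed=%d", as.integer(seed)),
    sprintf("config_hash=%s", .config_hash(config)))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, extracts kinematic parameters, and produces
#' the reliability table, group comparison, clinical correlation grid, the
#' fitted impairment-score model with ROC and leave-one-out evaluation, and
#' the disability-strata report. All outputs are CSV/JSON files under `out`,
#' each stamped with a provenance header (seed + config hash); a run under
#' the same config and seed is byte-identical.
#'
#' @param out output directory (created if needed).
#' @param seed integer RNG seed; recorded in every output.
#' @param config simulation configuration ([paper_defaults()] by default).
#' @param input optional list with paths `events`, `tones`, `cohort` (and
#'   optionally `retest_events`, `retest_tones`) to run on real recordings
#'   instead of simulating.
#' @param skip character vector of stages to skip (of
#'   `r paste(PIPELINE_STAGES, collapse = ", ")`); downstream stages that can
#'   still run do.
#' @param stages stages to execute (default all).
#' @param sessions sessions for the main cohort (default 1).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the in-memory stage results and the output
#'   file paths.
#' @export
run_pipeline <- function(out, seed = 1L, config = paper_defaults(),
                         input = NULL, skip = character(),
                         stages = PIPELINE_STAGES, sessions = 1L,
                         verbose = TRUE) {
  stopifnot(all(skip %in% PIPELINE_STAGES), all(stages %in% PIPELINE_STAGES))
  stages <- setdiff(stages, skip)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  prov <- .provenance(seed, config)
  log_lines <- c(prov, sprintf("stages=%s", paste(stages, collapse = ",")))
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message("[glovekin] ", msg)
  }
  res <- list(files = list())
  set.seed(as.integer(seed))

  run_stage <- function(name) name %in% stages
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- simulate ----------------------------------------------------------
  cohort <- NULL; trials <- NULL; retest_trials <- NULL
  if (!is.null(input)) {
    say("loading input data (%s)", input$events)
    trials <- read_trials(input$events, input$tones %||% NULL)
    cohort <- read_cohort(input$cohort)
    if (!is.null(input$retest_events)) {
      retest_trials <- read_trials(input$retest_events,
                                   input$retest_tones %||% NULL)
    }
  } else if (run_stage("simulate")) {
    tryCatch({
      say("simulating main cohort: %d HC + %d MS, %d session(s)",
          config$n_hc, config$n_ms, sessions)
      sim <- simulate_cohort(config, sessions = sessions,
                             dir = file.path(out, "data"),
                             provenance = prov)
      cohort <- sim$cohort; trials <- sim$trials
      res$files$data <- sim$files
      if ((config$n_retest_hc %||% 0) > 0) {
        say("simulating reliability sub-study: %d HC x 2 sessions",
            config$n_retest_hc)
        rconf <- config
        rconf$n_hc <- config$n_retest_hc
        rconf$n_ms <- 0L
        rsim <- simulate_cohort(rconf, sessions = 2L,
                                dir = file.path(out, "data_retest"),
                                provenance = prov)
        retest_trials <- rsim$trials
        res$files$data_retest <- rsim$files
      }
    }, error = function(e) fail("simulate", e))
  }
  res$cohort <- cohort

  # -- extract -----------------------------------------------------------
  params <- NULL; retest_params <- NULL
  if (run_stage("extract") && !is.null(trials)) {
    tryCatch({
      say("extracting kinematic parameters from %d trial(s)", length(trials))
      params <- extract_params(trials)
      res$files$params <- file.path(out, "params.csv")
      .write_glove_csv(params, res$files$params, prov)
      if (!is.null(retest_trials)) {
        retest_params <- extract_params(retest_trials)
        res$files$params_retest <- file.path(out, "params_retest.csv")
        .write_glove_csv(retest_params, res$files$params_retest, prov)
      }
    }, error = function(e) fail("extract", e))
  }
  res$params <- params

  # -- reliability -------------------------------------------------------
  if (run_stage("reliability") && !is.null(retest_params)) {
    tryCatch({
      say("reliability report (test-retest)")
      rel <- reliability_report(retest_params)
      res$reliability <- rel
      res$files$reliability <- file.path(out, "reliability.csv")
      .write_glove_csv(rel, res$files$reliability, prov)
    }, error = function(e) fail("reliability", e))
  }

  features <- NULL
  if (!is.null(params) && !is.null(cohort)) {
    wide <- params_wide(params[params$session == min(params$session), ])
    features <- merge(wide, as.data.frame(cohort)[, c("subject_id", "group",
                                                      "age")],
                      by = "subject_id")
  }

  # -- compare -----------------------------------------------------------
  if (run_stage("compare") && !is.null(features)) {
    tryCatch({
      say("group comparison (Mann-Whitney)")
      cmp <- group_comparison(features, cohort)
      res$comparison <- cmp
      res$files$comparison <- file.path(out, "comparison.csv")
      .write_glove_csv(cmp, res$files$comparison, prov)
    }, error = function(e) fail("compare", e))
  }

  # -- correlate ---------------------------------------------------------
  if (run_stage("correlate") && !is.null(features)) {
    tryCatch({
      say("clinical correlation grid (age-adjusted partial Spearman)")
      ct <- correlation_table(features, cohort)
      res$correlations <- ct
      res$files$correlations <- file.path(out, "correlations.csv")
      .write_glove_csv(ct, res$files$correlations, prov)
    }, error = function(e) fail("correlate", e))
  }

  # -- score -------------------------------------------------------------
  scores <- NULL
  if (run_stage("score") && !is.null(features)) {
    tryCatch({
      say("stepwise logistic impairment score + ROC / LOO-CV")
      cc <- features[complete.cases(
        features[c(DEFAULT_CANDIDATES, "age")]), , drop = FALSE]
      model <- stepwise_logistic(cc, cc$group)
      scores <- fmi_score(model, cc)
      lp_roc <- roc_auc(scores, cc$group)
      loo <- loo_cv_auc(cc, cc$group, selected = model$features)
      res$model <- model
      res$roc <- lp_roc
      res$loo <- loo
      say("selected: %s; apparent AUC = %.3f, LOO AUC = %.3f",
          paste(model$features, collapse = "+"), lp_roc$auc, loo$auc)
      res$files$model <- file.path(out, "model.json")
      jsonlite::write_json(list(
        provenance = prov,
        features = model$features, forced = model$forced,
        transforms = as.list(model$transforms),
        coefficients = as.list(model$coefficients),
        se = as.list(model$se),
        odds_ratio = as.list(model$odds_ratio),
        or_ci = if (length(model$features)) {
          setNames(lapply(seq_along(model$features), function(i)
            as.numeric(model$or_ci[i, ])), model$features)
        } else list(),
        separation = model$separation,
        auc = lp_roc$auc, auc_ci = lp_roc$ci, auc_p = lp_roc$p,
        loo_auc = loo$auc, loo_auc_ci = loo$ci, loo_auc_p = loo$p
      ), res$files$model, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      score_df <- data.frame(subject_id = cc$subject_id, group = cc$group,
                             fmi_score = scores)
      res$scores <- score_df
      res$files$scores <- file.path(out, "scores.csv")
      .write_glove_csv(score_df, res$files$scores, prov)
      res$files$roc <- file.path(out, "roc.csv")
      .write_glove_csv(lp_roc$curve, res$files$roc, prov)
    }, error = function(e) fail("score", e))
  }

  # -- report ------------------------------------------------------------
  if (run_stage("report") && !is.null(scores)) {
    tryCatch({
      say("disability-strata trend report")
      cc <- res$scores
      meta <- merge(cc, as.data.frame(cohort)[, c("subject_id", "edss")],
                    by = "subject_id")
      strata <- edss_strata(meta$group, meta$edss)
      tr <- edss_strata_trend(meta$fmi_score, strata)
      res$strata <- tr
      say("trend p = %.3g across %d strata", tr$trend_p, nrow(tr$strata))
      res$files$strata <- file.path(out, "strata.csv")
      .write_glove_csv(tr$strata, res$files$strata, prov)
      res$files$strata_pairwise <- file.path(out, "strata_pairwise.csv")
      .write_glove_csv(tr$pairwise_vs_first, res$files$strata_pairwise, prov)
    }, error = function(e) fail("report", e))
  }

  res$files$log <- file.path(out, "run_log.txt")
  writeLines(log_lines, res$files$log)
  invisible(res)
}

.cli_usage <- function() {
  cat("usage: glovekin <command> [--seed INT] [--out DIR] [--config PATH]\n",
      "                [--profile paper_defaults] [--skip STAGE[,STAGE]]\n",
      "                [--n-hc N] [--n-ms N] [--n-retest N] [--sessions N]\n",
      "commands: ", paste(c(PIPELINE_STAGES, "run"), collapse = ", "), "\n",
      sep = "")
}

.cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      stop("flag --", key, " needs a value")
    }
    flags[[gsub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `extract`, `reliability`, `compare`, `correlate`,
#' `score`, `report` run the pipeline up to (and including) that stage;
#' `run` executes everything. See `inst/cli/glovekin.R` for an Rscript
#' wrapper.
#'
#' @param args character vector of CLI arguments (default: the process
#'   command line).
#' @return Invisibly, the [run_pipeline()] result (or NULL for usage).
#' @export
glove_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[[1L]] %in% c("-h", "--help", "help")) {
    .cli_usage()
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  if (!cmd %in% c(PIPELINE_STAGES, "run")) {
    stop("unknown command: ", cmd)
  }
  flags <- .cli_parse_flags(args[-1L])
  seed <- as.integer(flags$seed %||% 1L)
  out <- flags$out %||% "glovekin_run"
  profile <- flags$profile %||% "paper_defaults"
  if (profile != "paper_defaults") stop("unknown profile: ", profile)
  config <- paper_defaults()
  if (!is.null(flags$config)) {
    config <- read_sim_config(flags$config)
  }
  if (!is.null(flags$n_hc)) config$n_hc <- as.integer(flags$n_hc)
  if (!is.null(flags$n_ms)) config$n_ms <- as.integer(flags$n_ms)
  if (!is.null(flags$n_retest)) config$n_retest_hc <- as.integer(flags$n_retest)
  sessions <- as.integer(flags$sessions %||% 1L)
  skip <- if (!is.null(flags$skip)) {
    strsplit(flags$skip, ",", fixed = TRUE)[[1L]]
  } else character()
  stages <- if (cmd == "run") {
    PIPELINE_STAGES
  } else {
    PIPELINE_STAGES[seq_len(match(cmd, PIPELINE_STAGES))]
  }
  invisible(run_pipeline(out, seed = seed, config = config, skip = skip,
                         stages = stages, sessions = sessions))
}

# named atomic vectors must become JSON objects, not bare arrays
.config_jsonify <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .config_jsonify))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' Save / load a simulation configuration as JSON
#'
#' @param config a `sim_config`.
#' @param path JSON file path.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(.config_jsonify(unclass(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) {
    v <- unlist(x)
    storage.mode(v) <- "double"
    v
  }
  for (g in names(raw$groups)) {
    raw$groups[[g]] <- lapply(raw$groups[[g]], function(x) {
      if (is.list(x) || (is.numeric(x) && !is.null(names(x)))) num(x)
      else if (is.numeric(x)) x else x
    })
  }
  raw$icc_split <- num(raw$icc_split)
  raw$trial <- lapply(raw$trial, function(x) if (is.numeric(x)) x else num(x))
  raw$copula <- as.data.frame(raw$copula, stringsAsFactors = FALSE)
  structure(raw, class = "sim_config")
}
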