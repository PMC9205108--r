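#' Configure an end-to-end valuation pipeline run
#'
#' Bundles every knob of the pipeline: the master seed (all stage seeds are
#' derived from it by fixed offsets), cohort size, design parameters, the
#' simulation truth, margin targets and sampling skew, the representativeness
#' threshold, raking tolerances, the constraint round cap, and the output
#' directory. In ingest mode, paths to externally collected choice/profile
#' CSVs replace the simulation stages.
#'
#' @param seed Master integer seed.
#' @param n_respondents Cohort size (default 1582, the Canadian analysis set).
#' @param n_blocks,n_sets,n_differ Design shape (see [generate_design()]).
#'   The default, 60 blocks of 16 sets, mirrors the design family used for
#'   FACT-8D/QLU-C10D valuations (each respondent answers one 16-set
#'   version of a much larger blocked design); a single shared block would
#'   leave a 33-parameter model unidentified.
#' @param prefs Simulation truth, a [true_preferences()]; default the
#'   published constrained Canadian coefficients.
#' @param margins Population [margin_targets()].
#' @param skew Panel sampling skew (see [simulate_respondents()]).
#' @param completion Completion model (see [simulate_choices()]).
#' @param rep_threshold Flagging threshold for [assess_representativeness()].
#' @param rake_tol,rake_max_iter Raking convergence controls.
#' @param max_rounds Constraint rounds cap for [constrain()].
#' @param out_dir Output directory (created if missing).
#' @param choices_file,profiles_file Optional ingest-mode CSV paths.
#' @return Object of class `fact8d_config`.
#' @export
pipeline_config <- function(seed = 1, n_respondents = 1582, n_blocks = 60,
                            n_sets = 16, n_differ = 5,
                            prefs = published_model_coefficients(3),
                            margins = canadian_margins(),
                            skew = canadian_sample_skew(),
                            completion = list(frac_partial = 81 / 1582,
                                              min_sets = 1),
                            rep_threshold = 0.02, rake_tol = 1e-6,
                            rake_max_iter = 100, max_rounds = 10,
                            out_dir = tempfile("fact8d_run_"),
                            choices_file = NULL, profiles_file = NULL) {
  stopifnot(rep_threshold > 0, rake_tol > 0, rake_max_iter >= 1,
            max_rounds >= 1, n_respondents >= 1)
  for (f in c(choices_file, profiles_file)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input file does not exist: ", f, call. = FALSE)
    }
  }
  cfg <- list(seed = as.integer(seed), n_respondents = n_respondents,
              n_blocks = n_blocks, n_sets = n_sets, n_differ = n_differ,
              prefs = prefs, margins = margins, skew = skew,
              completion = completion, rep_threshold = rep_threshold,
              rake_tol = rake_tol, rake_max_iter = rake_max_iter,
              max_rounds = max_rounds, out_dir = out_dir,
              choices_file = choices_file, profiles_file = profiles_file)
  class(cfg) <- "fact8d_config"
  cfg
}

#' Semantic hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialisation of every semantic field (the
#' output directory is excluded: where artifacts land does not change what
#' they are). Two configs hash equal iff they describe the same run.
#'
#' @param config A [pipeline_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  sem <- unclass(config)
  sem$out_dir <- NULL
  sem$prefs <- list(alpha = sem$prefs$alpha,
                    beta = as.vector(sem$prefs$beta))
  sem$margins <- lapply(unclass(sem$margins), as.list)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sem, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full valuation pipeline
#'
#' Executes, in order: design generation (or ingest), cohort simulation (or
#' ingest), choice simulation, representativeness assessment, raking, the
#' unweighted fit (Model 1), the weighted fit (Model 2), the
#' monotonicity-constrained fit (Model 3), the likelihood-ratio comparison,
#' value-set derivation, and a scoring demonstration on example FACT-G
#' responses. Every artifact is written under `config$out_dir`, stamped with
#' the seed and the [config_hash()]; a plain-text log with ISO timestamps
#' records each stage. A stage failure aborts with the stage named; artifacts
#' already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list bundle: `design`, `profiles`, `choices`,
#'   `representativeness`, `weights`, `fit_unweighted`, `fit_weighted`,
#'   `constrained` (spec/fit/history), `lr`, `value_set`, `scoring_demo`,
#'   `config`, `hash`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "fact8d_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  logf("pipeline start seed=%d hash=%s", config$seed, hash)
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage %s: done", name)
    out
  }
  files <- character()
  emit <- function(obj, fname, writer) {
    path <- file.path(config$out_dir, fname)
    writer(obj, path)
    files[[fname]] <<- path
    path
  }
  stamp <- list(seed = config$seed, config_hash = hash)

  design <- stage("design", {
    generate_design(n_blocks = config$n_blocks, seed = config$seed,
                    n_sets = config$n_sets, n_differ = config$n_differ)
  })
  emit(design, "design.csv", write_design_csv)

  if (is.null(config$choices_file)) {
    profiles <- stage("cohort", {
      simulate_respondents(config$margins, n = config$n_respondents,
                           skew = config$skew, seed = config$seed + 1L)
    })
    choices <- stage("choices", {
      simulate_choices(design, config$prefs, profiles,
                       seed = config$seed + 2L,
                       completion = config$completion)
    })
  } else {
    choices <- stage("ingest_choices", read_choices_csv(config$choices_file))
    profiles <- stage("ingest_profiles", {
      if (is.null(config$profiles_file)) {
        stop("ingest mode needs profiles_file alongside choices_file")
      }
      df <- utils::read.csv(config$profiles_file, stringsAsFactors = FALSE)
      if (!"resp_id" %in% names(df)) stop("profiles lack column: resp_id")
      df
    })
  }
  emit(profiles, "profiles.csv",
       function(x, p) utils::write.csv(x, p, row.names = FALSE))
  emit(choices, "choices.csv", write_choices_csv)

  rep_report <- stage("representativeness", {
    assess_representativeness(profiles, config$margins,
                              threshold = config$rep_threshold)
  })
  emit(rep_report, "representativeness.json", function(x, p) {
    jsonlite::write_json(c(stamp, list(report = x)), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  weights <- stage("raking", {
    rake(profiles, config$margins,
         variables = rep_report$variable[rep_report$flagged],
         tol = config$rake_tol, max_iter = config$rake_max_iter)
  })
  emit(weights, "weights.csv", write_weights_csv)

  spec <- default_model_spec()
  fit1 <- stage("model1_unweighted", fit_clogit(choices, spec))
  fit2 <- stage("model2_weighted", fit_clogit(choices, spec, weights))
  constrained <- stage("model3_constrained", {
    constrain(choices, spec, weights, max_rounds = config$max_rounds)
  })
  for (nmfit in list(list("model1", fit1), list("model2", fit2),
                     list("model3", constrained$fit))) {
    emit(nmfit[[2]], paste0(nmfit[[1]], "_fit.json"), function(x, p) {
      jsonlite::write_json(c(stamp, list(
        coefficients = as.list(x$coefficients),
        robust_se = as.list(x$se), loglik = x$loglik, k = x$k,
        n_obs = x$n_obs, aic = x$aic, bic = x$bic,
        converged = x$converged, weighted = x$weighted
      )), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    emit(coefficient_table(nmfit[[2]]), paste0(nmfit[[1]], "_coefficients.csv"),
         function(x, p) utils::write.csv(x, p, row.names = FALSE))
  }

  lr <- stage("model_comparison", lr_test(constrained$fit, fit2))
  emit(NULL, "model_comparison.json", function(x, p) {
    jsonlite::write_json(c(stamp, list(
      lr_statistic = lr$statistic, df = lr$df, p_value = lr$p_value,
      aic = list(model1 = fit1$aic, model2 = fit2$aic,
                 model3 = constrained$fit$aic),
      bic = list(model1 = fit1$bic, model2 = fit2$bic,
                 model3 = constrained$fit$bic),
      unweighted_vs_weighted = compare_fits(fit1, fit2)
    )), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  vs <- stage("value_set", {
    derive_value_set(constrained$fit,
                     label = sprintf("derived value set (seed %d)",
                                     config$seed))
  })
  emit(vs, "value_set.json", function(x, p) write_value_set(x, p, digits = NA))
  emit(vs, "value_set.csv", function(x, p) write_value_set(x, p, digits = 3))

  demo <- stage("scoring_demo", {
    resp <- data.frame(GP1 = c(0, 4, 1), GP2 = c(0, 4, 0), GP4 = c(0, 4, 2),
                       GF1 = c(4, 0, 3), GF5 = c(4, 0, 4), GS2 = c(4, 0, 4),
                       GS3 = c(4, 0, 2), GE1 = c(0, 4, 1), GE6 = c(0, 4, 1))
    resp$utility <- score_factg(resp, vs)
    resp
  })
  emit(demo, "scoring_demo.csv",
       function(x, p) utils::write.csv(x, p, row.names = FALSE))

  logf("pipeline done: %d artifacts", length(files))
  invisible(list(design = design, profiles = profiles, choices = choices,
                 representativeness = rep_report, weights = weights,
                 fit_unweighted = fit1, fit_weighted = fit2,
                 constrained = constrained, lr = lr, value_set = vs,
                 scoring_demo = demo, config = config, hash = hash,
                 files = files))
}
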