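# Pipeline driver and table rendering: one entry point that runs a named
# analysis stage from a config (R list or YAML file) and writes
# machine-readable artifacts, plus renderers that recompute the headline
# tables from scratch.

.config_hash <- function(config) {
  # stable content hash without extra dependencies; the artifact location
  # is not part of the run's identity
  config$out_dir <- NULL
  ser <- serialize(config, NULL, version = 2)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(ser, tmp)
  unname(tools::md5sum(tmp))
}

.load_bundle <- function(config) {
  get_par <- function(name, type) {
    key <- paste0(name, "_file")
    if (!is.null(config[[key]])) {
      if (!file.exists(config[[key]])) {
        stop(sprintf("parameter file '%s' does not exist", config[[key]]),
             call. = FALSE)
      }
      read_params(config[[key]], type)
    } else {
      fitted_params(if (name == "treatment") "treatment_a" else name)
    }
  }
  list(healthy = get_par("healthy", "healthy"),
       tumor = get_par("tumor", "tumor"),
       cachexia = get_par("cachexia", "cachexia"),
       treatment = get_par("treatment", "treatment"))
}

#' Run one pipeline stage from a configuration
#'
#' Supported commands: `"steady-state"` (closed-form equilibrium, stem
#' ratio, and day-49 reference ratio), `"tumor-threshold"`,
#' `"sensitivity"` (`context` = `"steady-state"` or `"day20"`),
#' `"wound-heal"` (`chi` vector), `"simulate"` (`model`, `days`), and
#' `"synth"` (`cohort` = `"healthy"`, `"cachexia"`, or `"treatment"`).
#' Every run writes a `summary.json` to `out_dir` containing the computed
#' headline quantities, the seed, the package version, and a hash of the
#' config; deterministic artifacts re-run byte-identically. On error any
#' partial outputs of the failed run are removed.
#'
#' @param config a named list or the path to a YAML file. Common fields:
#'   `command` (required), `out_dir` (default `"."`), `seed` (default 1),
#'   `healthy_file`/`tumor_file`/`cachexia_file`/`treatment_file` (optional
#'   JSON/YAML parameter files; the fitted bundles are used otherwise), and
#'   command-specific fields documented above.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop(sprintf("config file '%s' does not exist", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$command)) stop("config needs a `command`", call. = FALSE)
  out_dir <- config$out_dir %||% "."
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(path) { written <<- c(written, path); path }
  summary <- list(command = config$command, seed = seed,
                  package_version = as.character(utils::packageVersion("cachexim")),
                  config_hash = .config_hash(config))
  result <- tryCatch({
    pars <- .load_bundle(config)
    conv <- conversion_convention()
    if (config$command == "steady-state") {
      ss <- steady_state(pars$healthy)
      summary$S_ss_mm3 <- ss[["S"]]
      summary$M_ss_mm3 <- ss[["M"]]
      summary$stem_ratio_ss <- steady_state_stem_ratio(pars$healthy)
      summary$stem_ratio_day49 <- reference_stem_ratio(pars$healthy)
    } else if (config$command == "tumor-threshold") {
      summary$transition_threshold_mm3 <- transition_threshold(pars$tumor)
      summary$transition_day <-
        .threshold_day(pars$tumor, config$T0 %||% 0.5)
    } else if (config$command == "sensitivity") {
      ctx <- config$context %||% "steady-state"
      tab <- if (ctx == "steady-state") {
        healthy_sensitivity_table(pars$healthy)
      } else {
        cachexia_sensitivity_table(pars$healthy, pars$cachexia, pars$tumor,
                                   tx = pars$treatment)
      }
      note(render_sensitivity_table(tab, file.path(out_dir, "sensitivity")))
      summary$context <- ctx
      summary$n_rows <- nrow(tab)
    } else if (config$command == "wound-heal") {
      chi <- config$chi %||% c(0.9, 0.8, 0.7)
      ht <- vapply(chi, function(x) {
        wound_healing_experiment(x, pars$healthy)$healing_time
      }, 0)
      summary$chi <- chi
      summary$healing_time_days <- ht
    } else if (config$command == "simulate") {
      model <- config$model %||% "cachexia"
      days <- config$days %||% 30
      state0 <- if (model == "healthy") healthy_initial_state() else
        tissue_state(S = 252.75, M = 4799.25, T = config$T0 %||% 0.5)
      spec <- experiment_spec(if (model == "treatment") "cachexia" else model,
                              pars, state0, seq(0, days, by = 0.5))
      traj <- if (model == "treatment") simulate_treatment(spec) else
        integrate_model(spec)
      note(write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"),
                                conv))
      n <- length(traj$times)
      summary$model <- model
      summary$final_lean_mass_g <- conv$xi * (traj$S[n] + traj$M[n])
      summary$final_stem_ratio <- traj$S[n] / traj$M[n]
      if (model != "healthy") {
        summary$effective_muscle_death <-
          effective_muscle_death(pars$healthy, pars$cachexia,
                                 pars$treatment)
      }
    } else if (config$command == "synth") {
      cohort_kind <- config$cohort %||% "cachexia"
      if (cohort_kind == "healthy") {
        spec <- cohort_spec(config$n %||% 10, fitted_params("logistic"),
                            c(seq(0, 84, by = 7), seq(90, 300, by = 10)),
                            cv = config$cv %||% 0.02, seed = seed)
        cohort <- generate_healthy_cohort(spec)
        spec_out <- spec
      } else {
        spec <- cohort_spec(config$n %||% 10, pars,
                            seq(0, 30, by = 1),
                            cv = config$cv %||% 0.02, seed = seed)
        gen <- if (cohort_kind == "treatment") generate_treatment_cohort else
          generate_cachexia_cohort
        cohort <- gen(spec, config$day0_weight %||% cohort_day0_weight("A"))
        spec_out <- spec
      }
      paths <- write_cohort(cohort, spec_out, out_dir,
                            stem = paste0("synth_", cohort_kind))
      for (p_ in paths) note(p_)
      summary$cohort <- cohort_kind
      summary$n_animals <- spec_out$n
    } else {
      stop(sprintf("unknown command '%s'", config$command), call. = FALSE)
    }
    summary
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.threshold_day <- function(tp, T0) {
  # day the solved tumor crosses the exponential-to-linear threshold
  Tth <- transition_threshold(tp)
  out <- .solve_ode(c(T = T0), seq(0, 60, by = 0.01),
                    function(t, y, parms) list(tumor_rate(y, tp)),
                    rtol = 1e-8, atol = 1e-10)
  cross <- which(out[, "T"] >= Tth)
  if (length(cross) == 0) NA_real_ else unname(out[cross[1], 1])
}

#' Render a sensitivity table to CSV and Markdown
#'
#' Writes freshly computed sensitivity results (never fixture values) as
#' `<stem>.csv` and `<stem>.md`.
#'
#' @param tab a data frame from [healthy_sensitivity_table()] or
#'   [cachexia_sensitivity_table()]; must be non-empty.
#' @param stem output path without extension.
#' @return The CSV path, invisibly.
#' @export
render_sensitivity_table <- function(tab, stem) {
  if (is.null(tab) || nrow(tab) == 0) {
    stop("no sensitivity results to render", call. = FALSE)
  }
  csv <- paste0(stem, ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  md <- paste0(stem, ".md")
  writeLines(render_table_markdown(tab), md)
  invisible(csv)
}

#' Format a data frame as a Markdown table
#'
#' @param df a non-empty data frame.
#' @param digits significant digits for numeric columns.
#' @return Character vector of Markdown lines.
#' @export
render_table_markdown <- function(df, digits = 4) {
  if (is.null(df) || nrow(df) == 0) {
    stop("cannot render an empty table", call. = FALSE)
  }
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", signif(x, digits)) else
      as.character(x)
  }
  cells <- vapply(df, function(col) as.character(fmt(col)),
                  character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}
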