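#' Default pipeline configuration
#'
#' A complete demo configuration for [run_pipeline()]: FRAP trace
#' simulation and fitting for both channels, a photoconversion waveform
#' series with difference map, and pulse-chase population classification at
#' three chase times.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @return A named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(outdir = tempfile("myoturn_run_"),
                                    seed = 1L) {
  list(
    seed = seed,
    outdir = outdir,
    stages = list(frap = TRUE, waveform = TRUE, classify = TRUE,
                  report = TRUE, figures = FALSE),
    frap = list(
      n_traces = 7,
      times_h = seq(0, 10, by = 1 / 6),
      presets = list(green = "monoexp_green", red = "monoexp_red"),
      render = list(noise_sd = 0.02, bleach_rate_green = 0.02,
                    red_linear_drift = 2e-4)
    ),
    waveform = list(
      preset = "tip_biased_photoconv",
      times_min = seq(20, 200, by = 20),
      n_fibrils = 7,
      degree = 6
    ),
    population = list(
      preset = "tip_biased",
      chase_times_min = c(7, 15, 30),
      n_sarcomeres = 60,
      n_myotubes = 6
    ),
    rules = list()
  )
}

# stable hash: recursively sort names so key order does not matter
sorted_config <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(names(x) != "")) {
      x <- x[order(names(x))]
    }
    lapply(x, sorted_config)
  } else x
}

#' Validate a pipeline configuration
#'
#' Checks that the configuration has the sections its enabled stages need.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one.
#' @return The validated configuration list, invisibly filled with
#'   defaults.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("validation error: config must be a list or a YAML path",
         call. = FALSE)
  }
  bad <- character(0)
  if (is.null(config$seed)) bad <- c(bad, "seed")
  if (is.null(config$outdir)) bad <- c(bad, "outdir")
  if (is.null(config$stages)) bad <- c(bad, "stages")
  st <- config$stages
  if (isTRUE(st$frap) && is.null(config$frap)) bad <- c(bad, "frap")
  if (isTRUE(st$waveform) && is.null(config$waveform)) {
    bad <- c(bad, "waveform")
  }
  if (isTRUE(st$classify) && is.null(config$population)) {
    bad <- c(bad, "population")
  }
  if (length(bad) > 0) {
    stop(sprintf("validation error: missing or inconsistent config keys: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  config
}

render_from_list <- function(lst) {
  do.call(render_config, lst %||% list())
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order - FRAP simulation,
#' normalization and fitting; photoconversion waveform series and
#' difference map; pulse-chase population generation, classification and
#' summary; report - writing CSV outputs (and optionally figures) under the
#' configured output directory. Identical configuration and seed give
#' byte-identical CSV outputs.
#'
#' @param config A configuration list or YAML path; see
#'   [default_pipeline_config()] and [validate_config()].
#' @return An object of class `run_manifest`: configuration hash, package
#'   version, seed, per-stage output file list, collected warnings and wall
#'   time.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- validate_config(config)
  t0 <- Sys.time()
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  rules <- do.call(classification_rules, config$rules %||% list())
  files <- character(0)
  warns <- character(0)
  note <- function(msg) warns <<- c(warns, msg)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  if (isTRUE(config$stages$frap)) {
    fr <- config$frap
    render <- render_from_list(fr$render)
    fit_rows <- list()
    for (channel in names(fr$presets)) {
      kin <- kinetics_preset(fr$presets[[channel]])
      traces <- lapply(seq_len(fr$n_traces), function(i) {
        simulate_frap_trace(kin, render, times = fr$times_h,
                            seed = derive_seed(seed, i +
                              1000L * match(channel, names(fr$presets))))
      })
      cv <- if (channel == "red") {
        withCallingHandlers(estimate_red_correction(traces),
                            warning = function(w) {
                              note(conditionMessage(w))
                              invokeRestart("muffleWarning")
                            })
      } else NULL
      for (i in seq_along(traces)) {
        norm <- if (channel == "green") {
          normalize_green(traces[[i]])
        } else {
          withCallingHandlers(
            normalize_red(traces[[i]], correction_value = cv),
            warning = function(w) {
              note(conditionMessage(w)); invokeRestart("muffleWarning")
            })
        }
        f <- fit_recovery(norm)
        fit_rows[[length(fit_rows) + 1L]] <- dplyr::mutate(
          glance(f), channel = channel, trace = i, .before = 1)
      }
    }
    emit(dplyr::bind_rows(fit_rows), "frap_fits.csv")
  }

  waveform_tbl <- NULL
  if (isTRUE(config$stages$waveform)) {
    wf <- config$waveform
    waveform_tbl <- generate_photoconversion_series(
      kinetics = kinetics_preset(wf$preset),
      times_min = wf$times_min, n_fibrils = wf$n_fibrils,
      degree = wf$degree %||% 6, seed = derive_seed(seed, 77L))
    emit(waveform_tbl, "waveforms.csv")
    emit(build_difference_map(waveform_tbl), "difference_map.csv")
  }

  if (isTRUE(config$stages$classify)) {
    pp <- config$population
    cls <- list(); summ <- list()
    for (ct in pp$chase_times_min) {
      pop <- generate_pulse_chase_population(
        chase_time_min = ct, n_sarcomeres = pp$n_sarcomeres,
        n_myotubes = pp$n_myotubes,
        kinetics = kinetics_preset(pp$preset), rules = rules,
        seed = derive_seed(seed, 500L + ct))
      if (pop$n_failed > 0) {
        note(sprintf("chase %g min: %d sarcomere(s) skipped (segmentation)",
                     ct, pop$n_failed))
      }
      cls[[length(cls) + 1L]] <- classify_patterns(pop, rules)
    }
    cls <- dplyr::bind_rows(cls)
    emit(dplyr::select(cls, -"peaks"), "classifications.csv")
    ps <- summarize_patterns(cls)
    emit(ps$frequency, "summary.csv")
    emit(ps$rollup, "summary_rollup.csv")
    emit(ps$medians, "peak_shift_medians.csv")
  }

  manifest <- structure(
    list(config = config,
         config_hash = rlang::hash(sorted_config(config)),
         package_version = as.character(utils::packageVersion("myoturn")),
         seed = seed,
         files = files,
         warnings = warns,
         wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_manifest"
  )

  if (isTRUE(config$stages$report)) {
    report_path <- file.path(outdir, "report.md")
    report_run(manifest, path = report_path)
    manifest$files <- c(manifest$files, report_path)
  }
  manifest
}

read_csv_safe <- function(path, note) {
  tryCatch(utils::read.csv(path), error = function(e) {
    note(sprintf("could not read %s: %s", basename(path),
                 conditionMessage(e)))
    NULL
  })
}

#' Render a human-readable run report
#'
#' Summarizes a pipeline run as markdown: fitted mobile fraction and
#' half-life per channel, category proportions per time point, and median
#' peak shifts. Stages without outputs are marked as not run; unreadable
#' output files produce a warning and are skipped.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param path Optional file path to write the report to.
#' @return The report, a character vector of markdown lines (invisibly
#'   when written to a file).
#' @export
report_run <- function(manifest, path = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  warns <- character(0)
  note <- function(m) warns <<- c(warns, m)
  find_file <- function(name) {
    hit <- manifest$files[basename(manifest$files) == name]
    if (length(hit) == 1L && file.exists(hit)) hit else NA_character_
  }
  lines <- c("# myoturn pipeline report", "",
             sprintf("- package version: %s", manifest$package_version),
             sprintf("- seed: %d", manifest$seed),
             sprintf("- config hash: %s", manifest$config_hash), "")

  section <- function(title, file, body) {
    lines <<- c(lines, paste("##", title), "")
    dat <- {
      fp <- find_file(file)
      if (!is.na(fp)) read_csv_safe(fp, note) else NULL
    }
    if (is.null(dat)) {
      lines <<- c(lines, "*not run*", "")
      return(invisible())
    }
    body_lines <- tryCatch(body(dat), error = function(e) {
      note(sprintf("section '%s' skipped: %s", title, conditionMessage(e)))
      "*skipped (unreadable output)*"
    })
    lines <<- c(lines, body_lines, "")
  }

  section("FRAP kinetics", "frap_fits.csv", function(fits) {
    agg <- fits |>
      dplyr::filter(.data$converged) |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(Mf = mean(.data$Mf), t_half = mean(.data$t_half),
                       n = dplyr::n(), .groups = "drop")
    c("| channel | mean Mf | mean t_half (h) | n |",
      "|---|---|---|---|",
      sprintf("| %s | %.4f | %.3f | %d |",
              agg$channel, agg$Mf, agg$t_half, agg$n))
  })

  section("Incorporation patterns", "summary_rollup.csv", function(roll) {
    c("| chase (min) | group | mean proportion | SE |",
      "|---|---|---|---|",
      sprintf("| %g | %s | %.3f | %.3f |",
              roll$time_min, roll$group, roll$mean_prop, roll$se))
  })

  section("Peak shift", "peak_shift_medians.csv", function(med) {
    c("| chase (min) | median peak distance | n peaks |",
      "|---|---|---|",
      sprintf("| %g | %.3f | %d |",
              med$time_min, med$median_shift, med$n_peaks))
  })

  if (length(c(manifest$warnings, warns)) > 0) {
    lines <- c(lines, "## Warnings", "",
               paste0("- ", c(manifest$warnings, warns)), "")
  }
  for (w in warns) warning(w, call. = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
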