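# End-to-end reproducible runs: configuration, staged execution, manifest
# and report. Every stage reads and writes files, so stages compose
# without rerunning upstream; one global seed derives all stage seeds via
# derive_seed().

#' Build a pipeline run configuration
#'
#' @param protocol a \code{stimulus_protocol}.
#' @param generator a \code{generator_config}, or NULL when input files
#'   are supplied instead.
#' @param out_dir output directory (created if absent).
#' @param seed global seed; mandatory.
#' @param analyses character vector of stage toggles, any of
#'   \code{"classify", "fractions", "transitions", "fits", "circuit"}.
#' @param input_records optional path to a response-record CSV, used
#'   instead of the generator.
#' @param duration recording duration (s) for count series; default: the
#'   protocol span.
#' @param circuit a \code{circuit_params} for the circuit stage.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(protocol, generator, out_dir, seed,
                       analyses = c("classify", "fractions", "transitions",
                                    "fits", "circuit"),
                       input_records = NULL, duration = NULL,
                       circuit = circuit_params()) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (missing(seed) || !is.numeric(seed)) stop_domain("seed is mandatory")
  if (is.null(generator) && is.null(input_records))
    stop_domain("either a generator config or input files must be given")
  structure(
    list(protocol = protocol, generator = generator, out_dir = out_dir,
         seed = as.integer(seed), analyses = analyses,
         input_records = input_records,
         duration = if (is.null(duration)) protocol_span(protocol) else duration,
         circuit = circuit),
    class = "run_config"
  )
}

#' Execute a pipeline run
#'
#' Stages: simulate (records, counts, trajectories) or load inputs;
#' classify trajectories; population fractions; transition matrices;
#' exponential fits; circuit comparison. Outputs are deterministic under a
#' fixed seed. Failures of individual stages are recorded in the manifest
#' and reported with a nonzero \code{n_failed}.
#'
#' @param config a \code{run_config}.
#' @param n_boot bootstrap resamples for the fit stage (default 1000).
#' @return the run manifest (list): \code{files} (data.frame path/md5),
#'   \code{seed}, \code{parameters}, \code{log}, \code{errors},
#'   \code{n_failed}. Also written as \code{manifest.json} in
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config, n_boot = 1000) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- character(0)
  errors <- list()
  emit <- function(msg) log <<- c(log, msg)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      emit(sprintf("stage %s FAILED: %s", name, conditionMessage(e)))
      NULL
    })
    res
  }
  pathto <- function(f) file.path(config$out_dir, f)

  # --- inputs ------------------------------------------------------------
  records <- NULL
  if (!is.null(config$input_records)) {
    records <- stage("load", read_records_csv(config$input_records))
    emit(sprintf("loaded records from %s", config$input_records))
  } else {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, 10)
    records <- stage("simulate", generate_response_records(gen, config$protocol))
    if (!is.null(records)) {
      write_records_csv(records, pathto("records.csv"))
      files <- c(files, pathto("records.csv"))
      emit(sprintf("simulated %d records (%d larvae)", nrow(records),
                   gen$n_larvae))
    }
    counts <- stage("simulate_counts",
                    generate_count_timeseries(gen, config$protocol,
                                              config$duration))
    if (!is.null(counts)) {
      utils::write.csv(as.data.frame(counts), pathto("counts.csv"),
                       row.names = FALSE, quote = FALSE)
      files <- c(files, pathto("counts.csv"))
    }
  }

  # --- classification round trip ----------------------------------------
  if ("classify" %in% config$analyses && !is.null(records)) {
    trajs <- stage("trajectories",
                   generate_trajectories(records, config$protocol,
                                         seed = derive_seed(config$seed, 11)))
    if (!is.null(trajs)) {
      write_trajectories_csv(trajs, pathto("trajectories.csv"))
      files <- c(files, pathto("trajectories.csv"))
      classified <- stage("classify",
                          classify_responses(trajs, config$protocol))
      if (!is.null(classified)) {
        write_records_csv(classified, pathto("classified.csv"))
        files <- c(files, pathto("classified.csv"))
        agree <- mean(as.character(classified$label) ==
                        as.character(records$label[
                          order(records$pulse_n, records$larva_id)]),
                      na.rm = TRUE)
        emit(sprintf("classifier round-trip agreement: %.4f", agree))
      }
    }
  }

  # --- population fractions ----------------------------------------------
  if ("fractions" %in% config$analyses && !is.null(records)) {
    fr <- stage("fractions", fractions_by_pulse(records))
    if (!is.null(fr)) {
      utils::write.csv(fr, pathto("fractions.csv"), row.names = FALSE,
                       quote = FALSE)
      files <- c(files, pathto("fractions.csv"))
    }
  }

  # --- transitions --------------------------------------------------------
  if ("transitions" %in% config$analyses && !is.null(records) &&
      config$protocol$n_pulses > 1) {
    tm <- stage("transitions", transition_matrix(records, lag = 1))
    if (!is.null(tm)) {
      write_transition_csv(tm, pathto("transitions_lag1.csv"))
      files <- c(files, pathto("transitions_lag1.csv"))
      emit(sprintf("lag-1 REV repeat: %.1f%% (%d transitions)",
                   tm$percent["REV", "REV"], tm$n_transitions))
    }
  }

  # --- exponential fit on the count series --------------------------------
  if ("fits" %in% config$analyses && is.null(config$input_records)) {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, 10)
    fitres <- stage("fits", {
      cont <- stimulus_protocol(config$protocol$frequency_hz,
                                config$protocol$gamma,
                                t_on = config$duration, t_off = 0,
                                n_pulses = 1)
      cts <- generate_count_timeseries(gen, cont, config$duration)
      fts <- as_fraction_timeseries(cts)
      sem <- binomial_sem(cts$n_rev, cts$n_active)
      fit_exponential(fts$t, fts$f_rev, sem, y0 = gen$baseline_rev,
                      n_boot = n_boot, seed = derive_seed(config$seed, 12))
    })
    if (!is.null(fitres)) {
      rep_json <- list(tau_s = fitres$tau, sd_tau_s = fitres$sd_tau,
                       amplitude = fitres$amplitude, y0 = fitres$y0,
                       n_boot = fitres$n_boot, seed = fitres$seed,
                       converged = fitres$converged)
      jsonlite::write_json(rep_json, pathto("fit_desensitization.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, pathto("fit_desensitization.json"))
      emit(sprintf("tau_des fit: %.2f +/- %.2f s", fitres$tau, fitres$sd_tau))
    }
  }

  # --- circuit -------------------------------------------------------------
  if ("circuit" %in% config$analyses) {
    circ <- stage("circuit", {
      par <- config$circuit
      run_circuit(list(V = par$V, C1 = par$C1, C2 = par$C2, R = par$R,
                       T_switch = par$T_switch, F0 = par$F0,
                       n_switches = max(config$protocol$n_pulses, 2),
                       dt = 1),
                  out = pathto("circuit.csv"))
    })
    if (!is.null(circ)) files <- c(files, pathto("circuit.csv"))
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("larvahab")),
    parameters = list(
      protocol = unclass(config$protocol),
      n_larvae = if (!is.null(config$generator)) config$generator$n_larvae,
      strain = if (!is.null(config$generator)) config$generator$strain_name,
      analyses = config$analyses),
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files)),
                       row.names = NULL),
    log = log,
    errors = errors,
    n_failed = length(errors)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest
}

#' Render a human-readable report from a run manifest
#'
#' Numbers are read back from the artifacts the manifest lists, so the
#' report always matches the files exactly; missing artifacts are listed
#' as absent, never fabricated.
#'
#' @param manifest a manifest list from [run_pipeline()], or the path to a
#'   \code{manifest.json}.
#' @return the report as a character vector of markdown lines.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  out <- c("# Pipeline run report", "",
           sprintf("Seed: %d. Stages failed: %d.", manifest$seed,
                   manifest$n_failed), "")
  paths <- if (is.data.frame(manifest$files)) manifest$files$path else
    character(0)
  if (length(paths) == 0) {
    out <- c(out, "No analyses were run.")
    return(out)
  }
  find_file <- function(suffix) {
    hit <- paths[endsWith(paths, suffix)]
    if (length(hit) == 1 && file.exists(hit)) hit else NULL
  }
  f <- find_file("fractions.csv")
  if (!is.null(f)) {
    fr <- utils::read.csv(f)
    out <- c(out, "## Response fractions by pulse", "",
             paste(capture_table(fr)), "")
  } else out <- c(out, "Response fractions: absent.", "")
  f <- find_file("fit_desensitization.json")
  if (!is.null(f)) {
    ft <- jsonlite::read_json(f, simplifyVector = TRUE)
    out <- c(out, "## De-sensitization fit", "",
             sprintf("tau_des = %s s (sd %s), amplitude %s, y0 %s",
                     format(ft$tau_s), format(ft$sd_tau_s),
                     format(ft$amplitude), format(ft$y0)), "")
  } else out <- c(out, "De-sensitization fit: absent.", "")
  f <- find_file("transitions_lag1.csv")
  if (!is.null(f)) {
    out <- c(out, "## Lag-1 transition matrix (row %)", "",
             readLines(f), "")
  } else out <- c(out, "Transition matrix: absent.", "")
  f <- find_file("circuit.csv")
  if (!is.null(f)) {
    circ <- utils::read.csv(f)
    out <- c(out, "## Circuit model", "",
             sprintf("%d time points; final Q2 = %s, final F = %s",
                     nrow(circ), format(circ$Q2[nrow(circ)]),
                     format(circ$F[nrow(circ)])), "")
  } else out <- c(out, "Circuit model: absent.", "")
  out
}

#' @noRd
capture_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}
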