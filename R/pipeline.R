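# Pipeline orchestration ----------------------------------------------------

.log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(...)))
}

#' Run configuration
#'
#' Assembles the configuration of a full run. Either a synthetic experiment
#' is simulated (`simulate = TRUE`, governed by `sim`) or existing inputs
#' are used (`reference` FASTA and `counts` TSV paths plus the dataset
#' grouping).
#'
#' @param outdir output directory (created if absent).
#' @param seed seed for the run (overrides `sim$seed`).
#' @param simulate simulate inputs instead of reading them?
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param reference,counts,annotation input paths (when `simulate = FALSE`).
#' @param sets a [dataset_set()]; defaults to the simulated one.
#' @param params a [caller_params()].
#' @param array a [ppr_array()] (default [ppr56()]).
#' @param profile_window offsets for the consensus profile.
#' @param max_shift shift window for shift classification.
#' @param scan_min_matches threshold for the candidate-site scan.
#' @return a list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, simulate = TRUE,
                       sim = sim_config(seed = seed), reference = NULL,
                       counts = NULL, annotation = NULL, sets = NULL,
                       params = caller_params(), array = ppr56(),
                       profile_window = -20:5, max_shift = 2L,
                       scan_min_matches = 7L) {
  if (!simulate) {
    for (p in c(reference, counts)) {
      if (is.null(p) || !file.exists(p)) {
        stop(sprintf("input file missing: %s",
                     if (is.null(p)) "(unset)" else p), call. = FALSE)
      }
    }
    if (is.null(sets)) stop("dataset grouping required", call. = FALSE)
  }
  structure(list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
                 sim = sim, reference = reference, counts = counts,
                 annotation = annotation, sets = sets, params = params,
                 array = array, profile_window = profile_window,
                 max_shift = max_shift, scan_min_matches = scan_min_matches),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Flat keys mirror the [run_config()] arguments; nested sections `sim`,
#' `params` and `sets` override the respective defaults field by field, and
#' `array` may name a motif-table file or give an inline array string.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  sim <- do.call(sim_config, c(list(seed = seed),
                               y$sim[names(y$sim) != "seed"]))
  params <- do.call(caller_params, as.list(y$params))
  sets <- if (!is.null(y$sets)) {
    dataset_set(y$sets$protein %||% "factor", y$sets$treatment, y$sets$control)
  } else NULL
  array <- if (is.null(y$array)) ppr56()
    else if (file.exists(y$array)) read_ppr_array(y$array)
    else parse_ppr_array(y$array)
  run_config(outdir = y$outdir %||% ".", seed = seed,
             simulate = isTRUE(y$simulate) || is.null(y$counts),
             sim = sim, reference = y$reference, counts = y$counts,
             annotation = y$annotation, sets = sets, params = params,
             array = array,
             profile_window = if (!is.null(y$profile_window))
               seq(y$profile_window[1], y$profile_window[2]) else -20:5,
             max_shift = y$max_shift %||% 2L,
             scan_min_matches = y$scan_min_matches %||% 7L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes simulate (optional) -> call -> profile -> scan and writes, under
#' `config$outdir`: `reference.fasta`, `counts.tsv` and `truth.tsv` (when
#' simulating), `offtargets.tsv`, `profile.tsv`, `scan.tsv` and
#' `report.yaml`. All stages are pure functions of the inputs, configuration
#' and seed, so a rerun with identical inputs reproduces identical outputs.
#'
#' @param config a [run_config()] or the path to a YAML configuration.
#' @return the run report (named list), invisibly: per-stage counts,
#'   per-filter rejections, and recovery statistics when ground truth is
#'   available.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  .log_msg("INFO", "stage input: %s",
           if (config$simulate) "simulating synthetic experiment" else "loading")
  truth <- NULL
  if (config$simulate) {
    xp <- simulate_experiment(config$sim, array = config$array)
    reference <- xp$reference; counts <- xp$counts; sets <- xp$sets
    truth <- xp$truth
    Biostrings::writeXStringSet(reference, file.path(config$outdir,
                                                     "reference.fasta"))
    write_site_counts(counts, file.path(config$outdir, "counts.tsv"))
    utils::write.table(truth, file.path(config$outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    reference <- Biostrings::readDNAStringSet(config$reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    counts <- read_site_counts(config$counts)
    sets <- config$sets
  }
  report$n_datasets <- length(unique(counts$dataset))
  report$n_count_rows <- nrow(counts)

  .log_msg("INFO", "stage call: %d count rows", nrow(counts))
  calls <- call_offtargets(counts, sets, config$params,
                           annotation = config$annotation,
                           reference = reference, array = config$array,
                           max_shift = config$max_shift,
                           window = config$profile_window)
  write_offtargets(calls, file.path(config$outdir, "offtargets.tsv"))
  report$n_called <- nrow(calls)
  report$rejections <- as.list(attr(calls, "rejections"))

  if (!is.null(truth)) {
    planted <- truth[!startsWith(truth$class, "decoy"), , drop = FALSE]
    decoys <- truth[startsWith(truth$class, "decoy"), , drop = FALSE]
    callkey <- paste(calls$contig, calls$position, calls$strand)
    report$n_planted <- nrow(planted)
    report$n_planted_called <- sum(paste(planted$contig, planted$position,
                                         planted$strand) %in% callkey)
    report$n_decoys_called <- sum(paste(decoys$contig, decoys$position,
                                        decoys$strand) %in% callkey)
    report$n_background_called <- report$n_called -
      report$n_planted_called - report$n_decoys_called
  }

  .log_msg("INFO", "stage profile: %d calls", nrow(calls))
  if (nrow(calls)) {
    parts <- exclude_shifted(calls, config$array, reference,
                             max_shift = config$max_shift,
                             window = config$profile_window)
    report$n_unshifted <- nrow(parts$unshifted)
    report$n_shifted <- nrow(parts$shifted)
    if (nrow(parts$unshifted)) {
      ctx <- lapply(seq_len(nrow(parts$unshifted)), function(i) {
        extract_context(reference, parts$unshifted$contig[i],
                        parts$unshifted$position[i],
                        parts$unshifted$strand[i],
                        window = config$profile_window)
      })
      prof <- build_profile(ctx, parts$unshifted$aggregate_efficiency,
                            window = config$profile_window)
      export_profile(prof, file.path(config$outdir, "profile.tsv"))
    }
  }

  .log_msg("INFO", "stage scan")
  scan <- scan_sequence(config$array, reference,
                        min_matches = config$scan_min_matches)
  utils::write.table(scan, file.path(config$outdir, "scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$n_scan_candidates <- nrow(scan)

  yaml::write_yaml(report, file.path(config$outdir, "report.yaml"))
  .log_msg("INFO", "done: %d off-targets called", report$n_called)
  invisible(report)
}
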