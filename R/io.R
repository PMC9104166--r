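#' Read and write office pollutant datasets
#'
#' The dataset dialect is a plain CSV: a mandatory header naming the nine
#' [iaq_pollutants] (extra columns, e.g. precomputed labels, are ignored on
#' read), one office per row, "." decimal, UTF-8. Validation is strict:
#' a missing pollutant column, or a non-numeric, missing or negative value,
#' is an error naming the row and column — screening data are never imputed.
#'
#' @param path CSV path.
#' @return `read_dataset()`: tibble with the nine pollutant columns.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(iaq_pollutants, names(raw))
  if (length(missing) > 0L) {
    stop("dataset ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw)[iaq_pollutants]
  for (col in iaq_pollutants) {
    x <- out[[col]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))) | is.na(x))[1]
      stop("non-numeric value at row ", bad, ", column ", col, call. = FALSE)
    }
    if (anyNA(x)) {
      stop("missing value at row ", which(is.na(x))[1], ", column ", col,
           call. = FALSE)
    }
    if (any(x < 0)) {
      stop("negative value at row ", which(x < 0)[1], ", column ", col,
           call. = FALSE)
    }
  }
  out
}

#' @rdname read_dataset
#' @param data Office records; a `label` column, if present, is written too.
#' @param sidecar Also write `<path>.yaml` capturing the generator config
#'   and seed when the data carry one (see [generate_offices()]).
#' @return `write_dataset()`: `path`, invisibly.
#' @export
write_dataset <- function(data, path, sidecar = TRUE) {
  keep <- intersect(c(iaq_pollutants, "label"), names(data))
  utils::write.csv(as.data.frame(data)[keep], path, row.names = FALSE)
  cfg <- attr(data, "config")
  if (sidecar && !is.null(cfg)) {
    side <- unclass(cfg)
    side$group_stats <- if (is.null(side$group_stats)) "default"
      else purrr::transpose(as.list(side$group_stats))
    side$scheme <- attr(data, "scheme")
    yaml::write_yaml(side, paste0(path, ".yaml"), precision = 15)
  }
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' One serialisable object from which an entire simulate / evaluate /
#' update-screening run is reproducible: the master seed (every stage draws
#' a documented sub-seed from it), the generator settings, the evaluation
#' design and the screening Monte-Carlo design.
#'
#' @param master_seed Integer master seed.
#' @param n_offices Synthetic survey size.
#' @param p_satisfactory,correlation,hidden_failure_fraction Generator
#'   knobs, see [generator_config()].
#' @param scheme Scheme generating the intended labels (1 or 2).
#' @param r_d,k,schemes Evaluation design factors
#'   ([evaluation_conditions()]).
#' @param algorithms Classifiers to compare.
#' @param grid_set `"reduced"` or `"full"` search space.
#' @param n_top Screening ensemble size per scheme.
#' @param n_mc,mc_ranges Monte-Carlo sample size and surrogate ranges.
#' @return List of class `iaq_run_config`.
#' @export
run_config <- function(master_seed = 1L,
                       n_offices = 2000L,
                       p_satisfactory = 358 / 525,
                       correlation = 0.3,
                       hidden_failure_fraction = NULL,
                       scheme = 1,
                       r_d = c(0.2, 0.3, 0.4, 0.5),
                       k = c(5L, 10L),
                       schemes = c("scheme1", "scheme2"),
                       algorithms = iaq_algorithms,
                       grid_set = "reduced",
                       n_top = 4L,
                       n_mc = 1e5,
                       mc_ranges = sampling_ranges()) {
  structure(list(master_seed = as.integer(master_seed),
                 n_offices = as.integer(n_offices),
                 p_satisfactory = p_satisfactory,
                 correlation = correlation,
                 hidden_failure_fraction = hidden_failure_fraction,
                 scheme = scheme, r_d = r_d, k = as.integer(k),
                 schemes = schemes, algorithms = algorithms,
                 grid_set = grid_set, n_top = as.integer(n_top),
                 n_mc = n_mc, mc_ranges = mc_ranges),
            class = "iaq_run_config")
}

#' @rdname run_config
#' @param path YAML path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$mc_ranges <- if (is.null(raw$mc_ranges)) sampling_ranges()
    else do.call(sampling_ranges, raw$mc_ranges)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config An `iaq_run_config`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$mc_ranges <- lapply(unclass(out$mc_ranges), as.numeric)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run the whole pipeline: simulate, evaluate, update the screening table
#'
#' Executes the three stages in order under one master seed and persists
#' every artifact to `out_dir`: the synthetic dataset (CSV + config
#' sidecar), the per-model evaluation results and best-model tally, the
#' updated screening table, the per-bin predicted-satisfaction percentages,
#' the resolved run config and a plain-text log. Two runs from the same
#' config are identical.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory (created if absent).
#' @param verbose Log progress to the console as well.
#' @return Invisibly, a list with the in-memory artifacts (`dataset`,
#'   `evaluation`, `tally`, `screening`) and `paths` to the files written.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "iaq_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("simulate: n=%d scheme=%s seed=%d", config$n_offices,
      format(resolve_scheme(config$scheme)),
      derive_seed(config$master_seed, 1L))
  dataset <- stage("simulate", generate_offices(
    n_offices = config$n_offices, scheme = config$scheme,
    p_satisfactory = config$p_satisfactory,
    correlation = config$correlation,
    hidden_failure_fraction = config$hidden_failure_fraction,
    seed = derive_seed(config$master_seed, 1L)))
  write_dataset(dataset, file.path(out_dir, "dataset.csv"))
  for (s in config$schemes) {
    bl <- baseline_accuracy(assess_iaq(dataset[iaq_pollutants], s)$label)
    say("baseline accuracy under %s: %.3f (mode %d of %d)", s,
        bl$baseline_accuracy, bl$mode_count, bl$n)
  }

  say("evaluate: %d conditions x %d algorithms, %s grids",
      length(config$r_d) * length(config$k) * length(config$schemes),
      length(config$algorithms), config$grid_set)
  evaluation <- stage("evaluate", run_evaluation(
    dataset[iaq_pollutants],
    conditions = evaluation_conditions(config$r_d, config$k,
                                       config$schemes),
    algorithms = config$algorithms, grid_set = config$grid_set,
    seed = derive_seed(config$master_seed, 2L),
    keep_models = TRUE, verbose = verbose))
  utils::write.csv(tidy(evaluation), file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  tally <- tally_best(evaluation)
  utils::write.csv(tally, file.path(out_dir, "tally.csv"),
                   row.names = FALSE)
  nbad <- sum(evaluation$below_baseline)
  say("evaluate: %d of %d result rows below baseline (unsatisfactory)",
      nbad, nrow(evaluation))

  say("update-screening: n=%g seed=%d ensemble of %d per scheme",
      config$n_mc, derive_seed(config$master_seed, 3L), config$n_top)
  screening <- stage("update-screening", {
    old <- select_top_models(evaluation, config$schemes[1], config$n_top)
    new <- select_top_models(evaluation,
                             config$schemes[min(2, length(config$schemes))],
                             config$n_top)
    update_screening(old, new, lr1 = default_lr1(),
                     ranges = config$mc_ranges, n = config$n_mc,
                     seed = derive_seed(config$master_seed, 3L))
  })
  utils::write.csv(screening$table, file.path(out_dir, "screening_table.csv"),
                   row.names = FALSE)
  utils::write.csv(screening$percentages,
                   file.path(out_dir, "bin_percentages.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(dataset = dataset, evaluation = evaluation, tally = tally,
                 screening = screening,
                 paths = file.path(out_dir,
                                   c("dataset.csv", "results.csv",
                                     "tally.csv", "screening_table.csv",
                                     "bin_percentages.csv", "config.yaml",
                                     "run.log"))))
}
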