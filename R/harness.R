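#' Min-max scaling fitted on training data
#'
#' Linear per-column scaling of the features to [0, 1], fitted on the
#' training table only and applied unchanged to any other table, so no test
#' information leaks into the scaler. Values outside the training range map
#' outside [0, 1] and are deliberately not clipped. A zero-range training
#' column carries no information and is mapped to 0 with a warning.
#'
#' @param train Data frame of numeric training features.
#' @param other Optional data frame to transform with the fitted scaler.
#' @return List with `train` (scaled tibble), `other` (scaled tibble or
#'   `NULL`) and `scaler` (class `iaq_scaler`, reusable via
#'   [apply_scaler()]).
#' @examples
#' s <- minmax_scale(data.frame(x = c(2, 4, 6)))
#' s$train$x                       # 0, 0.5, 1
#' apply_scaler(s$scaler, data.frame(x = 8))  # 1.5
#' @export
minmax_scale <- function(train, other = NULL) {
  train <- tibble::as_tibble(train)
  mins <- purrr::map_dbl(train, min)
  maxs <- purrr::map_dbl(train, max)
  rng <- maxs - mins
  if (any(rng == 0)) {
    warning("zero-range column(s) mapped to 0: ",
            paste(names(train)[rng == 0], collapse = ", "), call. = FALSE)
  }
  scaler <- structure(list(min = mins, range = rng), class = "iaq_scaler")
  list(train = apply_scaler(scaler, train),
       other = if (!is.null(other)) apply_scaler(scaler, other),
       scaler = scaler)
}

#' @rdname minmax_scale
#' @param scaler An `iaq_scaler`.
#' @param data Data frame with the scaler's columns.
#' @export
apply_scaler <- function(scaler, data) {
  stopifnot(inherits(scaler, "iaq_scaler"))
  data <- tibble::as_tibble(data)[names(scaler$min)]
  out <- purrr::imap(data, function(x, nm) {
    if (scaler$range[[nm]] == 0) rep(0, length(x))
    else (x - scaler$min[[nm]]) / scaler$range[[nm]]
  })
  tibble::as_tibble(out)
}

#' Seeded train/test split
#'
#' Randomly partitions the rows into a training fraction (1 - r_d) and a
#' testing fraction r_d, with |test| = round(r_d * N). If the draw leaves a
#' single-class training set the split is retried with an incremented
#' sub-seed (up to 100 times) before failing.
#'
#' @param data Data frame including a label column.
#' @param r_d Testing fraction, strictly between 0 and 1.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param label Name of the label column used for the class check.
#' @return List with tibbles `train` and `test`.
#' @export
split_data <- function(data, r_d, seed = 1L, label = "label") {
  stopifnot(r_d > 0, r_d < 1)
  n <- nrow(data)
  if (n < 10L) stop("dataset too small to split (n < 10)", call. = FALSE)
  n_test <- round(r_d * n)
  for (try in 0:99) {
    idx <- with_seed(derive_seed(seed, try), sample.int(n))
    test_idx <- idx[seq_len(n_test)]
    train <- tibble::as_tibble(data)[-sort(test_idx), ]
    test <- tibble::as_tibble(data)[sort(test_idx), ]
    if (!label %in% names(data) ||
        length(unique(train[[label]])) > 1L) {
      return(list(train = train, test = test))
    }
  }
  stop("could not produce a two-class training set in 100 attempts",
       call. = FALSE)
}

#' K-fold cross-validation accuracy of one model specification
#'
#' Partitions the training records into K seeded folds of near-equal size
#' (differing by at most one record), fits the spec on K-1 folds and scores
#' the held-out fold, and returns the mean held-out accuracy. A fold whose
#' training portion is single-class is skipped with a warning and the
#' effective number of folds is reported in the `"k_effective"` attribute.
#'
#' @param spec An [model_spec()].
#' @param features Scaled training features.
#' @param labels Training labels (two-level factor).
#' @param k Number of folds (>= 2).
#' @param seed Seed for the fold assignment and backend fits.
#' @return Mean held-out accuracy, with attribute `k_effective`.
#' @export
kfold_cv <- function(spec, features, labels, k = 5L, seed = 1L) {
  n <- nrow(features)
  stopifnot(k >= 2L, n >= k)
  fold <- with_seed(derive_seed(seed, 0L),
                    sample(rep(seq_len(k), length.out = n)))
  accs <- numeric(0)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) {
      warning("fold ", f, " skipped: single-class training portion",
              call. = FALSE)
      next
    }
    m <- fit_classifier(spec, features[tr, , drop = FALSE], labels[tr],
                        seed = derive_seed(seed, f))
    accs <- c(accs, model_accuracy(m, features[!tr, , drop = FALSE],
                                   labels[!tr]))
  }
  structure(mean(accs), k_effective = length(accs))
}

#' Grid search over a hyperparameter grid
#'
#' Evaluates every grid point by [kfold_cv()] on shared folds and returns
#' the point with the highest cross-validation accuracy; ties resolve to the
#' earliest point in the grid's deterministic enumeration order.
#'
#' @param algorithm One of [iaq_algorithms].
#' @param features,labels Scaled training features and labels.
#' @param k Folds for the inner cross-validation.
#' @param grid Tibble of grid points; default the algorithm's reduced grid.
#' @param seed Seed shared across grid points (same folds for all).
#' @return List with `spec` (winning [model_spec()]), `cv_accuracy`, and
#'   `results` (per-point tibble in grid order).
#' @export
grid_search <- function(algorithm, features, labels, k = 5L, grid = NULL,
                        seed = 1L) {
  grid <- grid %||% hyperparameter_grid(algorithm)
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  cv <- numeric(nrow(grid))
  failures <- character(0)
  for (i in seq_len(nrow(grid))) {
    spec <- row_to_spec(algorithm, grid[i, ])
    cv[i] <- tryCatch(as.numeric(kfold_cv(spec, features, labels, k, seed)),
                      error = function(e) {
                        failures <<- c(failures, conditionMessage(e))
                        NA_real_
                      })
  }
  if (all(is.na(cv))) {
    stop("all grid points failed: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  }
  best <- which.max(cv)  # NA-safe; earliest max wins
  list(spec = row_to_spec(algorithm, grid[best, ]),
       cv_accuracy = cv[best],
       results = dplyr::mutate(grid, cv_accuracy = cv))
}

#' Baseline (majority-class) accuracy
#'
#' The accuracy of always predicting the most frequent label: the mode count
#' over the sample size. A model scoring below this is worse than no model.
#'
#' @param labels Vector or factor of labels.
#' @return One-row tibble with `n`, `mode_count`, `baseline_accuracy`.
#' @examples
#' baseline_accuracy(rep(c("s", "u"), c(358, 167)))$baseline_accuracy
#' @export
baseline_accuracy <- function(labels) {
  if (length(labels) == 0L) stop("empty labels", call. = FALSE)
  tab <- table(labels)
  tibble::tibble(n = length(labels),
                 mode_count = as.integer(max(tab)),
                 baseline_accuracy = max(tab) / length(labels))
}

#' The factorial evaluation design
#'
#' Crosses the testing fraction r_d, the cross-validation fold count K and
#' the assessment scheme into the evaluation conditions; the full default
#' design is 4 x 2 x 2 = 16 conditions, and with a trained and a retrained
#' stage per condition, 32 result sets per algorithm.
#'
#' @param r_d Testing fractions.
#' @param k Fold counts.
#' @param schemes Scheme names/versions (resolved by [assess_iaq()]).
#' @return Tibble with `condition` id and the three factors.
#' @export
evaluation_conditions <- function(r_d = c(0.2, 0.3, 0.4, 0.5),
                                  k = c(5L, 10L),
                                  schemes = c("scheme1", "scheme2")) {
  g <- tidyr::expand_grid(scheme = schemes, k = as.integer(k), r_d = r_d)
  dplyr::mutate(g, condition = dplyr::row_number(), .before = 1)
}

#' Run the full model-comparison experiment
#'
#' For every evaluation condition: label the offices by the condition's
#' scheme, split off the test fraction, min-max scale on the training data,
#' then for every algorithm fit the untuned default spec ("trained" stage)
#' and the grid-search winner ("retrained" stage) and score both on the
#' held-out test set. Models scoring below the dataset's baseline accuracy
#' are flagged unsatisfactory. All randomness derives from `seed` via a
#' fixed counter scheme, so a run is reproducible end to end.
#'
#' @param data Office records (nine pollutant columns); labels are
#'   recomputed per condition's scheme.
#' @param conditions Design tibble from [evaluation_conditions()].
#' @param algorithms Algorithms to compare.
#' @param features Feature columns used by the classifiers (default the
#'   three surrogates).
#' @param grid_set `"reduced"` (default) or `"full"` search space.
#' @param grid_path Optional user grid config.
#' @param seed Master seed.
#' @param keep_models Retain every fitted model (with its scaler) in the
#'   `"models"` attribute, needed to drive [update_screening()].
#' @param verbose Print a line per condition.
#' @return Tibble of class `iaq_evaluation`: one row per condition x
#'   algorithm x stage with cv/test accuracies, the chosen hyperparameters
#'   (list-column), the baseline and a below-baseline flag.
#' @export
run_evaluation <- function(data,
                           conditions = evaluation_conditions(),
                           algorithms = iaq_algorithms,
                           features = iaq_surrogates,
                           grid_set = c("reduced", "full"),
                           grid_path = NULL,
                           seed = 1L,
                           keep_models = FALSE,
                           verbose = FALSE) {
  grid_set <- match.arg(grid_set)
  stopifnot(nrow(conditions) >= 1L, length(algorithms) >= 1L)
  grids <- purrr::map(stats::setNames(nm = algorithms),
                      function(a) hyperparameter_grid(a, grid_set, grid_path))
  defaults <- purrr::map(stats::setNames(nm = algorithms),
                         function(a) default_model_spec(a, grid_path))
  rows <- list()
  models <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    labelled <- assess_iaq(data, cond$scheme)
    bl <- baseline_accuracy(labelled$label)$baseline_accuracy
    parts <- split_data(labelled, cond$r_d,
                        seed = derive_seed(seed, ci))
    sc <- minmax_scale(parts$train[features], parts$test[features])
    y_tr <- parts$train$label
    y_te <- parts$test$label
    if (verbose) {
      message(sprintf("condition %d: scheme=%s K=%d r_d=%.1f baseline=%.3f",
                      cond$condition, cond$scheme, cond$k, cond$r_d, bl))
    }
    for (ai in seq_along(algorithms)) {
      alg <- algorithms[ai]
      fit_seed <- derive_seed(seed, ci * 1000L + ai)
      one_stage <- function(spec, stage, cv_acc) {
        m <- fit_classifier(spec, sc$train, y_tr, seed = fit_seed)
        acc <- model_accuracy(m, sc$other, y_te)
        if (keep_models) {
          key <- paste(cond$condition, alg, stage, sep = ".")
          models[[key]] <<- list(model = m, scaler = sc$scaler,
                                 condition = cond$condition,
                                 scheme = cond$scheme, algorithm = alg,
                                 stage = stage, test_accuracy = acc)
        }
        tibble::tibble(condition = cond$condition, scheme = cond$scheme,
                       k = cond$k, r_d = cond$r_d, algorithm = alg,
                       stage = stage, cv_accuracy = cv_acc,
                       test_accuracy = acc,
                       baseline = bl, below_baseline = acc < bl,
                       hyperparameters = list(spec$hyperparameters),
                       n_train = nrow(sc$train), n_test = nrow(sc$other))
      }
      cv_tr <- as.numeric(kfold_cv(defaults[[alg]], sc$train, y_tr,
                                   k = cond$k, seed = fit_seed))
      rows <- c(rows, list(one_stage(defaults[[alg]], "trained", cv_tr)))
      gs <- grid_search(alg, sc$train, y_tr, k = cond$k,
                        grid = grids[[alg]], seed = fit_seed)
      rows <- c(rows, list(one_stage(gs$spec, "retrained", gs$cv_accuracy)))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iaq_evaluation", class(out))
  attr(out, "seed") <- seed
  if (keep_models) attr(out, "models") <- models
  out
}

#' Tally the most accurate classifier per design cell
#'
#' For each (condition, stage) cell, credits the algorithm(s) with the
#' highest test accuracy — ties credit every tied algorithm — and reports
#' per-algorithm win counts and the mean test accuracy of the winning
#' entries, per stage and combined.
#'
#' @param results An `iaq_evaluation` tibble.
#' @return Tibble with one row per algorithm: `trained_count`,
#'   `trained_accuracy`, `retrained_count`, `retrained_accuracy`,
#'   `combined_count`, `combined_accuracy`.
#' @export
tally_best <- function(results) {
  wins <- results |>
    dplyr::group_by(.data$condition, .data$stage) |>
    dplyr::filter(.data$test_accuracy == max(.data$test_accuracy)) |>
    dplyr::ungroup()
  per_stage <- wins |>
    dplyr::group_by(.data$algorithm, .data$stage) |>
    dplyr::summarise(count = dplyr::n(),
                     accuracy = mean(.data$test_accuracy),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "stage",
                       values_from = c("count", "accuracy"),
                       names_glue = "{stage}_{.value}")
  combined <- wins |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(combined_count = dplyr::n(),
                     combined_accuracy = mean(.data$test_accuracy),
                     .groups = "drop")
  out <- tibble::tibble(algorithm = unique(results$algorithm)) |>
    dplyr::left_join(per_stage, by = "algorithm") |>
    dplyr::left_join(combined, by = "algorithm")
  for (col in c("trained_count", "retrained_count", "combined_count")) {
    if (!col %in% names(out)) out[[col]] <- NA_integer_
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out
}

#' @exportS3Method generics::glance
glance.iaq_evaluation <- function(x, ...) {
  tibble::tibble(
    n_conditions = dplyr::n_distinct(x$condition),
    n_algorithms = dplyr::n_distinct(x$algorithm),
    n_result_sets = dplyr::n_distinct(paste(x$condition, x$stage)),
    mean_test_accuracy = mean(x$test_accuracy),
    max_test_accuracy = max(x$test_accuracy),
    frac_below_baseline = mean(x$below_baseline)
  )
}

#' @exportS3Method generics::tidy
tidy.iaq_evaluation <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$hyperparameters <- purrr::map_chr(
    out$hyperparameters,
    function(h) paste(names(h), purrr::map_chr(h, paste, collapse = ":"),
                      sep = "=", collapse = ", "))
  out
}
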