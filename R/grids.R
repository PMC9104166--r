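grid_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "grids.yaml",
                                package = "iaqscreen")
  yaml::read_yaml(path)
}

expand_grid_dims <- function(dims) {
  # first listed dimension varies fastest; value order as listed
  g <- do.call(expand.grid,
               c(purrr::map(dims, function(v) unlist(v)),
                 list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  tibble::as_tibble(g)
}

#' Hyperparameter grids for the nine algorithms
#'
#' Grid domains ship in a structured config (`extdata/grids.yaml`) with two
#' named sets: `"full"` spans the published test ranges (e.g. SVM C from 0.1
#' to 10,000, kNN k = 2..11, tree depth 3..14, Gini or entropy impurity, the
#' MLP activation/solver/schedule cross-product); `"reduced"` is a small
#' deterministic subset used as the default search space of
#' [run_evaluation()]. Enumeration order is fixed — the first listed
#' dimension varies fastest — so ties in a grid search resolve
#' reproducibly.
#'
#' @param algorithm One of [iaq_algorithms], or `NULL` for all.
#' @param set `"reduced"` or `"full"`.
#' @param path Optional path to a user grid config with the same YAML
#'   structure.
#' @return A tibble of grid points (one row per candidate spec), or a named
#'   list of such tibbles when `algorithm` is `NULL`.
#' @examples
#' hyperparameter_grid("knn")
#' nrow(hyperparameter_grid("decision_tree", set = "full"))
#' @export
hyperparameter_grid <- function(algorithm = NULL,
                                set = c("reduced", "full"),
                                path = NULL) {
  set <- match.arg(set)
  cfg <- grid_config(path)
  if (is.null(algorithm)) {
    return(purrr::map(stats::setNames(nm = iaq_algorithms),
                      function(a) expand_grid_dims(cfg[[a]][[set]])))
  }
  algorithm <- match.arg(algorithm, iaq_algorithms)
  expand_grid_dims(cfg[[algorithm]][[set]])
}

#' Untuned ("trained"-stage) model specifications
#'
#' The default hyperparameters fitted before any grid search, shipped in the
#' grid config. They follow the illustrative single values quoted alongside
#' the published test ranges and are defaults, not tuned winners.
#'
#' @param algorithm One of [iaq_algorithms], or `NULL` for all.
#' @param path Optional user grid config.
#' @return An [model_spec()], or a named list of them.
#' @export
default_model_spec <- function(algorithm = NULL, path = NULL) {
  cfg <- grid_config(path)
  build <- function(a) do.call(model_spec, c(list(a), cfg[[a]]$default))
  if (is.null(algorithm)) {
    return(purrr::map(stats::setNames(nm = iaq_algorithms), build))
  }
  build(match.arg(algorithm, iaq_algorithms))
}

#' Enumerated MLP architectures
#'
#' A deterministic cross-product of the evaluated MLP design space — total
#' hidden neurons (100, 200), layer ratios (1), (1:8:1), (1:4:4:1),
#' (1:2:2:2:2:1), four activations, three iteration schemes and three
#' learning-rate schedules — truncated to the first `n` rows in grid order.
#' The published study tabulated 60 such configurations without printing
#' them; this enumeration is the package's own reconstruction of that
#' design, not a copy of it.
#'
#' @param n Number of configurations to keep.
#' @param path Optional user grid config.
#' @return Tibble of MLP grid points.
#' @export
mlp_configurations <- function(n = 60, path = NULL) {
  cfg <- grid_config(path)$mlp$full
  cfg$C <- NULL
  g <- expand_grid_dims(cfg)
  utils::head(g, n)
}

# one grid-point row -> model spec
row_to_spec <- function(algorithm, row) {
  do.call(model_spec, c(list(algorithm), as.list(row)))
}
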