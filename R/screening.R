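#' Uniform sampling ranges of the surrogate space
#'
#' The rectangular region of surrogate space explored by the Monte-Carlo
#' update, covering the observable office range: CO2 400-1400 ppm, RSP
#' 1-120 ug/m3, TVOC 0-1500 ug/m3.
#'
#' @param co2,rsp,tvoc Length-2 numeric intervals (lower, upper).
#' @return List of class `iaq_ranges`.
#' @export
sampling_ranges <- function(co2 = c(400, 1400), rsp = c(1, 120),
                            tvoc = c(0, 1500)) {
  rng <- list(co2 = co2, rsp = rsp, tvoc = tvoc)
  ok <- purrr::map_lgl(rng, function(r) length(r) == 2 && r[1] < r[2])
  if (!all(ok)) stop("each range must satisfy lower < upper", call. = FALSE)
  structure(rng, class = "iaq_ranges")
}

#' Monte-Carlo sample of surrogate triples
#'
#' Draws independent uniform samples of the three surrogates over the given
#' ranges; the resulting triples (and their IAQ indices) probe how the
#' fitted classifiers partition surrogate space, without reference to any
#' particular office population.
#'
#' @param n Number of triples.
#' @param ranges A [sampling_ranges()].
#' @param seed Integer seed.
#' @return Tibble with columns `co2`, `rsp`, `tvoc`.
#' @export
monte_carlo_sample <- function(n = 1e5, ranges = sampling_ranges(),
                               seed = 0L) {
  stopifnot(n >= 1)
  if (!inherits(ranges, "iaq_ranges")) ranges <- do.call(sampling_ranges, ranges)
  with_seed(seed, tibble::tibble(
    co2 = stats::runif(n, ranges$co2[1], ranges$co2[2]),
    rsp = stats::runif(n, ranges$rsp[1], ranges$rsp[2]),
    tvoc = stats::runif(n, ranges$tvoc[1], ranges$tvoc[2])
  ))
}

#' Model-averaged satisfaction prediction
#'
#' Scores each surrogate triple with every model in an ensemble (each model
#' carries its own training scaler) and returns the fraction of models
#' predicting satisfactory plus the majority label; an exact tie is labelled
#' unsatisfactory, the conservative screening outcome.
#'
#' @param models List of entries with elements `model` (an `iaq_model`) and
#'   `scaler` (its `iaq_scaler`), e.g. from [select_top_models()].
#' @param triples Tibble of surrogate triples.
#' @return Tibble `fraction_satisfactory`, `label` (factor), one row per
#'   triple.
#' @export
model_average_predict <- function(models, triples) {
  stopifnot(length(models) >= 1L)
  votes <- purrr::map(models, function(m) {
    if (is.null(m$model) || is.null(m$scaler)) {
      stop("each ensemble entry needs `model` and `scaler`", call. = FALSE)
    }
    x <- apply_scaler(m$scaler, triples)
    as.integer(predict(m$model, x) == "satisfactory")
  })
  frac <- Reduce(`+`, votes) / length(votes)
  tibble::tibble(
    fraction_satisfactory = frac,
    label = factor(ifelse(frac > 0.5, "satisfactory", "unsatisfactory"),
                   levels = c("satisfactory", "unsatisfactory")))
}

#' Select the best models of an evaluation for the screening ensemble
#'
#' Picks the `n_top` algorithms with the highest test accuracy (across the
#' trained and retrained stages, one entry per algorithm) among the
#' conditions labelled with `scheme`, from an evaluation run with
#' `keep_models = TRUE`.
#'
#' @param results An `iaq_evaluation` from [run_evaluation()].
#' @param scheme Scheme name, e.g. `"scheme1"`.
#' @param n_top Ensemble size.
#' @return List of `list(model, scaler, ...)` entries.
#' @export
select_top_models <- function(results, scheme, n_top = 4L) {
  models <- attr(results, "models")
  if (is.null(models)) {
    stop("run_evaluation() must be called with keep_models = TRUE",
         call. = FALSE)
  }
  cand <- results |>
    dplyr::filter(.data$scheme == !!scheme) |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::slice_max(.data$test_accuracy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$test_accuracy)) |>
    utils::head(n_top)
  purrr::pmap(cand[c("condition", "algorithm", "stage")],
              function(condition, algorithm, stage)
                models[[paste(condition, algorithm, stage, sep = ".")]])
}

#' Screening bins of the IAQ index
#'
#' The five screening classes of the office likelihood-ratio table. The
#' published labels (<0.32, 0.32-0.42, 0.43-0.53, 0.54-0.64, >=0.65) carry
#' gaps that reflect two-decimal rounding of theta; internally the bins are
#' contiguous half-open intervals on raw theta whose edges (0.315, 0.425,
#' 0.535, 0.645) reproduce those labels under round-to-2-dp, so every index
#' value falls in exactly one bin.
#'
#' @return Tibble with `bin` (label), `lower`, `upper`.
#' @export
theta_bins <- function() {
  tibble::tibble(
    bin = c("<0.32", "0.32-0.42", "0.43-0.53", "0.54-0.64", ">=0.65"),
    lower = c(0, 0.315, 0.425, 0.535, 0.645),
    upper = c(0.315, 0.425, 0.535, 0.645, Inf))
}

#' Bundled Scheme-1 likelihood-ratio table
#'
#' The established five-level screening table for air-conditioned offices
#' under the old Hong Kong objective: LR below 1 in the low-index bins and
#' 25 in the top bin. Ships as `extdata/lr1_table.csv`.
#'
#' @return Tibble with `bin` and `lr1`.
#' @export
default_lr1 <- function() {
  path <- system.file("extdata", "lr1_table.csv", package = "iaqscreen")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

assign_bins <- function(theta, bins = theta_bins()) {
  cut(theta, breaks = c(bins$lower, Inf)[seq_len(nrow(bins) + 1L)],
      labels = bins$bin, right = FALSE, include.lowest = TRUE)
}

#' Per-bin predicted satisfaction percentages
#'
#' Tabulates, for each index bin, the percentage of triples predicted
#' satisfactory and unsatisfactory (summing to 100 within each non-empty
#' bin); empty bins are reported with missing percentages.
#'
#' @param theta IAQ index values.
#' @param labels Predicted labels (factor with levels satisfactory,
#'   unsatisfactory).
#' @param bins Bin table as from [theta_bins()].
#' @return Tibble `bin`, `n`, `pct_satisfactory`, `pct_unsatisfactory`.
#' @export
bin_percentages <- function(theta, labels, bins = theta_bins()) {
  b <- assign_bins(theta, bins)
  tab <- table(b, factor(as.character(labels),
                         levels = c("satisfactory", "unsatisfactory")))
  n <- rowSums(tab)
  out <- tibble::tibble(
    bin = rownames(tab),
    n = as.integer(n),
    pct_satisfactory = ifelse(n > 0, 100 * tab[, 1] / n, NA_real_),
    pct_unsatisfactory = ifelse(n > 0, 100 * tab[, 2] / n, NA_real_))
  if (any(out$n == 0L)) {
    warning("empty bin(s): ", paste(out$bin[out$n == 0], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Fit per-group normal distributions to the IAQ index
#'
#' Interprets the group-wise sample mean and standard deviation of theta as
#' normal parameters (the screening model's normality assumption) and logs
#' the studentized-range statistic u = (max - min)/s of each group — the
#' classic quick normality check; values outside the tabulated band suggest
#' the assumption is strained, which downgrades to a warning because the
#' screening procedure proceeds under normality regardless.
#'
#' @param theta IAQ index values.
#' @param labels Group labels (satisfactory/unsatisfactory).
#' @param u_bounds Acceptable band for the u statistic. The default
#'   `"auto"` widens with the group size n (upper bound
#'   `2 * qnorm(1 - 1/(2n)) + 1.5`, tracking the expected range of a normal
#'   sample); a length-2 numeric fixes the band; `NULL` skips the check.
#' @return Tibble of class `iaq_group_dists`: `group`, `n`, `mean`, `sd`,
#'   `u_stat`.
#' @export
fit_index_distributions <- function(theta, labels, u_bounds = "auto") {
  labels <- factor(as.character(labels),
                   levels = c("satisfactory", "unsatisfactory"))
  out <- purrr::map_dfr(levels(labels), function(g) {
    x <- theta[labels == g]
    if (length(x) < 2L) {
      stop("group '", g, "' has fewer than 2 samples", call. = FALSE)
    }
    s <- stats::sd(x)
    if (s == 0) stop("group '", g, "' has zero variance", call. = FALSE)
    tibble::tibble(group = g, n = length(x), mean = mean(x), sd = s,
                   u_stat = (max(x) - min(x)) / s)
  })
  if (!is.null(u_bounds)) {
    lo <- if (identical(u_bounds, "auto")) rep(2, nrow(out))
          else rep(u_bounds[1], nrow(out))
    hi <- if (identical(u_bounds, "auto"))
            2 * stats::qnorm(1 - 1 / (2 * out$n)) + 1.5
          else rep(u_bounds[2], nrow(out))
    off <- out$u_stat < lo | out$u_stat > hi
    if (any(off)) {
      warning("studentized-range statistic outside [",
              paste0(round(lo[off], 2), ", ", round(hi[off], 2),
                     collapse = "; "), "] for group(s): ",
              paste(out$group[off], collapse = ", "),
              " - normality assumption strained", call. = FALSE)
    }
  }
  class(out) <- c("iaq_group_dists", class(out))
  out
}

#' Likelihood ratio of an index bin
#'
#' The ratio of the unsatisfactory group's probability mass in the bin to
#' the satisfactory group's mass, each computed from the fitted normal via
#' its cumulative distribution. Over the whole axis both masses are 1, so
#' the all-bin LR is exactly 1; a satisfactory-group mass below 1e-12 yields
#' `Inf` (flagged, not an error).
#'
#' @param bins Bin table ([theta_bins()] format) or a single bin row.
#' @param dists An `iaq_group_dists` from [fit_index_distributions()].
#' @return Tibble `bin`, `mass_satisfactory`, `mass_unsatisfactory`, `lr`.
#' @export
likelihood_ratio <- function(bins, dists) {
  d <- as.data.frame(dists)
  ms <- d[d$group == "satisfactory", ]
  mu <- d[d$group == "unsatisfactory", ]
  mass <- function(m, s) {
    stats::pnorm(bins$upper, m, s) - stats::pnorm(bins$lower, m, s)
  }
  p_s <- mass(ms$mean, ms$sd)
  p_u <- mass(mu$mean, mu$sd)
  tibble::tibble(bin = bins$bin,
                 mass_satisfactory = p_s,
                 mass_unsatisfactory = p_u,
                 lr = ifelse(p_s < 1e-12, Inf, p_u / p_s))
}

#' Relative impact of an updated scheme on the screening LRs
#'
#' The per-bin factor by which the likelihood ratio changes when the
#' assessment scheme is updated: r = LR(new) / LR(old). Bins where either LR
#' is zero, infinite or missing are flagged with `NA`.
#'
#' @param lr_new,lr_old Per-bin LR tables (`bin`, `lr`) on matching bins.
#' @return Tibble `bin`, `lr_old`, `lr_new`, `impact`.
#' @export
relative_impact <- function(lr_new, lr_old) {
  if (!identical(lr_new$bin, lr_old$bin)) {
    stop("bin labels do not match", call. = FALSE)
  }
  bad <- !is.finite(lr_new$lr) | !is.finite(lr_old$lr) | lr_old$lr == 0 |
    lr_new$lr == 0
  if (any(bad)) {
    warning("undefined impact in bin(s): ",
            paste(lr_new$bin[bad], collapse = ", "), call. = FALSE)
  }
  impact <- ifelse(bad, NA_real_, lr_new$lr / lr_old$lr)
  tibble::tibble(bin = lr_new$bin, lr_old = lr_old$lr, lr_new = lr_new$lr,
                 impact = impact)
}

display_lr <- function(x) {
  ifelse(x < 10, round_half_up(x, 1), round_half_up(x, 0))
}

#' Update a screening likelihood-ratio table
#'
#' Applies per-bin relative impact ratios to an established LR table:
#' LR2 = r * LR1, stored unrounded alongside the display value (one decimal
#' below 10, whole numbers at 10 and above, round-half-up).
#'
#' @param lr1 Tibble `bin`, `lr1` (e.g. [default_lr1()]).
#' @param impacts Tibble with `bin` and `impact` ([relative_impact()]
#'   output), or a bare numeric vector of per-bin ratios.
#' @return Tibble of class `iaq_screening_table`: `bin`, `lr1`, `impact`,
#'   `lr2`, `lr2_display`.
#' @examples
#' update_screening_table(default_lr1(), c(1.4, 1.2, 1.1, 1.3, 1.5))
#' @export
update_screening_table <- function(lr1, impacts) {
  if (is.numeric(impacts)) {
    impacts <- tibble::tibble(bin = lr1$bin, impact = impacts)
  }
  if (!identical(lr1$bin, impacts$bin)) {
    stop("bin labels do not match", call. = FALSE)
  }
  lr1_vals <- lr1$lr1
  out <- tibble::tibble(bin = lr1$bin, lr1 = lr1_vals,
                        impact = impacts$impact,
                        lr2 = lr1_vals * impacts$impact)
  out$lr2_display <- display_lr(out$lr2)
  class(out) <- c("iaq_screening_table", class(out))
  out
}

#' Post-test probability of unsatisfactory IAQ
#'
#' Standard diagnostic-test odds algebra: the pre-test odds are multiplied
#' by the bin's likelihood ratio and converted back to a probability. With
#' LR = 1 the probability is unchanged; a degenerate pre-test probability of
#' 0 or 1 is returned unchanged with a warning.
#'
#' @param pre_p Pre-test probability (e.g. the regional failure rate).
#' @param lr Likelihood ratio(s) of the observed index bin.
#' @return Post-test probability, same length as `lr`.
#' @examples
#' post_test_probability(0.5, 3)  # 0.75
#' @export
post_test_probability <- function(pre_p, lr) {
  stopifnot(pre_p >= 0, pre_p <= 1, all(lr >= 0))
  if (pre_p %in% c(0, 1)) {
    warning("degenerate pre-test probability returned unchanged",
            call. = FALSE)
    return(rep(pre_p, length(lr)))
  }
  odds <- lr * pre_p / (1 - pre_p)
  ifelse(is.infinite(odds), 1, odds / (1 + odds))
}

#' Monte-Carlo update of the screening table for a new scheme
#'
#' The full screening-update procedure: sample surrogate space uniformly,
#' compute the IAQ index of every triple (Scheme-1 reference limits, as
#' always), predict satisfaction with a model ensemble per scheme, fit
#' normal index distributions to each scheme's predicted groups, form
#' per-bin likelihood ratios from the normal masses, take their per-bin
#' ratio as the relative impact of the new scheme, and apply it to the
#' established Scheme-1 table. Running it with the *same* ensemble for both
#' schemes (and one seed) returns impact 1 in every bin.
#'
#' @param models_old,models_new Ensembles (see [model_average_predict()])
#'   trained under the old and new scheme.
#' @param lr1 Established LR table for the old scheme ([default_lr1()]).
#' @param bins Screening bins.
#' @param ranges,n,seed Monte-Carlo design ([monte_carlo_sample()]).
#' @param reference Reference scheme for the index (Scheme 1 by convention).
#' @return List of class `iaq_screening_update`: `table` (the updated
#'   `iaq_screening_table`), `percentages` (per-scheme per-bin predicted
#'   satisfaction), `distributions` (per-scheme fitted normals), `lr`
#'   (per-scheme model-based LR tables) and the sampling design.
#' @export
update_screening <- function(models_old, models_new, lr1 = default_lr1(),
                             bins = theta_bins(),
                             ranges = sampling_ranges(), n = 1e5,
                             seed = 0L, reference = scheme_hk(1)) {
  triples <- monte_carlo_sample(n, ranges, seed)
  theta <- iaq_index(triples, reference = reference)$theta
  one <- function(models) {
    pred <- model_average_predict(models, triples)
    dists <- fit_index_distributions(theta, pred$label)
    list(pred = pred,
         dists = dists,
         pct = bin_percentages(theta, pred$label, bins),
         lr = likelihood_ratio(bins, dists))
  }
  old <- one(models_old)
  # identical ensembles vote identically on the shared sample: reuse, so the
  # self-consistency impact of 1 is exact rather than numerical
  new <- if (identical(models_old, models_new)) old else one(models_new)
  imp <- relative_impact(new$lr, old$lr)
  structure(list(
    table = update_screening_table(lr1, imp),
    impacts = imp,
    percentages = dplyr::bind_rows(
      dplyr::mutate(old$pct, scheme = "old", .before = 1),
      dplyr::mutate(new$pct, scheme = "new", .before = 1)),
    distributions = dplyr::bind_rows(
      dplyr::mutate(old$dists, scheme = "old", .before = 1),
      dplyr::mutate(new$dists, scheme = "new", .before = 1)),
    lr = list(old = old$lr, new = new$lr),
    n = n, seed = seed, ranges = ranges, bins = bins),
    class = "iaq_screening_update")
}

#' @export
print.iaq_screening_update <- function(x, ...) {
  cat("<iaq_screening_update> n =", format(x$n, big.mark = ","),
      "Monte-Carlo triples, seed", x$seed, "\n")
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.iaq_screening_update <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' @exportS3Method generics::glance
glance.iaq_screening_update <- function(x, ...) {
  tibble::tibble(n_samples = x$n, seed = x$seed,
                 n_bins = nrow(x$table),
                 min_impact = min(x$table$impact, na.rm = TRUE),
                 max_impact = max(x$table$impact, na.rm = TRUE))
}
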