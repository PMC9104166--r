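test_that("min-max scaling maps the training range to [0,1] without clipping", {
  s <- minmax_scale(data.frame(x = c(2, 4, 6)))
  expect_equal(s$train$x, c(0, 0.5, 1))
  expect_equal(apply_scaler(s$scaler, data.frame(x = 8))$x, 1.5)
  # refitting on already scaled output is the identity map
  s2 <- minmax_scale(s$train)
  expect_equal(s2$train, s$train)
  expect_warning(z <- minmax_scale(data.frame(x = c(3, 3, 3))), "zero-range")
  expect_equal(z$train$x, c(0, 0, 0))
})

test_that("splits are seeded, disjoint, exhaustive and correctly sized", {
  d <- small_survey(525, seed = 19)
  sp <- split_data(d, 0.4, seed = 2)
  expect_equal(nrow(sp$test), 210L)
  expect_equal(nrow(sp$train), 315L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(d))
  key <- function(x) paste(x$co2, x$rsp, x$tvoc)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(d))
  sp2 <- split_data(d, 0.4, seed = 2)
  expect_identical(sp, sp2)
  even <- split_data(d[1:100, ], 0.5, seed = 3)
  expect_equal(nrow(even$train), nrow(even$test))
})

test_that("cross-validation scores a perfect classifier at 1", {
  fx <- separable_set(100, seed = 30)
  cv <- kfold_cv(model_spec("decision_tree", D = 8, n_s = 2, n_r = 1),
                 fx$x, fx$y, k = 5, seed = 1)
  expect_equal(as.numeric(cv), 1)
  expect_equal(attr(cv, "k_effective"), 5L)
})

test_that("cross-validation of a near-majority rule sits near the baseline", {
  d <- small_survey(400, seed = 33)
  sc <- minmax_scale(d[iaq_surrogates])
  # k as large as the fold's training portion approximates majority voting
  cv <- kfold_cv(model_spec("knn", k = 300, weight = "uniform"),
                 sc$train, d$label, k = 5, seed = 2)
  bl <- baseline_accuracy(d$label)$baseline_accuracy
  expect_lt(abs(as.numeric(cv) - bl), 0.05)
})

test_that("grid search returns the cross-validation argmax, reproducibly", {
  d <- small_survey(200, seed = 44)
  sc <- minmax_scale(d[iaq_surrogates])
  single <- tibble::tibble(C = 1)
  gs1 <- grid_search("svm_rbf", sc$train, d$label, k = 5, grid = single,
                     seed = 6)
  expect_equal(gs1$spec$hyperparameters$C, 1)
  grid3 <- tibble::tibble(k = c(2L, 5L, 9L), weight = "uniform")
  gs <- grid_search("knn", sc$train, d$label, k = 5, grid = grid3, seed = 6)
  expect_true(all(gs$cv_accuracy >= gs$results$cv_accuracy))
  # brute-force re-evaluation of each point reproduces the same winner
  brute <- purrr::map_dbl(seq_len(3), function(i) {
    spec <- model_spec("knn", k = grid3$k[i], weight = "uniform")
    as.numeric(kfold_cv(spec, sc$train, d$label, k = 5, seed = 6))
  })
  expect_equal(gs$spec$hyperparameters$k, grid3$k[which.max(brute)])
  # when the default spec is in the grid, tuning can only help the cv score
  dflt <- default_model_spec("knn")$hyperparameters
  grid_with_default <- dplyr::bind_rows(
    tibble::tibble(k = as.integer(dflt$k), weight = dflt$weight), grid3)
  gs2 <- grid_search("knn", sc$train, d$label, k = 5,
                     grid = grid_with_default, seed = 6)
  cv_default <- as.numeric(kfold_cv(model_spec("knn", k = dflt$k,
                                               weight = dflt$weight),
                                    sc$train, d$label, k = 5, seed = 6))
  expect_gte(gs2$cv_accuracy, cv_default)
})

test_that("baseline accuracy is the majority fraction", {
  expect_equal(round(baseline_accuracy(
    rep(c("s", "u"), c(358, 167)))$baseline_accuracy, 3), 0.682)
  expect_equal(round(baseline_accuracy(
    rep(c("s", "u"), c(352, 173)))$baseline_accuracy, 3), 0.670)
  expect_equal(baseline_accuracy(rep("s", 9))$baseline_accuracy, 1)
  expect_error(baseline_accuracy(character()), "empty")
})

test_that("the full design enumerates 4 x 2 x 2 = 16 distinct conditions", {
  cond <- evaluation_conditions()
  expect_equal(nrow(cond), 16L)
  expect_equal(nrow(dplyr::distinct(cond[c("r_d", "k", "scheme")])), 16L)
})

test_that("one condition yields a trained and a retrained result per model", {
  d <- small_survey(250, seed = 50)
  ev <- run_evaluation(
    d[iaq_pollutants],
    conditions = evaluation_conditions(r_d = 0.3, k = 5,
                                       schemes = "scheme1"),
    algorithms = c("decision_tree", "logistic"), seed = 4)
  expect_equal(nrow(ev), 4L)
  expect_setequal(ev$stage, c("trained", "retrained"))
  expect_true(all(ev$test_accuracy >= 0 & ev$test_accuracy <= 1))
  expect_equal(unique(ev$n_train + ev$n_test), 250L)
  expect_identical(ev$below_baseline, ev$test_accuracy < ev$baseline)
  g <- glance(ev)
  expect_equal(g$n_result_sets, 2L)
})

test_that("the best-model tally credits argmaxes and all ties", {
  fake <- tibble::tibble(
    condition = rep(1:2, each = 3),
    stage = "trained",
    algorithm = rep(c("a", "b", "c"), 2),
    test_accuracy = c(0.9, 0.8, 0.7, 0.9, 0.9, 0.5))
  t <- tally_best(fake)
  expect_equal(t$combined_count[t$algorithm == "a"], 2L)
  expect_equal(t$combined_count[t$algorithm == "b"], 1L)  # tie in cell 2
  expect_equal(t$combined_count[t$algorithm == "c"], 0L)
  expect_equal(t$trained_accuracy[t$algorithm == "a"], 0.9)
  expect_gte(sum(t$combined_count), 2L)
})
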