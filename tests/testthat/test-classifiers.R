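test_that("neuron allocation is proportional, exact and deterministic", {
  expect_identical(allocate_neurons(100, c(1, 8, 1)), c(10L, 80L, 10L))
  expect_identical(allocate_neurons(200, c(1, 4, 4, 1)),
                   c(20L, 80L, 80L, 20L))
  expect_identical(allocate_neurons(100, 1), 100L)
  expect_error(allocate_neurons(3, c(1, 2, 2, 2, 2, 1)), "fewer than layers")
  # remainder lands in the first layer and the total is always preserved
  for (total in c(7, 100, 200)) {
    for (ratio in list(1, c(1, 8, 1), c(1, 4, 4, 1), c(1, 2, 2, 2, 2, 1))) {
      if (total < length(ratio)) next
      expect_equal(sum(allocate_neurons(total, ratio)), total)
    }
  }
})

test_that("grids enumerate deterministically over the published ranges", {
  expect_identical(hyperparameter_grid("knn", "full"),
                   hyperparameter_grid("knn", "full"))
  expect_equal(nrow(hyperparameter_grid("knn", "full")), 20L)  # 10 k x 2 W
  expect_equal(nrow(hyperparameter_grid("svm_linear", "full")), 6L)
  dt <- hyperparameter_grid("decision_tree", "full")
  expect_equal(nrow(dt), 12 * 17 * 5 * 2)
  expect_setequal(unique(dt$impurity), c("gini", "entropy"))
  expect_equal(nrow(mlp_configurations()), 60L)
  expect_identical(mlp_configurations(), mlp_configurations())
})

test_that("every reduced-grid spec fits and scores on synthetic data", {
  d <- small_survey(150, seed = 41)
  sc <- minmax_scale(d[iaq_surrogates])
  for (alg in iaq_algorithms) {
    grid <- hyperparameter_grid(alg)
    for (i in seq_len(nrow(grid))) {
      spec <- do.call(model_spec, c(list(alg), as.list(grid[i, ])))
      m <- fit_classifier(spec, sc$train, d$label, seed = 3)
      acc <- model_accuracy(m, sc$train, d$label)
      expect_gte(acc, 0)
      expect_lte(acc, 1)
    }
  }
})

test_that("single-class training labels are refused", {
  d <- small_survey(80, seed = 6)
  sc <- minmax_scale(d[iaq_surrogates])
  expect_error(
    fit_classifier(model_spec("svm_rbf", C = 1), sc$train,
                   rep("satisfactory", nrow(d))),
    "one class")
})

test_that("1-nearest-neighbour recalls its own training points", {
  d <- small_survey(60, seed = 8)
  sc <- minmax_scale(d[iaq_surrogates])
  m <- fit_classifier(model_spec("knn", k = 1, weight = "uniform"),
                      sc$train, d$label)
  expect_identical(as.character(predict(m, sc$train)),
                   as.character(d$label))
  # distance weighting with a zero distance also returns the stored label
  mw <- fit_classifier(model_spec("knn", k = 5, weight = "distance"),
                       sc$train, d$label)
  expect_equal(model_accuracy(mw, sc$train, d$label), 1)
})

test_that("a deep enough tree separates a linearly separable toy set", {
  fx <- separable_set(20)
  m <- fit_classifier(model_spec("decision_tree", D = 10, n_s = 2, n_r = 1),
                      fx$x, fx$y)
  expect_equal(model_accuracy(m, fx$x, fx$y), 1)
})

test_that("MLP activations and iteration schemes all train", {
  fx <- separable_set(80, seed = 12)
  for (act in c("identity", "logistic", "tanh", "relu")) {
    for (solver in c("lbfgs", "sgd", "adam")) {
      spec <- model_spec("mlp", total_neurons = 8, ratio = "1",
                         activation = act, solver = solver,
                         learning_rate = "constant", C = 1e-4,
                         max_iter = 150)
      m <- fit_classifier(spec, fx$x, fx$y, seed = 5)
      acc <- model_accuracy(m, fx$x, fx$y)
      expect_gte(acc, 0.5)  # clearly better than coin flips on separable data
    }
  }
  # deeper architectures with schedule variants fit without error
  for (lr in c("invscaling", "adaptive")) {
    spec <- model_spec("mlp", total_neurons = 20, ratio = "1:2:1",
                       activation = "tanh", solver = "sgd",
                       learning_rate = lr, max_iter = 100)
    m <- fit_classifier(spec, fx$x, fx$y, seed = 5)
    expect_s3_class(m, "iaq_model")
  }
})

test_that("stochastic backends are deterministic given spec and seed", {
  d <- small_survey(120, seed = 14)
  sc <- minmax_scale(d[iaq_surrogates])
  spec <- default_model_spec("random_forest")
  p1 <- predict(fit_classifier(spec, sc$train, d$label, seed = 7), sc$train)
  p2 <- predict(fit_classifier(spec, sc$train, d$label, seed = 7), sc$train)
  expect_identical(p1, p2)
  # the MLP is seeded, but threaded BLAS may reorder floating-point
  # reductions between runs: require agreement up to that noise
  spec <- default_model_spec("mlp")
  m1 <- fit_classifier(spec, sc$train, d$label, seed = 7)
  m2 <- fit_classifier(spec, sc$train, d$label, seed = 7)
  q1 <- predict(m1, sc$train)
  q2 <- predict(m2, sc$train)
  expect_gte(mean(q1 == q2), 0.98)
})
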