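test_that("Monte-Carlo samples are uniform on their ranges and seeded", {
  mc <- monte_carlo_sample(1e5, seed = 3)
  rng <- sampling_ranges()
  for (p in iaq_surrogates) {
    expect_true(all(mc[[p]] >= rng[[p]][1] & mc[[p]] <= rng[[p]][2]))
    mid <- mean(rng[[p]])
    width <- diff(rng[[p]])
    expect_lt(abs(mean(mc[[p]]) - mid) / width, 0.01)
  }
  expect_identical(mc, monte_carlo_sample(1e5, seed = 3))
  expect_error(sampling_ranges(co2 = c(5, 1)), "lower < upper")
})

test_that("model averaging returns vote fractions and a conservative tie", {
  d <- small_survey(200, seed = 61)
  sc <- minmax_scale(d[iaq_surrogates])
  mk <- function(alg) list(
    model = fit_classifier(default_model_spec(alg), sc$train, d$label,
                           seed = 2),
    scaler = sc$scaler)
  triples <- monte_carlo_sample(500, seed = 1)
  one <- model_average_predict(list(mk("decision_tree")), triples)
  expect_true(all(one$fraction_satisfactory %in% c(0, 1)))
  two <- model_average_predict(list(mk("decision_tree"), mk("logistic")),
                               triples)
  expect_true(all(two$fraction_satisfactory >= 0 &
                    two$fraction_satisfactory <= 1))
  tie <- two$fraction_satisfactory == 0.5
  if (any(tie)) {
    expect_true(all(two$label[tie] == "unsatisfactory"))
  }
  expect_error(model_average_predict(list(list(model = NULL)), triples),
               "model")
})

test_that("bin percentages sum to 100 and match a hand count", {
  theta <- c(0.10, 0.20, 0.35, 0.40, 0.45, 0.50, 0.60, 0.60, 0.70, 0.90)
  lab <- rep(c("satisfactory", "unsatisfactory"), 5)
  bp <- bin_percentages(theta, lab)
  expect_equal(bp$n, c(2L, 2L, 2L, 2L, 2L))
  expect_true(all(bp$pct_satisfactory + bp$pct_unsatisfactory == 100))
  expect_equal(bp$pct_satisfactory[1], 50)  # 0.10 sat, 0.20 unsat
  all_sat <- bin_percentages(theta, rep("satisfactory", 10))
  expect_true(all(all_sat$pct_satisfactory == 100))
  expect_warning(bin_percentages(c(0.1, 0.2), c("satisfactory", "satisfactory")),
                 "empty bin")
})

test_that("index bins partition the axis under 2-dp display rounding", {
  bins <- theta_bins()
  expect_equal(nrow(bins), 5L)
  expect_equal(bins$lower[-1], bins$upper[-5])  # contiguous
  # every rounded label boundary maps into its own bin
  b <- iaqscreen:::assign_bins(c(0.31, 0.32, 0.42, 0.43, 0.64, 0.65))
  expect_equal(as.character(b),
               c("<0.32", "0.32-0.42", "0.32-0.42", "0.43-0.53",
                 "0.54-0.64", ">=0.65"))
})

test_that("group normal fits recover parameters and report the u statistic", {
  expect_equal(
    fit_index_distributions(c(0.4, 0.6, 0.1, 0.9),
                            c("satisfactory", "satisfactory",
                              "unsatisfactory", "unsatisfactory"),
                            u_bounds = NULL)$mean,
    c(0.5, 0.5))
  th <- iaqscreen:::with_seed(77, c(stats::rnorm(10000, 0.40, 0.11),
                                    stats::rnorm(10000, 0.63, 0.25)))
  lab <- rep(c("satisfactory", "unsatisfactory"), each = 10000)
  fit <- fit_index_distributions(th, lab)
  expect_lt(abs(fit$mean[1] - 0.40) / 0.40, 0.02)
  expect_lt(abs(fit$sd[2] - 0.25) / 0.25, 0.02)
  # studentized range of 0..10: range 10 over sd of the sequence
  u <- fit_index_distributions(c(0:10, 0:10),
                               rep(c("satisfactory", "unsatisfactory"),
                                   each = 11), u_bounds = NULL)$u_stat
  expect_equal(u, rep(10 / stats::sd(0:10), 2))
  expect_error(
    fit_index_distributions(c(1, 1, 0, 2),
                            rep(c("satisfactory", "unsatisfactory"),
                                each = 2)),
    "zero variance")
})

test_that("likelihood ratios follow the normal masses", {
  same <- tibble::tibble(group = c("satisfactory", "unsatisfactory"),
                         n = 10, mean = 0.5, sd = 0.1)
  class(same) <- c("iaq_group_dists", class(same))
  lr <- likelihood_ratio(theta_bins(), same)
  expect_equal(lr$lr, rep(1, 5))
  whole <- tibble::tibble(bin = "all", lower = -Inf, upper = Inf)
  dists <- tibble::tibble(group = c("satisfactory", "unsatisfactory"),
                          n = 10, mean = c(0.40, 0.63), sd = c(0.11, 0.25))
  expect_equal(likelihood_ratio(whole, dists)$lr, 1)
  # survey-like moments, top bin: normal-CDF oracle
  top <- tibble::tibble(bin = ">=0.65", lower = 0.645, upper = Inf)
  oracle <- (1 - pnorm(0.645, 0.63, 0.25)) / (1 - pnorm(0.645, 0.40, 0.11))
  expect_equal(likelihood_ratio(top, dists)$lr, oracle)
  expect_equal(round(oracle, 1), 36.7)
})

test_that("relative impacts are element-wise LR ratios with flagged gaps", {
  lr1 <- tibble::tibble(bin = c("a", "b"), lr = c(4, 2))
  lr2 <- tibble::tibble(bin = c("a", "b"), lr = c(2, 2))
  ri <- relative_impact(lr2, lr1)
  expect_equal(ri$impact, c(0.5, 1))
  lr_bad <- tibble::tibble(bin = c("a", "b"), lr = c(Inf, 2))
  expect_warning(ri2 <- relative_impact(lr_bad, lr1), "undefined")
  expect_true(is.na(ri2$impact[1]))
  expect_error(relative_impact(tibble::tibble(bin = "z", lr = 1),
                               tibble::tibble(bin = "a", lr = 1)),
               "do not match")
})

test_that("table updating multiplies and rounds half-up for display", {
  up <- update_screening_table(default_lr1(), c(1.4, 1.2, 1.1, 1.3, 1.5))
  expect_equal(up$lr2, c(0.14, 0.48, 0.88, 2.21, 37.5))
  expect_equal(up$lr2_display, c(0.1, 0.5, 0.9, 2.2, 38))
  unit <- update_screening_table(default_lr1(), rep(1, 5))
  expect_equal(unit$lr2, unit$lr1)
})

test_that("post-test probability follows the odds algebra", {
  expect_equal(post_test_probability(0.3, 1), 0.3)
  expect_equal(post_test_probability(0.5, 3), 0.75)
  p <- post_test_probability(0.3, c(0.5, 1, 2, 10, 100))
  expect_true(all(diff(p) > 0))
  expect_warning(expect_equal(post_test_probability(1, 5), 1), "degenerate")
})
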