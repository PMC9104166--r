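test_that("a degenerate all-satisfactory mixture assesses satisfactory", {
  d <- generate_offices(n_offices = 50, p_satisfactory = 1, seed = 2)
  expect_equal(nrow(d), 50L)
  expect_true(all(d$label == "satisfactory"))
})

test_that("intended labels agree with assessment on the generating scheme", {
  for (sv in 1:2) {
    d <- generate_offices(n_offices = 400, scheme = sv, seed = 13)
    expect_identical(as.character(assess_iaq(d[iaq_pollutants], sv)$label),
                     as.character(d$label))
  }
})

test_that("generation is reproducible from config and seed alone", {
  cfg <- generator_config(n_offices = 200, seed = 31)
  d1 <- generate_offices(config = cfg)
  d2 <- generate_offices(config = cfg)
  expect_identical(d1, d2)
  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_dataset(d1, f1, sidecar = FALSE)
  write_dataset(d2, f2, sidecar = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(d1, generate_offices(n_offices = 200, seed = 32)))
})

test_that("group surrogate moments track the configured targets", {
  d <- generate_offices(n_offices = 6000, seed = 5)
  sm <- summarize_offices(d)
  tg <- default_group_stats(1)
  for (g in c("satisfactory", "unsatisfactory")) {
    for (p in iaq_surrogates) {
      target <- tg$mean[tg$group == g & tg$pollutant == p]
      got <- sm[[p]][sm$group == g & sm$statistic == "mean"]
      expect_lt(abs(got - target) / target, 0.05)
    }
  }
})

test_that("a forced hidden-failure fraction is honoured", {
  d <- generate_offices(n_offices = 2500, hidden_failure_fraction = 0.2,
                        seed = 17)
  u <- d[d$label == "unsatisfactory", ]
  lim <- scheme_hk(1)$limits
  hidden <- u$co2 <= lim["co2"] & u$rsp <= lim["rsp"] & u$tvoc <= lim["tvoc"]
  expect_lt(abs(mean(hidden) - 0.2), 0.05)
  # hidden failures exceed exactly one non-surrogate limit
  h <- u[hidden, ]
  ns <- setdiff(iaq_pollutants, iaq_surrogates)
  exceed <- rowSums(sweep(as.matrix(h[ns]), 2, lim[ns], `>`))
  expect_true(all(exceed == 1))
})

test_that("infeasible configurations raise a calibration error", {
  bad <- default_group_stats(1)
  bad$mean[bad$group == "satisfactory" & bad$pollutant == "co2"] <- 1100
  bad$max[bad$group == "satisfactory" & bad$pollutant == "co2"] <- 1400
  expect_error(generate_offices(n_offices = 20, group_stats = bad, seed = 1),
               "calibration error")
})

test_that("scheme-2 satisfactory count never exceeds scheme-1's", {
  d <- generate_offices(n_offices = 1000, seed = 23)
  n1 <- sum(assess_iaq(d[iaq_pollutants], 1)$label == "satisfactory")
  n2 <- sum(assess_iaq(d[iaq_pollutants], 2)$label == "satisfactory")
  expect_lte(n2, n1)
})

test_that("the survey summary has the expected structure and identities", {
  one <- generate_offices(n_offices = 1, p_satisfactory = 1, seed = 9)
  s1 <- suppressWarnings(summarize_offices(one))
  for (p in iaq_surrogates) {
    vals <- s1[[p]][s1$group == "overall" &
                      s1$statistic %in% c("mean", "min", "max")]
    expect_true(all(vals == one[[p]]))
  }
  d <- small_survey()
  s <- summarize_offices(d)
  expect_setequal(unique(s$group),
                  c("overall", "satisfactory", "unsatisfactory"))
  # linearity: mean theta equals the index of the mean surrogate triple
  m <- s[s$group == "overall" & s$statistic == "mean", ]
  expect_equal(m$theta,
               iaq_index(m[iaq_surrogates])$theta)
  # empty group is dropped with a warning
  all_sat <- generate_offices(n_offices = 30, p_satisfactory = 1, seed = 2)
  expect_warning(s2 <- summarize_offices(all_sat), "empty")
  expect_false("unsatisfactory" %in% s2$group)
})
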