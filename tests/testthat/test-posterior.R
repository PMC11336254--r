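test_that("directional posterior probabilities count ties conservatively", {
  expect_equal(p_bayes(2:5, 0:3 - 1, "A>B"), 0)
  expect_equal(p_bayes(1:4, 1:4, "A>B"), 1)  # all ties are contrary
  expect_equal(p_bayes(c(-1, 0, 1, 2), rep(0, 4), "A>B"), 0.5)
  expect_equal(p_bayes(c(-1, 0, 1, 2), rep(0, 4), "A<B"), 0.75)
  expect_error(p_bayes(1:3, 1:4), "equal length")
})

test_that("direction probabilities are complementary up to ties", {
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(200)
    b <- rnorm(200)
    s <- p_bayes(a, b, "A>B") + p_bayes(a, b, "A<B")
    expect_gte(s, 1)
    expect_equal(s, 1)  # continuous draws: no exact ties
  }
  a <- c(1, 2, 2); b <- c(1, 1, 3)
  expect_gt(p_bayes(a, b, "A>B") + p_bayes(a, b, "A<B"), 1)
})

test_that("posterior-odds conversion reproduces its arithmetic identities", {
  expect_equal(bf_from_pbayes(0.5), 1)
  expect_error(bf_from_pbayes(-0.1), "\\[0, 1\\]")
  expect_error(bf_from_pbayes(1.4), "\\[0, 1\\]")
  expect_identical(bf_from_pbayes(0), Inf)
  expect_identical(bf_from_pbayes(1), 0)
  p <- seq(0.01, 0.99, by = 0.01)
  bf <- bf_from_pbayes(p)
  expect_true(all(diff(bf) < 0))                 # strictly decreasing
  expect_equal(bf * bf_from_pbayes(1 - p), rep(1, length(p)))  # reciprocal
})

test_that("evidence-ratio formatting follows the reporting convention", {
  expect_equal(format_bf(0.031), "31")
  expect_equal(format_bf(0.0005), "> 1000")
  expect_equal(format_bf(0.75), "0.33")
  t <- directional_test(c(3, 4), c(1, 2), "A>B", cells = c("x", "y"))
  expect_equal(t$p_bayes, 0)
  expect_output(print(t), "> 1000")
})

test_that("prediction-error contrast arithmetic on constant draws", {
  post <- fake_eta_posterior(c(
    "stereotypic:high" = 0.10, "stereotypic:low" = 0.20,
    "counter-stereotypic:high" = 0.30, "counter-stereotypic:low" = 0.15))
  ctr <- prediction_error_contrast(post)
  expect_equal(unique(ctr$delta_stereotypic), 0.10, tolerance = 1e-12)
  expect_equal(unique(ctr$delta_counter), 0.15, tolerance = 1e-12)
  expect_equal(unique(ctr$difference), 0.05, tolerance = 1e-12)
  # identical cell distributions: the contrast is symmetric around zero
  set.seed(9)
  n <- 4000
  info <- fake_eta_posterior(c("stereotypic:high" = 0.2,
                               "stereotypic:low" = 0.2,
                               "counter-stereotypic:high" = 0.2,
                               "counter-stereotypic:low" = 0.2), n)
  info$draws[] <- info$draws + rnorm(length(info$draws), 0, 0.3)
  p <- prediction_error_contrast(info)$test$p_bayes
  expect_equal(p, 0.5, tolerance = 0.05)
  # a two-cell posterior cannot support the contrast
  two <- fake_eta_posterior(c("stereotypic" = 0.1,
                              "counter-stereotypic" = 0.2))
  expect_error(prediction_error_contrast(two), "integrative")
})

test_that("reports are deterministic and complete", {
  set.seed(37)
  coh <- generate_cohort(preset_expt1(n_per_context = 3))
  fit <- fit_rlddm(coh$log, "integrative", n_samples = 250, n_burn = 120,
                   seed = 6)
  ctr <- prediction_error_contrast(fit)
  eta <- extract_group(fit, "eta")
  tst <- directional_test(eta[, "counter-stereotypic:high"],
                          eta[, "stereotypic:high"], "A>B",
                          cells = c("counter-stereotypic high-fit",
                                    "stereotypic high-fit"))
  d1 <- tempfile(); d2 <- tempfile()
  report(fit, tests = list(tst), contrast = ctr, out_dir = d1)
  report(fit, tests = list(tst), contrast = ctr, out_dir = d2)
  j1 <- readLines(file.path(d1, "report.json"))
  expect_identical(j1, readLines(file.path(d2, "report.json")))
  # all four learning-rate cells appear in the summary
  summ <- read.csv(file.path(d1, "posterior_summary.csv"))
  expect_equal(sum(summ$param == "eta"), 4)
  expect_true(all(c("cri_lo", "cri_hi") %in% names(summ)))
})
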