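test_that("exactly three named candidate specifications exist", {
  expect_equal(model_spec("context")$label, "learning-context model")
  expect_equal(model_spec("fit")$label, "goodness-of-fit model")
  expect_equal(model_spec("integrative")$label, "integrative model")
  expect_error(model_spec("extra"))
  expect_length(model_spec("context")$cells, 2)
  expect_length(model_spec("fit")$cells, 2)
  expect_length(model_spec("integrative")$cells, 4)
})

test_that("model graphs free the right cells per specification", {
  set.seed(2)
  coh <- generate_cohort(preset_expt1(n_per_context = 2))
  for (nm in c("context", "fit", "integrative")) {
    m <- build_model(model_spec(nm), coh$log)
    info <- rlddm:::.node_info(m)
    n_cells <- c(context = 2, fit = 2, integrative = 4)[[nm]]
    expect_equal(sum(info$kind == "mu" & info$param == "eta"), n_cells)
    # t0 is factor-free in every candidate
    expect_equal(sum(info$kind == "mu" & info$param == "t0"), 1)
  }
  # a context-only spec needs both contexts in the data
  one_ctx <- coh$log[coh$log$context == "stereotypic", ]
  expect_error(build_model(model_spec("context"), one_ctx),
               "specification error")
  # a nearly empty cell is kept with a warning
  sparse <- coh$log
  drop <- sparse$subj_idx == 1 & sparse$fit_of_target == "low" &
    sparse$trial > min(sparse$trial[sparse$subj_idx == 1 &
                                      sparse$fit_of_target == "low"])
  expect_warning(build_model(model_spec("fit"), sparse[!drop, ]),
                 "retained")
})

test_that("MCMC returns the configured draw counts, reproducibly", {
  set.seed(3)
  coh <- generate_cohort(preset_expt1(n_per_context = 2))
  m <- build_model(model_spec("context"), coh$log)
  post <- run_mcmc(m, n_samples = 200, n_burn = 120, n_chains = 2, seed = 7)
  expect_equal(dim(post$draws)[1], 80)
  expect_equal(dim(post$draws)[3], 2)
  post2 <- run_mcmc(m, n_samples = 200, n_burn = 120, n_chains = 2, seed = 7)
  expect_identical(post$draws, post2$draws)
  expect_error(run_mcmc(m, n_samples = 100, n_burn = 100), "n_samples")
})

test_that("with a flat likelihood the sampler recovers the prior", {
  # subject with no trials: the session likelihood is identically zero, so
  # the group mean's marginal posterior is its prior (a conjugate
  # known-variance normal chain) -- closed-form oracle N(m0, s0)
  subj <- list(list(pair = integer(0), response = integer(0),
                    rt = numeric(0), feedback = integer(0),
                    cell = integer(0), n_pairs = 1L, map = 0L,
                    min_rt = 1))
  init <- list(mu = matrix(0, 3, 1), mu_t0 = 0,
               x = list(c(0, 1, 0, 0)))
  set.seed(14)
  out <- rlddm:::cpp_run_chain(subj, 1L, 12000L, 2000L,
                               c(0, 1, 0, 0), 2, 1, 0.5, 1e-7, init)
  mu_v <- out$draws[, 2]  # group-mean node of the drift scaling
  n <- length(mu_v)
  # batch-means standard error to account for autocorrelation
  bm <- tapply(mu_v, rep(1:100, each = n / 100), mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(mu_v) - 1), 4 * se)
  expect_equal(sd(mu_v), 2, tolerance = 0.15)
})

test_that("potential scale reduction behaves at its reference points", {
  set.seed(5)
  iid <- array(rnorm(5000 * 2 * 3), c(5000, 2, 3))
  r <- gelman_rubin(iid)
  expect_true(all(r > 0.99 & r < 1.01))

  apart <- array(c(rnorm(1000), rnorm(1000, 10)), c(1000, 1, 2))
  expect_gt(gelman_rubin(apart)[1], 3)

  flat <- array(1, c(100, 1, 3))
  expect_equal(unname(gelman_rubin(flat)[1]), 1)

  expect_error(gelman_rubin(array(rnorm(100), c(100, 1, 1))), "2 chains")
})

test_that("DIC follows the posterior-deviance decomposition", {
  r <- compute_dic(c(10, 12, 14), plugin_deviance = 11)
  expect_equal(r$p_d, 1)
  expect_equal(r$dic, 13)
  r0 <- compute_dic(rep(10, 50), plugin_deviance = 10)
  expect_equal(r0$p_d, 0)
  expect_equal(r0$dic, 10)
  expect_error(compute_dic(c(rep(10, 50), Inf), plugin_deviance = 10),
               "non-finite")
  expect_error(compute_dic(c(10, 12)), "plugin_deviance")
})

test_that("short fits recover group parameters on a small cohort", {
  set.seed(8)
  coh <- generate_cohort(preset_expt1(n_per_context = 6))
  fit <- fit_rlddm(coh$log, "integrative", n_samples = 500, n_burn = 250,
                   seed = 4)
  expect_s3_class(fit, "rlddm_fit")
  expect_true(is.finite(fit$dic) && fit$p_d > 0)
  t0_hat <- mean(extract_group(fit, "t0"))
  expect_equal(t0_hat, 0.35, tolerance = 0.25)
  a_hat <- colMeans(extract_group(fit, "a"))
  expect_true(all(a_hat > 1 & a_hat < 3.5))
  sm <- subject_posterior_means(fit)
  expect_setequal(unique(sm$param), c("eta", "v_scaling", "a", "t0"))
})
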