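test_that("delta rule updates and its limits", {
  expect_equal(update_q(0.5, 1, 0.1), 0.55)
  expect_equal(update_q(0.7, 0, 1), 0)   # full-update limit
  expect_equal(update_q(0.3, 1, 0), 0.3) # no-learning limit
  expect_error(update_q(0.5, 1, -0.1), "eta")
  expect_error(update_q(0.5, 1, 1.2), "eta")
  expect_error(update_q(0.5, 2, 0.5))
  # values stay inside [0, 1] for binary feedback
  q <- 0.5
  set.seed(1)
  for (i in 1:200) q <- update_q(q, rbinom(1, 1, 0.8), 0.9)
  expect_true(q >= 0 && q <= 1)
})

test_that("trial drift is the scaled value difference, antisymmetric", {
  expect_equal(trial_drift(0.5, 0.5, 10), 0)
  expect_equal(trial_drift(0.8, 0.2, 3), 1.8)
  expect_equal(trial_drift(0.2, 0.8, 3), -trial_drift(0.8, 0.2, 3))
})

test_that("parameter sets expand scalars and enforce domains", {
  p <- parameter_set(eta = 0.3, v_scaling = c(high = 3, low = 2), a = 2,
                     t0 = 0.3)
  expect_equal(p$eta, c(high = 0.3, low = 0.3))
  expect_equal(p$v_scaling[["low"]], 2)
  expect_error(parameter_set(eta = 1.2, v_scaling = 1, a = 1, t0 = 0),
               "eta")
  expect_error(parameter_set(eta = 0.3, v_scaling = 1, a = -1, t0 = 0),
               "`a`")
})

test_that("forced agents expose the termination rules", {
  pars <- parameter_set(eta = 0.3, v_scaling = 3, a = 2, t0 = 0.3)
  d <- default_design("stereotypic", 1, 2)
  set.seed(5)
  never <- simulate_session(pars, d, policy = "always_other")
  expect_equal(nrow(never), 480)  # ceiling: 4 blocks of 120
  always <- simulate_session(pars, d, policy = "always_target")
  expect_equal(nrow(always), 120)  # perfect accuracy stops after block 1
  expect_true(all(always$response == 1))
})

test_that("feedback frequencies track the reward schedule", {
  d <- default_design("stereotypic", 1, 1)
  set.seed(11)
  fb <- simulate_pair_feedback(d, "AB", 10000)$feedback
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(mean(fb) - 0.8), 3 * se)
  fb_other <- simulate_pair_feedback(d, "AB", 10000,
                                     choose_target = FALSE)$feedback
  expect_lt(abs(mean(fb_other) - 0.2), 3 * se)
  expect_error(simulate_pair_feedback(d, "XY", 10), "unknown pair")
})

test_that("simulated agents learn: late accuracy beats early accuracy", {
  pars <- parameter_set(eta = 0.3, v_scaling = 3, a = 2, t0 = 0.3)
  # independent probability-matching RL oracle for the same trend
  oracle_acc <- function(n, eta, p_r) {
    qt <- 0.5; qo <- 0.5; acc <- integer(n)
    for (i in 1:n) {
      choose_t <- runif(1) < qt / (qt + qo)
      fb <- rbinom(1, 1, if (choose_t) p_r else 1 - p_r)
      if (choose_t) qt <- qt + eta * (fb - qt) else qo <- qo + eta * (fb - qo)
      acc[i] <- as.integer(choose_t)
    }
    acc
  }
  set.seed(21)
  gains_ddm <- gains_orc <- numeric(20)
  for (r in 1:20) {
    log <- fixed_length_session(pars, 198, seed = 100 + r)
    ab <- log[log$pair == "AB", ]
    q <- nrow(ab) %/% 4
    gains_ddm[r] <- mean(utils::tail(ab$response, q)) -
      mean(utils::head(ab$response, q))
    oa <- oracle_acc(80, 0.3, 0.8)
    gains_orc[r] <- mean(utils::tail(oa, 20)) - mean(utils::head(oa, 20))
  }
  expect_gt(mean(gains_ddm), 0)
  expect_gt(mean(gains_orc), 0)  # oracle shows the same learning trend
})

test_that("session log-likelihood is deterministic and matches the single-trial case", {
  pars <- parameter_set(eta = 0.3, v_scaling = 3, a = 2, t0 = 0.3)
  d <- default_design("stereotypic", 1, 1)
  log1 <- tiny_log()[1, ]
  ll <- session_loglik(log1, pars, d)
  direct <- wiener_logpdf(log1$rt, "upper",
                          ddm_params(v = 0, a = 2, t0 = 0.3))
  expect_equal(ll, direct)  # first trial: q_t = q_o = 0.5, drift 0

  log <- fixed_length_session(pars, 120, seed = 3)
  expect_identical(session_loglik(log, pars, d),
                   session_loglik(log, pars, d))

  fast <- log; fast$rt[5] <- 0.1  # below t0
  llf <- session_loglik(fast, pars, d)
  expect_identical(as.numeric(llf), -Inf)
  expect_true(isTRUE(attr(llf, "invalid_rt")))
})

test_that("Q replay is pair-local: interleaving across pairs is irrelevant", {
  pars <- parameter_set(eta = 0.4, v_scaling = 2.5, a = 1.8, t0 = 0.25)
  d <- default_design("stereotypic", 1, 1)
  log <- fixed_length_session(pars, 120, seed = 8)
  # regroup trials by pair, preserving each pair's internal order
  perm <- order(match(log$pair, c("EF", "AB", "CD")),
                seq_len(nrow(log)))
  relog <- log[perm, ]
  relog$trial <- seq_len(nrow(relog))
  expect_equal(session_loglik(relog, pars, d), session_loglik(log, pars, d),
               tolerance = 1e-12)
})

test_that("log-likelihood is smooth in eta, v_scaling and a", {
  base <- list(eta = 0.3, v = 3, a = 2)
  d <- default_design("stereotypic", 1, 1)
  log <- fixed_length_session(
    parameter_set(eta = base$eta, v_scaling = base$v, a = base$a, t0 = 0.3),
    120, seed = 13)
  ll <- function(eta = base$eta, v = base$v, a = base$a)
    session_loglik(log, parameter_set(eta, v, a, t0 = 0.3), d)
  h <- 1e-6
  expect_lt(abs(ll(eta = base$eta + h) - ll()), 1e-3)
  expect_lt(abs(ll(v = base$v + h) - ll()), 1e-3)
  expect_lt(abs(ll(a = base$a + h) - ll()), 1e-3)
})

test_that("generating parameters dominate perturbed ones in likelihood", {
  pars <- parameter_set(eta = 0.3, v_scaling = 3, a = 2, t0 = 0.3)
  lo <- parameter_set(eta = 0.15, v_scaling = 3, a = 2, t0 = 0.3)
  hi <- parameter_set(eta = 0.45, v_scaling = 3, a = 2, t0 = 0.3)
  d <- default_design("stereotypic", 1, 1)
  wins <- 0
  for (r in 1:100) {
    log <- fixed_length_session(pars, 198, seed = 1000 + r)
    ll0 <- session_loglik(log, pars, d)
    if (ll0 > session_loglik(log, lo, d) &&
        ll0 > session_loglik(log, hi, d)) wins <- wins + 1
  }
  expect_gte(wins, 80)
})

test_that("exact-proportion schedules hit the nominal counts per block", {
  pars <- parameter_set(eta = 0.3, v_scaling = 3, a = 2, t0 = 0.3)
  d <- default_design("stereotypic", 1, 1)
  set.seed(77)
  log <- simulate_session(pars, d, policy = "always_target",
                          feedback_schedule = "exact")
  reps <- d$block_length / nrow(d$pairs)
  for (b in unique(log$block)) for (i in seq_len(nrow(d$pairs))) {
    rows <- log$block == b & log$pair == d$pairs$pair_id[i]
    expect_equal(sum(log$feedback[rows]),
                 round(d$pairs$p_reward_target[i] * reps))
  }
})
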