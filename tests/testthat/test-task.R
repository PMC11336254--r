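test_that("default design carries the standard PST structure", {
  d <- default_design("stereotypic", 1, 1)
  expect_equal(d$pairs$p_reward_target, c(0.80, 0.70, 0.60))
  expect_equal(d$pairs$criterion, c(0.60, 0.55, 0.50))
  expect_equal(nrow(d$pairs), 3)

  d2 <- default_design("counter-stereotypic", 2, 2)
  expect_equal(nrow(d2$pairs), 6)
  expect_equal(d2$pairs$target_fit[d2$pairs$face_sex == "female"],
               rep("low", 3))
  expect_equal(d2$pairs$target_fit[d2$pairs$face_sex == "male"],
               rep("high", 3))
  expect_equal(default_design("stereotypic", 1, 2)$max_blocks *
                 default_design("stereotypic", 1, 2)$block_length, 480)

  expect_error(default_design("bogus"), "arg")
  expect_error(default_design(counterbalance_group = 3), "counterbalance")
  expect_error(default_design(block_length = 100, n_pair_sets = 2),
               "divisible")
})

test_that("counterbalance groups flip the fit mapping bijectively", {
  for (sets in 1:2) {
    g1 <- default_design("stereotypic", 1, sets)$pairs
    g2 <- default_design("stereotypic", 2, sets)$pairs
    expect_identical(g1$pair_id, g2$pair_id)
    expect_true(all(g1$target_fit != g2$target_fit))
  }
})

test_that("block criterion uses inclusive per-pair thresholds", {
  d <- default_design("stereotypic", 1, 1, block_length = 120)
  mk <- function(acc) {
    reps <- 40
    do.call(rbind, lapply(1:3, function(i)
      data.frame(pair = d$pairs$pair_id[i],
                 response = rep(c(1L, 0L),
                                c(round(acc[i] * reps),
                                  reps - round(acc[i] * reps))))))
  }
  expect_equal(check_block_criterion(mk(c(0.65, 0.60, 0.55)), d)$decision,
               "stop")
  expect_equal(check_block_criterion(mk(c(0.60, 0.55, 0.50)), d)$decision,
               "stop")  # equality is enough
  res <- check_block_criterion(mk(c(0.575, 1, 1)), d)
  expect_equal(res$decision, "continue")
  expect_named(res$accuracy, d$pairs$pair_id)

  expect_error(check_block_criterion(mk(c(1, 1, 1))[1:80, ], d), "exactly")
  bad <- mk(c(1, 1, 1)); bad$pair[bad$pair == "EF"] <- "AB"
  expect_error(check_block_criterion(bad, d), "absent")
})

test_that("trial logs round-trip and invalid logs are rejected", {
  log <- tiny_log()
  path <- tempfile(fileext = ".csv")
  write_trial_log(log, path)
  back <- read_trial_log(path)
  expect_equal(back, log)

  bad <- log; bad$rt[2] <- 0
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_trial_log(path), "non-positive rt.*2")

  bad <- log; bad$pair[1] <- "XY"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_trial_log(path, default_design("stereotypic", 1, 1)),
               "unknown pair.*XY")

  expect_error(validate_trial_log(log[, -4]), "missing column")
  bad <- log; bad$trial <- c(1L, 1L, 2L)
  expect_error(validate_trial_log(bad), "strictly increasing")
  bad <- log; bad$response[1] <- 2L
  expect_error(validate_trial_log(bad), "non-binary")
})

test_that("pairs are presented equally often within every block", {
  pars <- parameter_set(eta = 0.3, v_scaling = 3, a = 2, t0 = 0.3)
  d <- default_design("stereotypic", 1, 2)
  set.seed(7)
  log <- simulate_session(pars, d)
  expect_true(nrow(log) %% d$block_length == 0)
  expect_lte(nrow(log), d$max_blocks * d$block_length)
  for (b in unique(log$block)) {
    counts <- table(log$pair[log$block == b])
    expect_true(all(counts == d$block_length / nrow(d$pairs)))
  }
})
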