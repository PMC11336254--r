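# Hierarchical Bayesian estimation of the RL-DDM by adaptive
# Metropolis-within-Gibbs, with Gelman-Rubin diagnostics and DIC.

#' Candidate model specifications
#'
#' The three candidate RL-DDMs differ only in which experimental factors the
#' learning rate, drift-rate scaling and boundary separation may vary over:
#' the learning-context model frees them across contexts only, the
#' goodness-of-fit model across fit levels only, and the integrative model
#' across all four context x fit cells.  Non-decision time is subject-level
#' and factor-free in every model.
#'
#' @param name `"context"`, `"fit"` or `"integrative"`.
#' @return A list of class `rlddm_model_spec` with the cell labels each
#'   freed parameter ranges over.
#' @export
model_spec <- function(name = c("context", "fit", "integrative")) {
  name <- match.arg(name)
  cells <- switch(name,
    context = .pst_contexts,
    fit = .pst_fits,
    integrative = {
      g <- .cell_grid()
      paste(g$context, g$fit, sep = ":")
    })
  label <- switch(name, context = "learning-context model",
                  fit = "goodness-of-fit model",
                  integrative = "integrative model")
  structure(list(name = name, label = label, cells = cells),
            class = "rlddm_model_spec")
}

# global cell index (1-based) of each trial under a spec
.trial_cells <- function(spec, context, fit) {
  switch(spec$name,
    context = match(context, .pst_contexts),
    fit = match(fit, .pst_fits),
    integrative = match(paste(context, fit, sep = ":"), spec$cells))
}

#' Default priors for the hierarchical model
#'
#' Weakly informative priors on the sampling scales: group means
#' normal(0, 2) for logit learning rate, log boundary separation and log
#' non-decision time, normal(1, 2) for the (natural-scale) drift scaling;
#' group SDs half-normal(1).
#'
#' @return List with `m0` (prior means for eta, v_scaling, a, t0 in that
#'   order), `s0` (prior SD of group means) and `hn_scale` (half-normal
#'   scale of group SDs).
#' @export
default_priors <- function() {
  list(m0 = c(eta = 0, v_scaling = 1, a = 0, t0 = 0), s0 = 2, hn_scale = 1)
}

#' Build the hierarchical RL-DDM graph
#'
#' Prepares a validated trial log for MCMC under a candidate specification:
#' one group mean and SD per freed parameter and cell, partially pooled
#' subject-level nodes for the cells each subject contributes data to, and
#' the RL-DDM session likelihood with response coding "upper boundary =
#' positively reinforced face".  A subject with fewer than 2 trials in a
#' freed cell is retained with a warning (pooling absorbs it); a cell with
#' no data cohort-wide is a specification error.
#'
#' @param spec a [model_spec()].
#' @param trial_log cohort trial-log data frame.
#' @param priors see [default_priors()].
#' @return A list of class `rlddm_model`.
#' @export
build_model <- function(spec, trial_log, priors = default_priors()) {
  stopifnot(inherits(spec, "rlddm_model_spec"))
  validate_trial_log(trial_log)
  K <- length(spec$cells)
  cell_all <- .trial_cells(spec, trial_log$context, trial_log$fit_of_target)
  empty <- setdiff(seq_len(K), unique(cell_all))
  if (length(empty))
    stop("specification error: no data cohort-wide for cell(s) ",
         paste(spec$cells[empty], collapse = ", "), call. = FALSE)
  subj_ids <- unique(trial_log$subj_idx)
  subjects <- vector("list", length(subj_ids))
  for (i in seq_along(subj_ids)) {
    rows <- trial_log$subj_idx == subj_ids[i]
    sl <- trial_log[rows, , drop = FALSE]
    pair_ids <- sort(unique(sl$pair))
    gcell <- .trial_cells(spec, sl$context, sl$fit_of_target)
    map <- sort(unique(gcell))
    counts <- table(factor(gcell, levels = map))
    if (any(counts < 2))
      warning("subject ", subj_ids[i], " has < 2 trials in cell(s) ",
              paste(spec$cells[map[counts < 2]], collapse = ", "),
              "; retained (partial pooling)", call. = FALSE)
    subjects[[i]] <- list(pair = match(sl$pair, pair_ids) - 1L,
                          response = as.integer(sl$response),
                          rt = as.numeric(sl$rt),
                          feedback = as.integer(sl$feedback),
                          cell = match(gcell, map) - 1L,
                          n_pairs = length(pair_ids),
                          map = map - 1L,
                          min_rt = min(sl$rt))
  }
  structure(list(spec = spec, subjects = subjects, subj_ids = subj_ids,
                 K = K, priors = priors),
            class = "rlddm_model")
}

# node bookkeeping: names and natural-scale transforms
.node_info <- function(model) {
  K <- model$K
  cells <- model$spec$cells
  pn <- c("eta", "v_scaling", "a")
  group <- data.frame(
    node = c(paste0("mu_", rep(pn, each = K), "[", cells, "]"),
             paste0("sigma_", rep(pn, each = K), "[", cells, "]"),
             "mu_t0", "sigma_t0"),
    kind = c(rep("mu", 3 * K), rep("sigma", 3 * K), "mu", "sigma"),
    param = c(rep(pn, each = K), rep(pn, each = K), "t0", "t0"),
    cell = c(rep(cells, 3), rep(cells, 3), NA, NA),
    subj = NA, stringsAsFactors = FALSE)
  subj <- do.call(rbind, lapply(seq_along(model$subjects), function(i) {
    map <- model$subjects[[i]]$map + 1L
    id <- model$subj_ids[i]
    data.frame(
      node = c(paste0(rep(pn, each = length(map)), "[", id, ",",
                      cells[map], "]"),
               paste0("t0[", id, "]")),
      kind = "subject",
      param = c(rep(pn, each = length(map)), "t0"),
      cell = c(rep(cells[map], 3), NA),
      subj = id, stringsAsFactors = FALSE)
  }))
  dev <- data.frame(node = "deviance", kind = "deviance", param = NA,
                    cell = NA, subj = NA, stringsAsFactors = FALSE)
  rbind(group, subj, dev)
}

.init_state <- function(model) {
  K <- model$K
  mu <- matrix(c(rep(logit(0.2), K), rep(2, K), rep(log(1.5), K)),
               nrow = 3, byrow = TRUE)
  x <- lapply(model$subjects, function(s) {
    L <- length(s$map)
    c(rep(logit(0.2), L), rep(2, L), rep(log(1.5), L),
      log(0.5 * s$min_rt)) + rnorm(3 * L + 1, 0, 0.05)
  })
  # keep t0 safely below each subject's fastest response
  for (i in seq_along(x)) {
    j <- length(x[[i]])
    cap <- log(0.95 * model$subjects[[i]]$min_rt)
    if (x[[i]][j] >= cap) x[[i]][j] <- cap - 0.1
  }
  mu_t0 <- mean(vapply(x, function(xx) xx[length(xx)], numeric(1)))
  list(mu = mu, mu_t0 = mu_t0, x = x)
}

#' Run the MCMC sampler
#'
#' Samples the hierarchical posterior by adaptive Metropolis-within-Gibbs:
#' scalar random-walk updates of subject-level nodes on their sampling
#' scales (step sizes tuned toward 44% acceptance during burn-in, then
#' frozen), conjugate Gibbs draws of group means and random-walk updates of
#' log group SDs.  Defaults mirror the settings used for estimation
#' (10,000 samples including 5,000 burn, one chain); convergence checks use
#' 3 chains of 5,000 samples with 500 burn.
#'
#' @param model a [build_model()] object.
#' @param n_samples total MCMC sweeps per chain.
#' @param n_burn burn-in sweeps discarded per chain.
#' @param n_chains number of independent chains.
#' @param seed integer seed; chains use derived seeds and are reproducible.
#' @return An object of class `rlddm_posterior`: draw array
#'   `[iteration, node, chain]` with node metadata, per-draw deviance as a
#'   node, and the plug-in deviance needed by [compute_dic()].
#' @export
run_mcmc <- function(model, n_samples = 10000, n_burn = 5000, n_chains = 1,
                     seed = 1) {
  stopifnot(inherits(model, "rlddm_model"), n_samples > n_burn, n_burn >= 0)
  info <- .node_info(model)
  n_keep <- n_samples - n_burn
  draws <- array(NA_real_, c(n_keep, nrow(info), n_chains),
                 dimnames = list(NULL, info$node, NULL))
  plugin <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 131L * (ch - 1L))
    init <- .init_state(model)
    out <- cpp_run_chain(model$subjects, model$K, as.integer(n_samples),
                         as.integer(n_burn), model$priors$m0,
                         model$priors$s0, model$priors$hn_scale, 0.5, 1e-7,
                         init)
    draws[, , ch] <- out$draws
    plugin[ch] <- out$plugin_deviance
  }
  structure(list(draws = draws, nodes = info, model = model,
                 n_samples = n_samples, n_burn = n_burn,
                 n_chains = n_chains, seed = seed,
                 plugin_deviance = plugin),
            class = "rlddm_posterior")
}

#' Gelman-Rubin potential scale reduction
#'
#' Multi-chain potential-scale-reduction statistic per node:
#' `sqrt(((n-1)/n W + B/n) / W)` with within-chain variance `W` and
#' between-chain variance `B`.  Nodes with zero total variance (constant
#' chains) are defined as 1.  Requires at least two chains.
#'
#' @param posterior an [run_mcmc()] result (or an iterations x nodes x
#'   chains array).
#' @return Named vector of Rhat values.
#' @export
gelman_rubin <- function(posterior) {
  draws <- if (inherits(posterior, "rlddm_posterior")) posterior$draws
           else posterior
  if (length(dim(draws)) != 3 || dim(draws)[3] < 2)
    stop("Rhat needs >= 2 chains; rerun with n_chains >= 2 ",
         "(convergence configuration: 3 chains, 5000 samples, 500 burn)",
         call. = FALSE)
  n <- dim(draws)[1]
  apply(draws, 2, function(node) {
    ch_means <- colMeans(node)
    W <- mean(apply(node, 2, var))
    B_over_n <- var(ch_means)
    if (!is.finite(W) || W <= 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
}

#' Deviance information criterion
#'
#' `p_d = mean(D) - D(posterior mean)` and `DIC = mean(D) + p_d`, with
#' deviance `D = -2 log L`.  Non-finite deviance draws are excluded with a
#' count; more than 1% non-finite is an error.  For a fitted
#' `rlddm_posterior` the per-draw deviance is recorded during sampling and
#' the plug-in is evaluated at the posterior means of the subject-level
#' nodes on their sampling scales.
#'
#' @param posterior an `rlddm_posterior`, or a numeric vector of deviance
#'   draws (then supply `plugin_deviance` or `loglik_fn`).
#' @param loglik_fn optional function of a named posterior-mean vector
#'   returning the total log-likelihood, used for the plug-in deviance.
#' @param plugin_deviance optional precomputed plug-in deviance.
#' @return List with `dic`, `p_d`, `n_nonfinite`.
#' @export
compute_dic <- function(posterior, loglik_fn = NULL, plugin_deviance = NULL) {
  if (inherits(posterior, "rlddm_posterior")) {
    dev <- as.vector(posterior$draws[, "deviance", ])
    if (is.null(plugin_deviance)) {
      if (!is.null(loglik_fn)) {
        means <- apply(posterior$draws, 2, mean)
        plugin_deviance <- -2 * loglik_fn(means)
      } else {
        plugin_deviance <- .plugin_deviance(posterior)
      }
    }
  } else {
    dev <- as.numeric(posterior)
    if (is.null(plugin_deviance)) {
      if (is.null(loglik_fn))
        stop("supply `plugin_deviance` or `loglik_fn`", call. = FALSE)
      plugin_deviance <- -2 * loglik_fn()
    }
  }
  bad <- !is.finite(dev)
  if (mean(bad) > 0.01)
    stop("more than 1% non-finite deviance draws (",
         sum(bad), "/", length(dev), ")", call. = FALSE)
  dev <- dev[!bad]
  dbar <- mean(dev)
  p_d <- dbar - plugin_deviance
  list(dic = dbar + p_d, p_d = p_d, n_nonfinite = sum(bad))
}

# plug-in deviance at posterior means of subject nodes, pooled over chains
.plugin_deviance <- function(posterior) {
  model <- posterior$model
  info <- posterior$nodes
  means <- apply(posterior$draws, 2, mean)
  ll <- 0
  idx <- which(info$kind == "subject")
  for (i in seq_along(model$subjects)) {
    s <- model$subjects[[i]]
    id <- model$subj_ids[i]
    rows <- idx[info$subj[idx] == id]
    x <- means[rows]
    L <- length(s$map)
    eta <- inv_logit(x[seq_len(L)])
    v <- x[L + seq_len(L)]
    a <- exp(x[2 * L + seq_len(L)])
    t0 <- exp(x[3 * L + 1])
    ll <- ll + cpp_session_loglik(s$pair, s$response, s$rt, s$feedback,
                                  s$cell, s$n_pairs, eta, v, a, t0, 0.5,
                                  1e-7)
  }
  -2 * ll
}

#' Fit one candidate RL-DDM
#'
#' Convenience wrapper: build the model, run the chain(s), compute DIC and
#' (for multi-chain runs) Gelman-Rubin diagnostics.
#'
#' @inheritParams run_mcmc
#' @param trial_log cohort trial log.
#' @param spec a [model_spec()] or its name.
#' @param priors see [default_priors()].
#' @return An object of class `rlddm_fit` with elements `posterior`, `dic`,
#'   `p_d`, `rhat` (NA for single-chain runs), `model_spec`, `converged`
#'   (`TRUE` when all Rhat <= 1.01, `NA` if not assessed).
#' @export
fit_rlddm <- function(trial_log, spec = "integrative", n_samples = 10000,
                      n_burn = 5000, n_chains = 1, seed = 1,
                      priors = default_priors()) {
  if (is.character(spec)) spec <- model_spec(spec)
  model <- build_model(spec, trial_log, priors)
  posterior <- run_mcmc(model, n_samples, n_burn, n_chains, seed)
  dic <- compute_dic(posterior)
  rhat <- if (n_chains >= 2) gelman_rubin(posterior) else NA
  converged <- if (n_chains >= 2) all(rhat <= 1.01, na.rm = TRUE) else NA
  structure(list(posterior = posterior, dic = dic$dic, p_d = dic$p_d,
                 rhat = rhat, model_spec = spec, converged = converged),
            class = "rlddm_fit")
}

#' @export
print.rlddm_fit <- function(x, ...) {
  cat("RL-DDM fit:", x$model_spec$label, "\n")
  cat(sprintf("DIC = %.1f (p_d = %.1f), %d chain(s) x %d draws\n", x$dic,
              x$p_d, x$posterior$n_chains,
              x$posterior$n_samples - x$posterior$n_burn))
  if (!all(is.na(x$rhat)))
    cat(sprintf("max Rhat = %.3f (converged: %s)\n", max(x$rhat),
                x$converged))
  invisible(x)
}

#' Extract group-level posterior draws
#'
#' Returns the draws of a parameter's group means across its cells, pooled
#' over chains, on the natural or sampling scale.  Natural-scale views
#' invert the sampling transforms (logistic for `eta`, exponential for `a`
#' and `t0`).
#'
#' @param posterior an `rlddm_posterior` or `rlddm_fit`.
#' @param param one of `"eta"`, `"v_scaling"`, `"a"`, `"t0"`.
#' @param scale `"natural"` or `"sampling"`.
#' @return Matrix of draws (rows) by cell (columns).
#' @export
extract_group <- function(posterior, param = "eta",
                          scale = c("natural", "sampling")) {
  if (inherits(posterior, "rlddm_fit")) posterior <- posterior$posterior
  stopifnot(inherits(posterior, "rlddm_posterior"))
  scale <- match.arg(scale)
  param <- match.arg(param, c("eta", "v_scaling", "a", "t0"))
  info <- posterior$nodes
  sel <- which(info$kind == "mu" & info$param == param)
  d <- posterior$draws[, sel, , drop = FALSE]
  m <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) d[, , ch,
                                                               drop = TRUE]))
  m <- matrix(m, ncol = length(sel),
              dimnames = list(NULL, if (param == "t0") "t0"
                                    else info$cell[sel]))
  if (scale == "natural") {
    m <- switch(param, eta = inv_logit(m), v_scaling = m, a = exp(m),
                t0 = exp(m))
  }
  m
}

#' Extract subject-level posterior means
#'
#' Posterior means of the subject-level nodes on the natural scale, one row
#' per subject and cell; used for parameter-recovery checks against a
#' cohort's truth table.
#'
#' @inheritParams extract_group
#' @return Data frame with `subj_idx`, `cell`, `param`, `mean`.
#' @export
subject_posterior_means <- function(posterior) {
  if (inherits(posterior, "rlddm_fit")) posterior <- posterior$posterior
  stopifnot(inherits(posterior, "rlddm_posterior"))
  info <- posterior$nodes
  means <- apply(posterior$draws, 2, mean)
  sel <- which(info$kind == "subject")
  nat <- means[sel]
  nat[info$param[sel] == "eta"] <- inv_logit(nat[info$param[sel] == "eta"])
  nat[info$param[sel] %in% c("a", "t0")] <-
    exp(nat[info$param[sel] %in% c("a", "t0")])
  data.frame(subj_idx = info$subj[sel], cell = info$cell[sel],
             param = info$param[sel], mean = unname(nat),
             stringsAsFactors = FALSE)
}
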