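# Candidate-model comparison by DIC and posterior predictive checks.

#' Fit the three candidate models and rank by DIC
#'
#' Fits the learning-context, goodness-of-fit and integrative models to the
#' same trial log and ranks them by DIC (rank 1 = lowest).  A candidate
#' failing the convergence flag is annotated in the table; the ranking is
#' still produced.
#'
#' @param trial_log cohort trial log.
#' @param n_samples,n_burn,n_chains,seed MCMC settings (see [run_mcmc()]).
#' @return A data frame of class `rlddm_comparison` with one row per
#'   candidate (`name`, `label`, `dic`, `p_d`, `max_rhat`, `converged`,
#'   `rank`) and the full fits in `attr(, "fits")`.
#' @export
fit_candidates <- function(trial_log, n_samples = 10000, n_burn = 5000,
                           n_chains = 1, seed = 1) {
  specs <- c("context", "fit", "integrative")
  fits <- lapply(specs, function(s)
    fit_rlddm(trial_log, s, n_samples = n_samples, n_burn = n_burn,
              n_chains = n_chains, seed = seed))
  names(fits) <- specs
  tab <- data.frame(
    name = specs,
    label = vapply(fits, function(f) f$model_spec$label, character(1)),
    dic = vapply(fits, function(f) f$dic, numeric(1)),
    p_d = vapply(fits, function(f) f$p_d, numeric(1)),
    max_rhat = vapply(fits, function(f)
      if (all(is.na(f$rhat))) NA_real_ else max(f$rhat), numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged) ||
                         is.na(f$converged), logical(1)),
    stringsAsFactors = FALSE)
  tab$rank <- rank(tab$dic, ties.method = "first")
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("rlddm_comparison", "data.frame")
  tab
}

# per-pair summary statistics: choice accuracy and RT deciles
.ppc_stats <- function(log) {
  probs <- seq(0.1, 0.9, by = 0.1)
  out <- lapply(sort(unique(log$pair)), function(p) {
    rows <- log$pair == p
    data.frame(pair = p,
               stat = c("accuracy", paste0("rt_q", probs * 100)),
               value = c(mean(log$response[rows]),
                         unname(quantile(log$rt[rows], probs))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# rebuild one subject's design from their own observed trials; session
# structure is matched exactly: the replicate runs the subject's observed
# number of blocks with the stopping criterion disabled, so predictive
# spread reflects parameters and trial noise, not re-rolled session lengths
.subject_design <- function(sl, template) {
  ids <- sort(unique(sl$pair))
  base <- template$pairs[match(ids, template$pairs$pair_id), , drop = FALSE]
  base$target_fit <- vapply(ids, function(p)
    sl$fit_of_target[sl$pair == p][1], character(1))
  base$criterion <- 2  # unattainable: replicate length is fixed
  d <- template
  d$pairs <- base
  d$learning_context <- sl$context[1]
  d$max_blocks <- max(sl$block)
  d
}

# one subject's natural-scale parameters at a single posterior draw,
# keyed by fit level
.subject_params_at_draw <- function(posterior, subj_id, draw, chain) {
  info <- posterior$nodes
  sel <- which(info$kind == "subject" & info$subj == subj_id)
  x <- posterior$draws[draw, sel, chain]
  param <- info$param[sel]
  cell <- info$cell[sel]
  by_fit <- function(p, trans) {
    i <- which(param == p)
    v <- trans(x[i])
    cl <- cell[i]
    vapply(.pst_fits, function(f) {
      hit <- grepl(f, cl, fixed = TRUE) | cl %in% .pst_contexts
      if (any(cl == f)) v[cl == f]
      else if (any(hit)) v[which(hit)[1]]
      else v[1]
    }, numeric(1))
  }
  parameter_set(eta = by_fit("eta", inv_logit),
                v_scaling = by_fit("v_scaling", identity),
                a = by_fit("a", exp),
                t0 = exp(x[param == "t0"]))
}

#' Posterior predictive check
#'
#' Simulates `n_datasets` replicate cohorts from the fitted posterior — one
#' joint posterior draw per dataset, each subject re-simulated with their
#' own drawn parameters under their observed design (context, pairs) and
#' their observed session length — and compares per-pair choice accuracy
#' and RT deciles with the observed data.  Conditioning on the observed
#' number of blocks (rather than re-rolling the accuracy-criterion
#' termination) keeps the predictive spread attributable to parameters and
#' trial-level noise; session length under criterion termination is highly
#' stochastic and would otherwise dominate pooled RT statistics.  A
#' statistic is covered when the observed value lies inside the central
#' 95% of its simulated distribution.
#'
#' @param fit an [fit_rlddm()] result.
#' @param trial_log the observed cohort log the model was fitted to.
#' @param design_template a [default_design()] supplying reward
#'   probabilities, criteria and block structure.
#' @param n_datasets number of simulated datasets (default 50).
#' @return A list of class `rlddm_ppc`: `table` (per pair and statistic:
#'   observed value, simulated 2.5/50/97.5% quantiles, coverage flag),
#'   `sims` (long data frame of all simulated statistics) and
#'   `coverage` (overall proportion covered).
#' @export
posterior_predictive_check <- function(fit, trial_log,
                                       design_template = default_design(),
                                       n_datasets = 50) {
  stopifnot(inherits(fit, "rlddm_fit"), n_datasets >= 1)
  posterior <- fit$posterior
  n_keep <- dim(posterior$draws)[1]
  n_ch <- dim(posterior$draws)[3]
  # spread the joint draws evenly over the retained chain(s)
  pick <- floor(seq(1, n_keep * n_ch, length.out = n_datasets))
  subj_ids <- posterior$model$subj_ids
  obs <- .ppc_stats(trial_log)
  sims <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    chain <- (pick[d] - 1L) %/% n_keep + 1L
    draw <- (pick[d] - 1L) %% n_keep + 1L
    logs <- lapply(subj_ids, function(id) {
      sl <- trial_log[trial_log$subj_idx == id, , drop = FALSE]
      pars <- .subject_params_at_draw(posterior, id, draw, chain)
      simulate_session(pars, .subject_design(sl, design_template),
                       subj_idx = id)
    })
    st <- .ppc_stats(do.call(rbind, logs))
    st$dataset <- d
    sims[[d]] <- st
  }
  sims <- do.call(rbind, sims)
  tab <- obs
  names(tab)[names(tab) == "value"] <- "observed"
  qs <- lapply(seq_len(nrow(tab)), function(i) {
    v <- sims$value[sims$pair == tab$pair[i] & sims$stat == tab$stat[i]]
    quantile(v, c(0.025, 0.5, 0.975))
  })
  qs <- do.call(rbind, qs)
  tab$sim_lo <- qs[, 1]; tab$sim_med <- qs[, 2]; tab$sim_hi <- qs[, 3]
  tab$covered <- tab$observed >= tab$sim_lo & tab$observed <= tab$sim_hi
  structure(list(table = tab, sims = sims, coverage = mean(tab$covered),
                 n_datasets = n_datasets),
            class = "rlddm_ppc")
}

#' @export
print.rlddm_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check: %d simulated datasets, %.0f%% of %d statistics covered\n",
              x$n_datasets, 100 * x$coverage, nrow(x$table)))
  invisible(x)
}
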