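# Reinforcement-learning layer: delta-rule values, trial-wise drift,
# session simulation, and the RL-DDM session log-likelihood.

#' Delta-rule value update
#'
#' `q' = q + eta * (feedback - q)`; only the chosen option's expected value
#' is updated after each trial.
#'
#' @param q current expected value.
#' @param feedback 0/1 outcome of the trial.
#' @param eta learning rate in (0, 1): the fraction of the prediction error
#'   incorporated into the updated value.
#' @return Updated expected value.
#' @examples
#' update_q(0.5, 1, 0.1)  # 0.55
#' @export
update_q <- function(q, feedback, eta) {
  if (any(eta < 0) || any(eta > 1))
    stop("`eta` must lie in [0, 1]", call. = FALSE)
  stopifnot(all(feedback %in% c(0, 1)))
  q + eta * (feedback - q)
}

#' Trial-wise drift rate
#'
#' `v = v_scaling * (q_target - q_other)`, signed toward the upper
#' (positively reinforced) boundary.  Early in learning the two expected
#' values are close, the drift is near zero and responses are slow and
#' near-random; as values separate the drift grows.
#'
#' @param q_target expected value of the positively reinforced face.
#' @param q_other expected value of the other face.
#' @param v_scaling drift-rate scaling (feedback sensitivity).
#' @return Drift rate.
#' @export
trial_drift <- function(q_target, q_other, v_scaling) {
  v_scaling * (q_target - q_other)
}

#' Subject-level RL-DDM parameter set
#'
#' One subject's parameters, indexed by the goodness-of-fit level of the
#' trial's target face (the within-subject factor; the learning context is
#' fixed within a session).  `eta`, `v_scaling` and `a` may be scalars
#' (shared across fit levels) or named vectors `c(high = , low = )`;
#' `t0` is always shared.
#'
#' @param eta learning rate(s) in (0, 1).
#' @param v_scaling drift-rate scaling(s).
#' @param a boundary separation(s), `> 0`.
#' @param t0 non-decision time (seconds), `>= 0`.
#' @return A list of class `rlddm_params` with `eta`, `v_scaling`, `a`
#'   expanded to named high/low vectors.
#' @export
parameter_set <- function(eta, v_scaling, a, t0) {
  expand <- function(x, nm) {
    if (length(x) == 1) x <- c(high = unname(x), low = unname(x))
    if (!all(.pst_fits %in% names(x)))
      stop("`", nm, "` must be a scalar or named c(high=, low=)",
           call. = FALSE)
    x[.pst_fits]
  }
  eta <- expand(eta, "eta"); v_scaling <- expand(v_scaling, "v_scaling")
  a <- expand(a, "a")
  if (any(eta <= 0) || any(eta >= 1))
    stop("`eta` must be in (0, 1)", call. = FALSE)
  if (any(a <= 0)) stop("`a` must be > 0", call. = FALSE)
  if (t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  structure(list(eta = eta, v_scaling = v_scaling, a = a, t0 = t0),
            class = "rlddm_params")
}

.cells_of_design <- function(design) {
  match(design$pairs$target_fit, .pst_fits)  # 1 = high, 2 = low
}

#' Simulate one PST session
#'
#' Runs a single subject through the task: on each trial the drift rate is
#' built from the pair's current expected values, the choice and RT are
#' drawn from the two-boundary diffusion, feedback is Bernoulli with the
#' pair's reward probability (for target choices; its complement otherwise),
#' and the chosen face's value is updated by the delta rule.  Blocks end
#' after `block_length` trials and the session stops once every pair meets
#' its accuracy criterion or after `max_blocks` blocks.
#'
#' @param params an [parameter_set()] object.
#' @param design a [default_design()] object.
#' @param subj_idx subject identifier written into the log.
#' @param policy `"ddm"` (default) draws choices from the diffusion;
#'   `"always_target"` / `"always_other"` force the choice (RTs then come
#'   from the conditional first-passage law), useful for exercising the
#'   termination rules.
#' @param feedback_schedule `"bernoulli"` (default) draws feedback i.i.d.
#'   per trial; `"exact"` pre-shuffles outcomes so each pair's target is
#'   correct on exactly `round(p * presentations)` trials per block.
#' @param ngrid grid resolution of the per-trial RT sampler.
#' @return A trial-log data frame (see [read_trial_log()]).
#' @export
simulate_session <- function(params, design, subj_idx = 1,
                             policy = c("ddm", "always_target",
                                        "always_other"),
                             feedback_schedule = c("bernoulli", "exact"),
                             ngrid = 256) {
  stopifnot(inherits(params, "rlddm_params"), inherits(design, "pst_design"))
  policy <- match.arg(policy)
  feedback_schedule <- match.arg(feedback_schedule)
  pol <- match(policy, c("ddm", "always_target", "always_other")) - 1L
  cell <- .cells_of_design(design) - 1L
  out <- cpp_simulate_session(design$pairs$p_reward_target,
                              design$pairs$criterion, cell,
                              unname(params$eta), unname(params$v_scaling),
                              unname(params$a), params$t0, 0.5,
                              design$block_length, design$max_blocks, pol,
                              as.integer(ngrid), 1e-7,
                              match(feedback_schedule,
                                    c("bernoulli", "exact")) - 1L)
  n <- length(out$pair)
  data.frame(subj_idx = subj_idx, trial = seq_len(n), block = out$block,
             pair = design$pairs$pair_id[out$pair + 1L],
             response = out$response, rt = out$rt, feedback = out$feedback,
             context = design$learning_context,
             fit_of_target = design$pairs$target_fit[out$pair + 1L],
             stringsAsFactors = FALSE)
}

#' RL-DDM session log-likelihood
#'
#' Replays the subject's expected values deterministically from the logged
#' feedback sequence (values are pair-local, so only each pair's own trial
#' order matters) and sums the Wiener log density of each (choice, RT) at
#' the trial's drift rate.  Any `rt <= t0` yields `-Inf` with attribute
#' `invalid_rt = TRUE` rather than an error, so samplers can reject such
#' proposals.
#'
#' @param trial_log one subject's trials, in chronological order.
#' @param params an [parameter_set()] object.
#' @param design a [default_design()] object.
#' @return Scalar log-likelihood.
#' @export
session_loglik <- function(trial_log, params, design) {
  stopifnot(inherits(params, "rlddm_params"), inherits(design, "pst_design"))
  pair <- match(trial_log$pair, design$pairs$pair_id)
  if (anyNA(pair)) stop("log contains pairs not in the design", call. = FALSE)
  cell <- .cells_of_design(design)[pair]
  ll <- cpp_session_loglik(pair - 1L, as.integer(trial_log$response),
                           as.numeric(trial_log$rt),
                           as.integer(trial_log$feedback), cell - 1L,
                           nrow(design$pairs), unname(params$eta),
                           unname(params$v_scaling), unname(params$a),
                           params$t0, 0.5, 1e-7)
  if (!is.finite(ll) && any(trial_log$rt <= params$t0))
    attr(ll, "invalid_rt") <- TRUE
  ll
}
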