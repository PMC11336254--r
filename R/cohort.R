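# Synthetic cohort generator: hierarchical ground truth -> simulated study.

.cell_grid <- function() {
  expand.grid(context = .pst_contexts, fit = .pst_fits,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.cell_matrix <- function(stereo_high, stereo_low, counter_high, counter_low) {
  m <- matrix(c(stereo_high, stereo_low, counter_high, counter_low),
              nrow = 2, byrow = TRUE,
              dimnames = list(.pst_contexts, .pst_fits))
  m
}

#' Group-level ground truth for a synthetic cohort
#'
#' Describes the population that subjects are drawn from: a mean per
#' parameter and condition cell (2 learning contexts x 2 goodness-of-fit
#' levels) plus a between-subject SD per parameter.  Each subject gets one
#' normal deviation per parameter on its sampling scale, shared across
#' cells, so condition effects enter through the cell means only.  Means
#' are given on the natural scale; deviations live on the sampling scales
#' used throughout the package — log-odds for `eta`, natural for
#' `v_scaling`, log for `a` and `t0` — which keeps every draw inside the
#' parameter space.
#'
#' @param eta_mean,v_mean,a_mean 2x2 matrices (contexts x fit levels) of
#'   natural-scale cell means, as built by [matrix()] with dimnames
#'   `list(c("stereotypic","counter-stereotypic"), c("high","low"))`.
#' @param t0_mean scalar natural-scale non-decision-time mean (seconds).
#' @param eta_sd,v_sd,a_sd,t0_sd between-subject SDs on the sampling scales
#'   (log-odds, natural, log, log respectively), `>= 0`.
#' @param n_per_context subjects per learning context.
#' @param label free-text description.
#' @return A list of class `rlddm_group_truth`.
#' @export
group_truth <- function(eta_mean, v_mean, a_mean, t0_mean = 0.35,
                        eta_sd = 0.4, v_sd = 0.6, a_sd = 0.12, t0_sd = 0.15,
                        n_per_context = 40, label = "custom") {
  chk <- function(m, nm, lo = -Inf, hi = Inf) {
    if (!is.matrix(m) || !identical(dim(m), c(2L, 2L)))
      stop("`", nm, "` must be a 2x2 matrix (contexts x fit levels)",
           call. = FALSE)
    if (any(m <= lo) || any(m >= hi))
      stop("`", nm, "` outside its natural range", call. = FALSE)
    dimnames(m) <- list(.pst_contexts, .pst_fits)
    m
  }
  eta_mean <- chk(eta_mean, "eta_mean", 0, 1)
  v_mean <- chk(v_mean, "v_mean")
  a_mean <- chk(a_mean, "a_mean", 0)
  if (t0_mean <= 0) stop("`t0_mean` must be > 0", call. = FALSE)
  sds <- c(eta_sd, v_sd, a_sd, t0_sd)
  if (any(sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (n_per_context < 1) stop("`n_per_context` must be >= 1", call. = FALSE)
  structure(list(eta_mean = eta_mean, v_mean = v_mean, a_mean = a_mean,
                 t0_mean = t0_mean, eta_sd = eta_sd, v_sd = v_sd,
                 a_sd = a_sd, t0_sd = t0_sd,
                 n_per_context = as.integer(n_per_context), label = label),
            class = "rlddm_group_truth")
}

#' Cohort presets
#'
#' Named ground truths whose qualitative ordering matches each experiment's
#' learning-rate findings: the surprising cell learns faster (in the
#' counter-stereotypic context the high-fit target, in the stereotypic
#' context the low-fit target), with the surprise advantage larger in the
#' counter-stereotypic context.  `preset_expt1()` additionally carries
#' larger drift scaling for expected targets and larger boundary separation
#' in the counter-stereotypic context; `preset_expt2()` carries larger
#' drift scaling and boundary separation in the stereotypic context.
#' Effect magnitudes are synthetic (documented generator choices, not
#' estimates); `n_per_context` defaults to 40 for desk-scale use.
#'
#' @param n_per_context subjects per learning context.
#' @return A [group_truth()] object.
#' @export
preset_expt1 <- function(n_per_context = 40) {
  group_truth(
    eta_mean = .cell_matrix(0.10, 0.20, 0.30, 0.15),
    v_mean   = .cell_matrix(3.5, 2.5, 2.5, 3.5),
    a_mean   = .cell_matrix(1.8, 1.8, 2.2, 2.2),
    n_per_context = n_per_context, label = "expt1")
}

#' @rdname preset_expt1
#' @export
preset_expt2 <- function(n_per_context = 40) {
  group_truth(
    eta_mean = .cell_matrix(0.10, 0.20, 0.30, 0.15),
    v_mean   = .cell_matrix(3.3, 3.3, 2.7, 2.7),
    a_mean   = .cell_matrix(2.2, 2.2, 1.9, 1.9),
    n_per_context = n_per_context, label = "expt2")
}

#' Generate a synthetic cohort
#'
#' Draws subject-level parameters from the group truth — a normal
#' subject-level deviation per parameter on its sampling scale, shared
#' across condition cells, around the cell-specific means — assigns the
#' between-subject learning context alternately (and the counterbalance
#' group alternately within context), and simulates one
#' criterion-terminated PST session per subject.  Uses
#' R's RNG: call `set.seed()` first for reproducibility.
#'
#' @param truth a [group_truth()] object.
#' @param design_template a [default_design()] whose pair structure, block
#'   length and termination settings every subject shares (context and
#'   counterbalance are overridden per subject).
#' @param sessions if `FALSE`, draw subject parameters but skip session
#'   simulation (`log` is then `NULL`); useful for checking the generator's
#'   own distributional properties cheaply.
#' @return List with `log` (trial-log data frame for the whole cohort) and
#'   `truth_table` (one row per subject and fit level with the natural-scale
#'   parameters actually drawn).
#' @export
generate_cohort <- function(truth, design_template = default_design(),
                            sessions = TRUE) {
  stopifnot(inherits(truth, "rlddm_group_truth"),
            inherits(design_template, "pst_design"))
  n <- truth$n_per_context
  subjects <- data.frame(
    subj_idx = seq_len(2L * n),
    context = rep(.pst_contexts, n),          # alternate assignment
    cb_group = rep(c(1L, 2L), length.out = 2L * n))
  logs <- vector("list", nrow(subjects))
  truths <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    ctx <- subjects$context[i]
    # one subject-level deviation per parameter, shared across fit cells
    # (random intercept); cell contrasts enter through the means only, so a
    # truth with equal cell means yields genuinely cell-free subjects
    draw_cell <- function(mean_mat, sdev, trans, inv) {
      z <- rnorm(1, 0, sdev)
      vapply(.pst_fits, function(f)
        inv(trans(mean_mat[ctx, f]) + z), numeric(1))
    }
    eta <- draw_cell(truth$eta_mean, truth$eta_sd, logit, inv_logit)
    v <- draw_cell(truth$v_mean, truth$v_sd, identity, identity)
    a <- draw_cell(truth$a_mean, truth$a_sd, log, exp)
    t0 <- exp(rnorm(1, log(truth$t0_mean), truth$t0_sd))
    pars <- parameter_set(eta = eta, v_scaling = v, a = a, t0 = t0)
    if (sessions) {
      design <- default_design(ctx, subjects$cb_group[i],
                               n_pair_sets = if (nrow(design_template$pairs) == 3) 1 else 2,
                               block_length = design_template$block_length,
                               max_blocks = design_template$max_blocks)
      logs[[i]] <- simulate_session(pars, design,
                                    subj_idx = subjects$subj_idx[i])
    }
    truths[[i]] <- data.frame(subj_idx = subjects$subj_idx[i], context = ctx,
                              fit = .pst_fits, eta = unname(eta),
                              v_scaling = unname(v), a = unname(a), t0 = t0,
                              stringsAsFactors = FALSE)
  }
  truth_table <- do.call(rbind, truths)
  rownames(truth_table) <- NULL
  log <- NULL
  if (sessions) {
    log <- do.call(rbind, logs)
    rownames(log) <- NULL
    validate_trial_log(log)
  }
  list(log = log, truth_table = truth_table)
}
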