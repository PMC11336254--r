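# Shared fixtures: tiny designs, logs and hand-built posterior objects.

tiny_log <- function() {
  data.frame(
    subj_idx = 1L, trial = 1:3, block = 1L,
    pair = c("AB", "CD", "AB"),
    response = c(1L, 0L, 1L), rt = c(0.8, 1.1, 0.65),
    feedback = c(1L, 0L, 1L),
    context = "stereotypic", fit_of_target = "high",
    stringsAsFactors = FALSE)
}

# a session of exactly n trials (criterion never evaluated before the single
# block ends)
fixed_length_session <- function(params, n, seed = 1,
                                 context = "stereotypic") {
  design <- default_design(context, 1, 1, block_length = n, max_blocks = 1)
  set.seed(seed)
  simulate_session(params, design)
}

# minimal posterior object carrying only group-mean eta nodes, for
# arithmetic tests of the contrast machinery
fake_eta_posterior <- function(eta_cells, n_draws = 2) {
  cells <- names(eta_cells)
  info <- data.frame(node = paste0("mu_eta[", cells, "]"), kind = "mu",
                     param = "eta", cell = cells, subj = NA,
                     stringsAsFactors = FALSE)
  draws <- array(rep(qlogis(unname(eta_cells)), each = n_draws),
                 c(n_draws, length(cells), 1),
                 dimnames = list(NULL, info$node, NULL))
  structure(list(draws = draws, nodes = info, n_chains = 1),
            class = "rlddm_posterior")
}

# truth with learning-context effects only (no goodness-of-fit effects),
# used for model-recovery checks
context_only_truth <- function(n_per_context = 12) {
  cm <- function(s, c) matrix(c(s, s, c, c), nrow = 2, byrow = TRUE,
                              dimnames = list(c("stereotypic",
                                                "counter-stereotypic"),
                                              c("high", "low")))
  group_truth(eta_mean = cm(0.12, 0.25), v_mean = cm(3.3, 2.7),
              a_mean = cm(1.8, 2.2), n_per_context = n_per_context,
              label = "context-only")
}
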