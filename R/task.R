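# Probabilistic selection task: design, blockwise termination, trial logs.

#' Default probabilistic selection task design
#'
#' Builds the standard PST structure: three same-sex face pairs per set with
#' reward probabilities 0.80/0.70/0.60 for the positively reinforced (target)
#' face and blockwise accuracy criteria 0.60/0.55/0.50.  A session presents
#' each pair equally often within 120-trial blocks and stops once every
#' pair's block accuracy reaches its criterion, or after four blocks
#' (480 trials).
#'
#' Goodness-of-stereotype-fit of the target face is assigned by the
#' counterbalance rule: group 1 reinforces high-fit female and low-fit male
#' faces, group 2 the reverse.
#'
#' @param learning_context `"stereotypic"` or `"counter-stereotypic"`;
#'   between-subject factor describing whether the to-be-learned
#'   associations confirm or violate gender stereotypes.
#' @param counterbalance_group 1 or 2; which fit level is positively
#'   reinforced for each face sex.
#' @param n_pair_sets 1 (three pairs of one face sex) or 2 (three female and
#'   three male pairs, the default).
#' @param block_length trials per learning block; must be divisible by the
#'   number of pairs.
#' @param max_blocks maximum number of learning blocks.
#' @return An object of class `pst_design`: a list with a `pairs` data frame
#'   (`pair_id`, `p_reward_target`, `criterion`, `face_sex`, `target_fit`)
#'   and the session-level settings.
#' @examples
#' d <- default_design("stereotypic", 1, 1)
#' d$pairs
#' @export
default_design <- function(learning_context = "stereotypic",
                           counterbalance_group = 1,
                           n_pair_sets = 2,
                           block_length = 120,
                           max_blocks = 4) {
  learning_context <- match.arg(learning_context, .pst_contexts)
  if (!counterbalance_group %in% c(1, 2))
    stop("`counterbalance_group` must be 1 or 2", call. = FALSE)
  if (!n_pair_sets %in% c(1, 2))
    stop("`n_pair_sets` must be 1 or 2", call. = FALSE)

  p <- c(0.80, 0.70, 0.60)
  crit <- c(0.60, 0.55, 0.50)
  base <- c("AB", "CD", "EF")
  sexes <- c("female", "male")[seq_len(n_pair_sets)]
  pairs <- do.call(rbind, lapply(sexes, function(sx) {
    id <- if (n_pair_sets == 1) base
          else paste0(base, "_", toupper(substr(sx, 1, 1)))
    # group 1: female targets high-fit, male targets low-fit; group 2 flipped
    fit <- if ((sx == "female") == (counterbalance_group == 1)) "high" else "low"
    data.frame(pair_id = id, p_reward_target = p, criterion = crit,
               face_sex = sx, target_fit = fit, stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  if (block_length %% nrow(pairs) != 0)
    stop("`block_length` must be divisible by the number of pairs",
         call. = FALSE)
  structure(list(pairs = pairs, block_length = block_length,
                 max_blocks = max_blocks,
                 learning_context = learning_context,
                 counterbalance_group = counterbalance_group),
            class = "pst_design")
}

#' @export
print.pst_design <- function(x, ...) {
  cat("PST design:", nrow(x$pairs), "pairs,",
      x$block_length, "trials/block, max", x$max_blocks, "blocks\n")
  cat("Learning context:", x$learning_context,
      "| counterbalance group:", x$counterbalance_group, "\n")
  print(x$pairs)
  invisible(x)
}

#' Blockwise accuracy-criterion check
#'
#' Evaluates one completed learning block: accuracy per pair is the
#' proportion of choices of the positively reinforced face, and the session
#' stops when every pair's accuracy meets its criterion (inclusive
#' thresholds, evaluated on the just-completed block only).
#'
#' @param block_records data frame with columns `pair` and `response`
#'   containing exactly one block of one subject's trials.
#' @param design a [default_design()] object.
#' @return List with `decision` (`"stop"` or `"continue"`) and `accuracy`,
#'   a named vector of per-pair block accuracies.
#' @export
check_block_criterion <- function(block_records, design) {
  stopifnot(inherits(design, "pst_design"))
  if (nrow(block_records) != design$block_length)
    stop("block must contain exactly ", design$block_length, " trials",
         call. = FALSE)
  present <- design$pairs$pair_id %in% block_records$pair
  if (!all(present))
    stop("malformed log: pair(s) absent from block: ",
         paste(design$pairs$pair_id[!present], collapse = ", "),
         call. = FALSE)
  acc <- vapply(design$pairs$pair_id, function(id)
    mean(block_records$response[block_records$pair == id]), numeric(1))
  decision <- if (all(acc >= design$pairs$criterion)) "stop" else "continue"
  list(decision = decision, accuracy = acc)
}

.log_columns <- c("subj_idx", "trial", "block", "pair", "response", "rt",
                  "feedback", "context", "fit_of_target")

#' Validate a trial log
#'
#' Checks the trial-log contract: required columns present, reaction times
#' strictly positive, binary response/feedback codes, strictly increasing
#' trial indices within subject, and (when a design is supplied) only known
#' pair ids.  Offending rows are listed in the error message.
#'
#' @param log trial-log data frame (see [read_trial_log()] for columns).
#' @param design optional [default_design()] to check pair ids against.
#' @return The validated log, invisibly.
#' @export
validate_trial_log <- function(log, design = NULL) {
  missing_cols <- setdiff(.log_columns, names(log))
  if (length(missing_cols))
    stop("trial log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!(log$rt > 0))
  if (length(bad))
    stop("non-positive rt at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(!(log$response %in% c(0, 1)) | !(log$feedback %in% c(0, 1)))
  if (length(bad))
    stop("non-binary response/feedback at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  for (s in unique(log$subj_idx)) {
    tr <- log$trial[log$subj_idx == s]
    if (any(diff(tr) <= 0))
      stop("trial index not strictly increasing for subject ", s,
           call. = FALSE)
  }
  if (!is.null(design)) {
    unknown <- setdiff(unique(log$pair), design$pairs$pair_id)
    if (length(unknown))
      stop("unknown pair id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  invisible(log)
}

#' Read / write trial logs
#'
#' Trial logs are comma-separated UTF-8 text with header
#' `subj_idx,trial,block,pair,response,rt,feedback,context,fit_of_target`.
#' Reaction times are in seconds; `response` is 1 when the positively
#' reinforced face was chosen (the diffusion's upper boundary) and 0
#' otherwise; `feedback` is 1 for "Correct".  `write_trial_log()` then
#' `read_trial_log()` round-trips field-for-field.
#'
#' @param path file path.
#' @param log trial-log data frame.
#' @param design optional design used for pair-id validation on read.
#' @return `read_trial_log()` returns the validated data frame.
#' @export
read_trial_log <- function(path, design = NULL) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_log(log, design)
  log
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(log, path) {
  validate_trial_log(log)
  utils::write.csv(log[, .log_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Simulate repeated presentations of a single pair
#'
#' Presents one pair `n` times to a fixed-choice agent and draws feedback
#' from the pair's reward schedule: Bernoulli(`p_reward_target`) when the
#' target is chosen, Bernoulli(1 - `p_reward_target`) otherwise.  Used to
#' check the feedback generator against the nominal 80/70/60% schedule.
#'
#' @param design a [default_design()] object.
#' @param pair_id which pair to present.
#' @param n number of trials.
#' @param choose_target if `TRUE` the agent always picks the positively
#'   reinforced face.
#' @return Data frame with `trial`, `response`, `feedback`.
#' @export
simulate_pair_feedback <- function(design, pair_id, n, choose_target = TRUE) {
  stopifnot(inherits(design, "pst_design"), n >= 1)
  row <- match(pair_id, design$pairs$pair_id)
  if (is.na(row)) stop("unknown pair id: ", pair_id, call. = FALSE)
  p <- design$pairs$p_reward_target[row]
  pr <- if (choose_target) p else 1 - p
  data.frame(trial = seq_len(n),
             response = as.integer(choose_target),
             feedback = rbinom(n, 1, pr))
}
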