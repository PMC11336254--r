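# Directional posterior tests, prediction-error contrasts, reports.

#' Directional posterior probability
#'
#' Proportion of paired posterior draws contrary to the stated direction:
#' for "A > B" the proportion with `a - b <= 0` (ties count as contrary,
#' the conservative rule), symmetrically for "A < B".  Small values are
#' strong evidence for the stated direction.
#'
#' @param draws_a,draws_b equal-length paired posterior draws.
#' @param direction `"A>B"` or `"A<B"`.
#' @return Probability in \[0, 1\].
#' @examples
#' p_bayes(c(-1, 0, 1, 2), rep(0, 4), "A>B")  # 0.5
#' @export
p_bayes <- function(draws_a, draws_b, direction = c("A>B", "A<B")) {
  direction <- match.arg(direction)
  if (length(draws_a) != length(draws_b))
    stop("`draws_a` and `draws_b` must have equal length", call. = FALSE)
  d <- draws_a - draws_b
  if (direction == "A>B") mean(d <= 0) else mean(d >= 0)
}

#' Complementary posterior odds
#'
#' Converts a directional posterior probability into the evidence ratio
#' `BF10 = (1 - p) / p`.  With `rounded = TRUE` the default reporting
#' convention is applied: nearest integer (half up) for values >= 1, raw
#' otherwise.  `p = 0` returns `Inf` (reported as "> 1000" by
#' [format_bf()]), `p = 1` returns 0.
#'
#' @param p directional posterior probability in \[0, 1\].
#' @param rounded apply the integer reporting convention.
#' @return Evidence ratio.
#' @examples
#' bf_from_pbayes(0.031, rounded = TRUE)  # 31
#' bf_from_pbayes(0.002, rounded = TRUE)  # 499
#' @export
bf_from_pbayes <- function(p, rounded = FALSE) {
  if (any(p < 0) || any(p > 1))
    stop("`p` must be in [0, 1]", call. = FALSE)
  bf <- ifelse(p == 0, Inf, (1 - p) / p)
  if (rounded) bf <- ifelse(is.finite(bf) & bf >= 1, floor(bf + 0.5), bf)
  bf
}

#' Format an evidence ratio for reporting
#'
#' Evidence ratios implying `p < 0.001` are printed as `"> 1000"`; values
#' `>= 1` as the nearest integer; smaller values with two decimals.
#'
#' @param p directional posterior probability.
#' @return Character scalar.
#' @export
format_bf <- function(p) {
  if (p < 0.001) return("> 1000")
  bf <- bf_from_pbayes(p, rounded = TRUE)
  if (bf >= 1) sprintf("%d", as.integer(bf)) else sprintf("%.2f", bf)
}

#' Directional test of two posterior cells
#'
#' @param draws_a,draws_b paired draws for cells A and B.
#' @param direction `"A>B"` or `"A<B"`.
#' @param cells optional length-2 character labels.
#' @return List of class `rlddm_test`: `cells`, `direction`, `p_bayes`,
#'   `bf10` (raw), `bf10_reported`.
#' @export
directional_test <- function(draws_a, draws_b, direction = "A>B",
                             cells = c("A", "B")) {
  p <- p_bayes(draws_a, draws_b, direction)
  structure(list(cells = cells, direction = direction, p_bayes = p,
                 bf10 = bf_from_pbayes(p), bf10_reported = format_bf(p)),
            class = "rlddm_test")
}

#' @export
print.rlddm_test <- function(x, ...) {
  dir <- if (x$direction == "A>B") ">" else "<"
  cat(sprintf("p_Bayes[%s %s %s] = %.3f, BF10 = %s\n", x$cells[1], dir,
              x$cells[2], x$p_bayes, x$bf10_reported))
  invisible(x)
}

#' Prediction-error contrast across learning contexts
#'
#' Surprise scores per posterior draw, on the natural learning-rate scale:
#' in the stereotypic context the low-fit target is the surprising one, so
#' `delta_stereotypic = eta(low) - eta(high)`; in the counter-stereotypic
#' context the high-fit target is surprising, so
#' `delta_counter = eta(high) - eta(low)`.  The contrast compares the two
#' surprise advantages with a directional test of
#' `delta_counter > delta_stereotypic`.
#'
#' @param posterior an `rlddm_posterior` or `rlddm_fit` from the
#'   integrative model (all four eta cells are required).
#' @return List of class `rlddm_contrast`: per-draw `delta_stereotypic`,
#'   `delta_counter`, `difference`, and `test`.
#' @export
prediction_error_contrast <- function(posterior) {
  if (inherits(posterior, "rlddm_fit")) posterior <- posterior$posterior
  eta <- extract_group(posterior, "eta", scale = "natural")
  need <- paste(rep(.pst_contexts, each = 2), .pst_fits, sep = ":")
  if (!all(need %in% colnames(eta)))
    stop("the prediction-error contrast requires the integrative model ",
         "(2 x 2 learning-rate cells)", call. = FALSE)
  d_st <- eta[, "stereotypic:low"] - eta[, "stereotypic:high"]
  d_ct <- eta[, "counter-stereotypic:high"] - eta[, "counter-stereotypic:low"]
  diff <- d_ct - d_st
  test <- directional_test(d_ct, d_st, "A>B",
                           cells = c("counter-stereotypic surprise",
                                     "stereotypic surprise"))
  structure(list(delta_stereotypic = d_st, delta_counter = d_ct,
                 difference = diff, test = test),
            class = "rlddm_contrast")
}

#' Analysis report
#'
#' Writes a deterministic report bundle: posterior summaries (means and 95%
#' credible intervals per group-level parameter cell, natural scale),
#' directional tests with `p_Bayes` and the reported evidence ratio, the
#' optional prediction-error contrast and model-comparison table, as both
#' machine-readable JSON (`report.json`) and CSV tables.
#'
#' @param fit an [fit_rlddm()] result.
#' @param tests optional list of [directional_test()] results.
#' @param contrast optional [prediction_error_contrast()] result.
#' @param comparison optional [fit_candidates()] table.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the path of the JSON report.
#' @export
report <- function(fit, tests = NULL, contrast = NULL, comparison = NULL,
                   out_dir) {
  stopifnot(inherits(fit, "rlddm_fit"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- do.call(rbind, lapply(c("eta", "v_scaling", "a", "t0"),
                                function(p) {
    m <- extract_group(fit, p, "natural")
    data.frame(param = p, cell = colnames(m), mean = colMeans(m),
               cri_lo = apply(m, 2, quantile, 0.025),
               cri_hi = apply(m, 2, quantile, 0.975),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  write.csv(summ, file.path(out_dir, "posterior_summary.csv"),
            row.names = FALSE)
  payload <- list(
    model = fit$model_spec$label,
    dic = fit$dic, p_d = fit$p_d,
    posterior_summary = summ)
  if (!is.null(tests)) {
    payload$tests <- lapply(tests, function(t)
      list(cells = t$cells, direction = t$direction, p_bayes = t$p_bayes,
           bf10 = t$bf10, bf10_reported = t$bf10_reported))
  }
  if (!is.null(contrast)) {
    payload$prediction_error_contrast <- list(
      delta_stereotypic_mean = mean(contrast$delta_stereotypic),
      delta_counter_mean = mean(contrast$delta_counter),
      difference_mean = mean(contrast$difference),
      p_bayes = contrast$test$p_bayes,
      bf10_reported = contrast$test$bf10_reported)
  }
  if (!is.null(comparison)) {
    tab <- as.data.frame(comparison)
    write.csv(tab, file.path(out_dir, "comparison.csv"), row.names = FALSE)
    payload$comparison <- tab
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
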