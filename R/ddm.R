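# Two-boundary Wiener diffusion: density, absorption probability, sampler.

#' Diffusion parameter set
#'
#' Container for the two-boundary Wiener process with drift `v` (signed
#' toward the upper boundary, evidence units per second), boundary
#' separation `a`, relative starting point `z_rel` (0.5 = unbiased, the
#' model default), non-decision time `t0` in seconds, and diffusion
#' coefficient fixed at `s = 1` (the scaling convention that identifies the
#' remaining parameters).
#'
#' @param v drift rate.
#' @param a boundary separation, `> 0`.
#' @param z_rel relative starting point in (0, 1).
#' @param t0 non-decision time in seconds, `>= 0`.
#' @return A list of class `ddm_params`.
#' @export
ddm_params <- function(v, a, z_rel = 0.5, t0 = 0) {
  if (!all(is.finite(c(v, a, z_rel, t0))))
    stop("diffusion parameters must be finite", call. = FALSE)
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (z_rel <= 0 || z_rel >= 1) stop("`z_rel` must be in (0,1)", call. = FALSE)
  if (t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  structure(list(v = v, a = a, z_rel = z_rel, t0 = t0, s = 1),
            class = "ddm_params")
}

#' Log density of the Wiener first-passage time
#'
#' Log of the defective first-passage-time density of a two-boundary Wiener
#' diffusion at time `t` and the given boundary.  The density is evaluated
#' through two series expansions of the normalised zero-drift density — a
#' small-time expansion in Gaussian terms and a large-time expansion in
#' sinusoidal terms — with the number of terms chosen adaptively to reach
#' absolute tolerance `eps`, and the expansion with the smaller term bound
#' selected at each time point.  Times `t <= t0` have zero density
#' (`-Inf` log density), not an error.
#'
#' @param t vector of response times (seconds).
#' @param boundary `"upper"` or `"lower"` (recycled); the upper boundary is
#'   the positively reinforced response under the package's response coding.
#' @param params a [ddm_params()] object.
#' @param eps absolute tolerance of the series truncation.
#' @param method `"auto"` picks the cheaper expansion per time point;
#'   `"small"` / `"large"` force one expansion (used to verify continuity
#'   across the switch).
#' @return Vector of log densities.
#' @examples
#' p <- ddm_params(v = 0.5, a = 2, t0 = 0.3)
#' wiener_logpdf(1.0, "upper", p)
#' @export
wiener_logpdf <- function(t, boundary, params, eps = 1e-7,
                          method = c("auto", "small", "large")) {
  stopifnot(inherits(params, "ddm_params"))
  method <- match.arg(method)
  boundary <- match.arg(boundary, c("upper", "lower"), several.ok = TRUE)
  up <- as.integer(rep_len(boundary == "upper", length(t)))
  force <- match(method, c("auto", "small", "large")) - 1L
  cpp_wiener_logpdf(as.numeric(t), up, params$v, params$a, params$z_rel,
                    params$t0, eps, force)
}

#' Probability of absorption at the upper boundary
#'
#' Closed form `(1 - exp(-2 v z a / s^2)) / (1 - exp(-2 v a / s^2))` with
#' `z = z_rel` on the relative scale; the driftless limit is `z_rel`.
#'
#' @inheritParams wiener_logpdf
#' @return Scalar probability.
#' @examples
#' upper_prob(ddm_params(v = 1, a = 2))  # 1 / (1 + exp(-2))
#' @export
upper_prob <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  cpp_upper_prob(params$v, params$a, params$z_rel)
}

#' Sample first-passage times
#'
#' Draws `n` (boundary, time) pairs from the joint first-passage law.  The
#' boundary is drawn from the exact absorption probability and the
#' conditional time by inverse-CDF lookup on a quadratically spaced grid of
#' the integrated series density.  Uses R's RNG, so `set.seed()` makes draws
#' reproducible.
#'
#' @inheritParams wiener_logpdf
#' @param n number of draws.
#' @param ngrid grid resolution of the inverse-CDF table.
#' @return Data frame with `response` (1 = upper) and `rt` (`> t0`).
#' @export
sample_fpt <- function(params, n, ngrid = 2048, eps = 1e-7) {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  out <- cpp_sample_fpt(as.integer(n), params$v, params$a, params$z_rel,
                        params$t0, as.integer(ngrid), eps)
  data.frame(response = out$response, rt = out$rt)
}

#' Euler-Maruyama reference simulator
#'
#' Brute-force first-passage sampling by discretising the diffusion path
#' with fixed step `dt` and Gaussian increments, using a self-contained
#' counter-based RNG.  Slow and slightly biased (boundary crossings between
#' steps are missed at order `sqrt(dt)`); kept as an independent reference
#' against which the series density, absorption probability and grid
#' sampler are checked.
#'
#' @inheritParams sample_fpt
#' @param dt Euler time step (seconds).
#' @param seed integer seed of the simulator's own RNG.
#' @return Data frame with `response` and `rt`.
#' @export
euler_fpt <- function(params, n, dt = 1e-4, seed = 1) {
  stopifnot(inherits(params, "ddm_params"))
  out <- cpp_euler_fpt(as.integer(n), params$v, params$a, params$z_rel,
                       params$t0, dt, as.integer(seed))
  data.frame(response = out$response, rt = out$rt)
}
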