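#' Stimulus set specification
#'
#' Configuration for generating a lottery set whose model-implied mean
#' safe-choice probability equals a prescribed target (for example 0.70 for
#' a safe-default group and 0.30 for a risky-default group). Safe
#' probabilities are drawn from `P_grid`, safe magnitudes uniformly from
#' `a_range`, and the risky amount is solved analytically from the choice
#' model so that each trial's model-implied safe-choice probability equals
#' the (possibly jittered) per-trial target.
#'
#' @param target_ps Target safe-choice probability in (0, 1).
#' @param n_trials Number of lottery pairs.
#' @param frame `"gain"` or `"loss"`.
#' @param P_grid Allowed safe probabilities, all within (0.5, 0.8].
#' @param a_range Safe-amount magnitude interval (currency units).
#' @param params `model_params` used for the inversion (defaults to the
#'   mean preliminary estimates beta = 4.38, u = 0.56).
#' @param rounding Currency quantum amounts are rounded to (default 0.05).
#' @param jitter_sd SD of Gaussian per-trial target jitter, truncated to
#'   (0.05, 0.95); 0 (default) keeps the target constant so the set-level
#'   mean is exact.
#' @param A_cap Reject trials whose risky magnitude exceeds this cap
#'   (default 60) to keep stimuli plausible.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(target_ps, n_trials, frame = c("gain", "loss"),
                          P_grid = seq(0.55, 0.80, by = 0.05),
                          a_range = c(2, 10),
                          params = model_params(4.38, 0.56),
                          rounding = 0.05, jitter_sd = 0, A_cap = 60) {
  frame <- match.arg(frame)
  if (target_ps <= 0 || target_ps >= 1)
    stop("target_ps must lie in (0, 1)", call. = FALSE)
  if (any(P_grid <= 0.5 | P_grid > 0.8))
    stop("P_grid must lie within (0.5, 0.8]", call. = FALSE)
  if (any(a_range <= 0) || a_range[2] < a_range[1])
    stop("a_range must be a positive magnitude interval", call. = FALSE)
  if (rounding <= 0) stop("rounding quantum must be positive", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be non-negative", call. = FALSE)
  structure(list(target_ps = target_ps, n_trials = n_trials, frame = frame,
                 P_grid = P_grid, a_range = a_range, params = params,
                 rounding = rounding, jitter_sd = jitter_sd, A_cap = A_cap),
            class = "stimulus_spec")
}

#' Solve for the risky amount that yields a target choice probability
#'
#' Analytic inversion of the softmax expected-utility model on magnitudes:
#' given the safe lottery `(P, a)`, the model parameters, and a target
#' safe-choice probability, the risky magnitude satisfying
#' `p_safe = target_ps` is
#' \deqn{|A| = \left(\frac{P |a|^u - \mathrm{logit}(p_s)/\beta}{1-P}\right)^{1/u}}
#' with the sign of `a` restored. Substituting the result back into the
#' forward model recovers the target to floating-point precision.
#'
#' @param P Safe probability.
#' @param a Safe amount (signed; the solution carries the same sign).
#' @param target_ps Target safe-choice probability in (0, 1).
#' @param params A `model_params` object.
#' @return The risky amount `A` (signed currency, unrounded).
#' @examples
#' A <- solve_risky_amount(0.7, 4, 0.7, model_params(4.38, 0.56))
#' p_safe(list(P = 0.7, a = 4, A = A), model_params(4.38, 0.56),
#'        validate = FALSE)  # 0.7
#' @export
solve_risky_amount <- function(P, a, target_ps, params) {
  if (any(target_ps <= 0 | target_ps >= 1))
    stop("target_ps must lie in (0, 1)", call. = FALSE)
  if (any(a == 0)) stop("safe amount a must be non-zero", call. = FALSE)
  # Loss frame: delta-EU flips sign with the amounts, so solve magnitudes at
  # the mirrored target and restore the sign.
  eff_target <- ifelse(a > 0, target_ps, 1 - target_ps)
  logit <- log(eff_target / (1 - eff_target))
  num <- P * abs(a)^params$u - logit / params$beta
  if (any(num <= 0))
    stop("infeasible target: required risky expected utility is non-positive ",
         "(increase |a| or P, or move target_ps toward 0.5)", call. = FALSE)
  sign(a) * (num / (1 - P))^(1 / params$u)
}

#' Generate a lottery stimulus set with a prescribed mean choice probability
#'
#' Samples safe lotteries `(P, a)` from the specification, solves the risky
#' amount analytically for the per-trial target probability, rounds amounts
#' to the currency quantum, and rejects/resamples pairs whose rounded risky
#' magnitude violates `|A| > |a|` or exceeds the cap. With `jitter_sd = 0`
#' every pair's model-implied (pre-rounding) safe-choice probability equals
#' `target_ps` exactly, so the set mean is exact by construction.
#'
#' @param spec A `stimulus_spec`.
#' @param seed Integer seed; the same seed reproduces the same set, and
#'   gain/loss sets from the same seed differ only in amount signs.
#' @return A data frame of class `stimulus_set` with columns `P`, `a`, `A`
#'   (rounded, signed), `A_exact` (unrounded solution), `target_ps`
#'   (per-trial target), `frame`.
#' @export
generate_stimulus_set <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"))
  sgn <- if (spec$frame == "gain") 1 else -1
  n <- spec$n_trials
  out <- vector("list", 0L)
  got <- 0L
  attempts <- 0L
  # deterministic local RNG stream, independent of the caller's state
  rng <- local_rng(seed)
  on.exit(rng$restore(), add = TRUE)
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > 10L)
      stop("stimulus generation failed: >10x oversampling still rejected; ",
           "the target/amount region is infeasible (target_ps = ",
           spec$target_ps, ", a_range = [", spec$a_range[1], ", ",
           spec$a_range[2], "])", call. = FALSE)
    m <- n - got
    P <- sample(spec$P_grid, m, replace = TRUE)
    amag <- stats::runif(m, spec$a_range[1], spec$a_range[2])
    amag <- round(amag / spec$rounding) * spec$rounding
    tgt <- rep(spec$target_ps, m)
    if (spec$jitter_sd > 0) {
      tgt <- tgt + stats::rnorm(m, 0, spec$jitter_sd)
      tgt <- pmin(pmax(tgt, 0.05), 0.95)
    }
    # Solve on magnitudes, then restore the frame sign. A loss pair's
    # delta-EU is the negative of its magnitude pair's, so the magnitude
    # solve uses the mirrored target; a loss set at target t therefore has
    # the magnitudes of a gain set at 1 - t, sign-flipped.
    tgt_eff <- if (spec$frame == "loss") 1 - tgt else tgt
    A_exact <- tryCatch(
      solve_risky_amount(P, amag, tgt_eff, spec$params),
      error = function(e) rep(NA_real_, m))
    A_round <- round(abs(A_exact) / spec$rounding) * spec$rounding
    keep <- is.finite(A_exact) & A_round > amag & A_round <= spec$A_cap
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        P = P[keep], a = amag[keep], A_exact = abs(A_exact[keep]),
        A = A_round[keep], target_ps = tgt[keep])
      got <- got + sum(keep)
    }
  }
  res <- do.call(rbind, out)[seq_len(n), , drop = FALSE]
  res$a <- sgn * res$a
  res$A <- sgn * res$A
  res$A_exact <- sgn * res$A_exact
  res$frame <- spec$frame
  rownames(res) <- NULL
  class(res) <- c("stimulus_set", "data.frame")
  res
}

#' Model-implied safe-choice probabilities of a stimulus set
#'
#' Evaluates the forward model on each pair, by default on the exact
#' (pre-rounding) risky amounts so the construction identity
#' `mean(p) == target_ps` can be checked.
#'
#' @param set A `stimulus_set` data frame.
#' @param params `model_params`; defaults to the generating parameters.
#' @param exact Use the unrounded risky amounts (default `TRUE`).
#' @return Numeric vector of safe-choice probabilities.
#' @export
implied_p_safe <- function(set, params = model_params(4.38, 0.56),
                           exact = TRUE) {
  A <- if (exact && "A_exact" %in% names(set)) set$A_exact else set$A
  p_safe_vec(set$P, set$a, A, params$beta, params$u)
}

# Saves/restores .Random.seed around a locally seeded RNG stream so that
# generator calls are reproducible without disturbing the caller.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}
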