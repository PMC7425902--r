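#' Construct a lottery pair
#'
#' A binary choice problem between a safe lottery (amount `a` with
#' probability `P`, nothing otherwise) and a risky lottery (amount `A` with
#' probability `1 - P`). In the gain frame both amounts are positive; in the
#' loss frame both are negative. The safe option always carries the majority
#' probability (`P > 0.5`) and the smaller magnitude (`|A| > |a|`).
#'
#' @param P Probability of the safe outcome, in (0.5, 0.8].
#' @param a Safe amount (currency units; positive in gains, negative in
#'   losses).
#' @param A Risky amount, same sign as `a`, with `|A| > |a|`.
#' @param frame `"gain"` or `"loss"`. Defaults to the sign of the amounts.
#' @return An object of class `lottery_pair`.
#' @examples
#' lottery_pair(P = 0.65, a = 6.95, A = 9.15)
#' @export
lottery_pair <- function(P, a, A, frame = if (a > 0) "gain" else "loss") {
  frame <- match.arg(frame, c("gain", "loss"))
  pair <- structure(list(P = P, a = a, A = A, frame = frame),
                    class = "lottery_pair")
  validate_lottery_pair(pair)
  pair
}

#' Validate a lottery pair
#'
#' Checks the probability band, the sign convention of the two amounts
#' against the frame, and the magnitude ordering `|A| > |a|`. The first
#' violated invariant is named in the error message.
#'
#' @param pair A `lottery_pair`.
#' @return `pair`, invisibly, if valid.
#' @export
validate_lottery_pair <- function(pair) {
  with(pair, {
    if (!is.numeric(P) || P <= 0.5 || P > 0.8)
      stop("invalid lottery pair: safe probability P must lie in (0.5, 0.8], got ",
           format(P), call. = FALSE)
    if (a == 0 || A == 0)
      stop("invalid lottery pair: amounts must be non-zero", call. = FALSE)
    if (sign(a) != sign(A))
      stop("invalid lottery pair: amounts a and A must share a sign (same frame)",
           call. = FALSE)
    if (frame == "gain" && a < 0)
      stop("invalid lottery pair: gain frame requires positive amounts",
           call. = FALSE)
    if (frame == "loss" && a > 0)
      stop("invalid lottery pair: loss frame requires negative amounts",
           call. = FALSE)
    if (abs(A) <= abs(a))
      stop("invalid lottery pair: risky amount must exceed the safe amount in magnitude (|A| > |a|)",
           call. = FALSE)
  })
  invisible(pair)
}

#' @export
print.lottery_pair <- function(x, ...) {
  cat(sprintf("<lottery_pair (%s frame)> safe: %.0f%% of %.2f | risky: %.0f%% of %.2f\n",
              x$frame, 100 * x$P, x$a, 100 * (1 - x$P), x$A))
  invisible(x)
}

#' Choice model parameters
#'
#' The two free parameters of the softmax expected-utility model: the
#' inverse temperature `beta` (softmax steepness; larger values give more
#' deterministic, value-maximizing choice) and the utility curvature `u`
#' (`u < 1` is concave utility: risk-averse in gains and, under the
#' sign-preserving convention, risk-seeking in losses).
#'
#' @param beta Inverse temperature, strictly positive.
#' @param u Utility curvature, strictly positive.
#' @return An object of class `model_params`.
#' @examples
#' model_params(beta = 4.38, u = 0.56)
#' @export
model_params <- function(beta, u) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    stop("beta must be a single positive number", call. = FALSE)
  if (!is.numeric(u) || length(u) != 1 || !is.finite(u) || u <= 0)
    stop("u must be a single positive number", call. = FALSE)
  structure(list(beta = beta, u = u), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> beta = %.4g, u = %.4g\n", x$beta, x$u))
  invisible(x)
}

#' Gaussian prior specification for MAP estimation
#'
#' Independent Gaussian priors on `beta` and `u` on the natural scale.
#' Defaults are the wide, unbiased priors used for individual-level
#' estimation: beta ~ N(3, 10^2), u ~ N(1, 10^2).
#'
#' @param beta_mean,beta_sd Prior mean and SD for the inverse temperature.
#' @param u_mean,u_sd Prior mean and SD for the utility curvature.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_mean = 3, beta_sd = 10, u_mean = 1, u_sd = 10) {
  if (beta_sd <= 0 || u_sd <= 0)
    stop("prior standard deviations must be positive", call. = FALSE)
  structure(list(beta_mean = beta_mean, beta_sd = beta_sd,
                 u_mean = u_mean, u_sd = u_sd),
            class = "prior_spec")
}

#' Sign-preserving power utility
#'
#' `utility(x, u) = sign(x) * |x|^u`. For positive amounts this is the usual
#' power utility; for negative amounts the power is applied to the magnitude
#' and the sign restored, so that curvature `u < 1` produces risk aversion in
#' gains and risk seeking in losses, and the inversion used for stimulus
#' generation stays well defined on magnitudes.
#'
#' @param amount Signed amount(s), non-zero.
#' @param u Utility curvature, strictly positive.
#' @return Utility value(s), same sign as `amount`.
#' @examples
#' utility(4, 1)      # 4
#' utility(-4, 1)     # -4
#' utility(6.95, 0.56)
#' @export
utility <- function(amount, u) {
  if (!is.numeric(u) || length(u) != 1 || !is.finite(u) || u <= 0)
    stop("utility curvature u must be a single positive number", call. = FALSE)
  if (any(amount == 0))
    stop("amount must be non-zero", call. = FALSE)
  sign(amount) * abs(amount)^u
}

#' Expected-utility difference between safe and risky lotteries
#'
#' `delta_eu = P * utility(a, u) - (1 - P) * utility(A, u)`, the expected
#' utility of the safe option minus that of the risky option. Positive values
#' favor the safe choice. Under the sign-preserving utility, flipping the
#' sign of both amounts (gain to loss frame) negates the result.
#'
#' @param pair A `lottery_pair` (or a list with fields `P`, `a`, `A`).
#' @param params A `model_params` object.
#' @param validate Check the pair's invariants first (default `TRUE`).
#' @return The expected-utility difference (finite scalar).
#' @export
delta_eu <- function(pair, params, validate = TRUE) {
  if (validate && inherits(pair, "lottery_pair")) validate_lottery_pair(pair)
  pair$P * utility(pair$a, params$u) - (1 - pair$P) * utility(pair$A, params$u)
}

# Numerically stable logistic: never returns NaN/Inf for any finite x.
stable_logistic <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Probability of choosing the safe lottery
#'
#' Softmax (logistic) choice rule on the expected-utility difference:
#' `p_safe = 1 / (1 + exp(-beta * delta_eu))`. Computed with a numerically
#' stable logistic so that extreme `beta * delta_eu` saturates to 0 or 1
#' without overflow.
#'
#' @inheritParams delta_eu
#' @return Probability in (0, 1) (up to floating-point saturation).
#' @examples
#' p <- lottery_pair(0.65, 6.95, 9.15)
#' p_safe(p, model_params(4.38, 0.56))
#' @export
p_safe <- function(pair, params, validate = TRUE) {
  stable_logistic(params$beta * delta_eu(pair, params, validate = validate))
}

# Vectorized p_safe over parallel attribute vectors; used internally where
# constructing one lottery_pair per trial would be wasteful.
p_safe_vec <- function(P, a, A, beta, u) {
  stable_logistic(beta * (P * sign(a) * abs(a)^u - (1 - P) * sign(A) * abs(A)^u))
}

#' Bernoulli log-likelihood of a choice sequence
#'
#' Sum of `log p_safe` over safe choices and `log(1 - p_safe)` over risky
#' choices, under the softmax expected-utility model. Choices are coded
#' project-wide as 1 = safe, 0 = risky.
#'
#' @param trials A data frame with columns `P`, `a`, `A`, `choice` (0/1).
#' @param params A `model_params` object.
#' @return The log-likelihood (finite, non-positive).
#' @export
log_likelihood <- function(trials, params) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("trials must be a non-empty data frame", call. = FALSE)
  if (!all(c("P", "a", "A", "choice") %in% names(trials)))
    stop("trials must have columns P, a, A, choice", call. = FALSE)
  if (!all(trials$choice %in% c(0, 1)))
    stop("choice must be coded 0 (risky) / 1 (safe)", call. = FALSE)
  ps <- p_safe_vec(trials$P, trials$a, trials$A, params$beta, params$u)
  # log1p-style guards: saturated probabilities clipped to the smallest
  # representable step away from 0/1 to keep the sum finite
  eps <- .Machine$double.xmin
  ps <- pmin(pmax(ps, eps), 1 - .Machine$double.eps)
  sum(trials$choice * log(ps) + (1 - trials$choice) * log(1 - ps))
}

# Negative log joint (likelihood + Gaussian prior) used by the MAP fit.
neg_log_joint <- function(theta, trials, prior) {
  beta <- theta[1]; u <- theta[2]
  if (beta <= 0 || u <= 0) return(Inf)
  ll <- log_likelihood(trials, list(beta = beta, u = u))
  lp <- stats::dnorm(beta, prior$beta_mean, prior$beta_sd, log = TRUE) +
    stats::dnorm(u, prior$u_mean, prior$u_sd, log = TRUE)
  -(ll + lp)
}

#' MAP fit of the softmax expected-utility model
#'
#' Maximizes the log joint (Bernoulli log-likelihood plus independent
#' Gaussian log-priors on the natural scale) over `(beta, u)`, box
#' constrained to the positive quadrant, from a fixed 5 x 5 multi-start grid
#' so the result is deterministic for a given data set. The posterior is
#' summarized by a Laplace approximation: the covariance is the inverse of
#' the numerical Hessian of the negative log joint at the mode. The original
#' individual-level estimates were obtained by free-energy minimization
#' (variational Bayes under the Laplace approximation); MAP with a Laplace
#' covariance is the point-estimate analogue and is what downstream
#' stimulus generation consumes.
#'
#' @param trials Data frame with columns `P`, `a`, `A`, `choice`.
#' @param prior A `prior_spec` (default: the wide priors
#'   `beta ~ N(3, 100)`, `u ~ N(1, 100)`).
#' @return A `fit_result` list: `params` (`model_params` at the mode),
#'   `laplace_cov` (2 x 2 covariance, or `NULL` with
#'   `cov_available = FALSE` if the Hessian is degenerate), `loglik`
#'   (maximized log joint), `n_trials`, `convergence`.
#' @export
fit_map <- function(trials, prior = prior_spec()) {
  if (!is.data.frame(trials) || nrow(trials) < 2)
    stop("need at least 2 trials to fit", call. = FALSE)
  if (length(unique(trials$choice)) < 2)
    warning("all choices identical: estimates rely on prior shrinkage",
            call. = FALSE)
  starts <- expand.grid(beta = c(0.5, 1.5, 3, 6, 12),
                        u = c(0.2, 0.5, 1, 1.5, 2.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), neg_log_joint,
                   trials = trials, prior = prior,
                   method = "L-BFGS-B",
                   lower = c(1e-6, 1e-6), upper = c(1e3, 1e2)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("MAP fit failed to converge from every start", call. = FALSE)
  hess <- tryCatch(
    stats::optimHess(best$par, neg_log_joint, trials = trials, prior = prior),
    error = function(e) NULL)
  laplace_cov <- NULL
  cov_available <- FALSE
  if (!is.null(hess) && all(is.finite(hess))) {
    cv <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cv) && all(is.finite(cv)) && all(diag(cv) > 0)) {
      laplace_cov <- (cv + t(cv)) / 2
      cov_available <- TRUE
    }
  }
  structure(list(params = model_params(best$par[1], best$par[2]),
                 laplace_cov = laplace_cov,
                 cov_available = cov_available,
                 loglik = -best$value,
                 n_trials = nrow(trials),
                 convergence = best$convergence),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> beta = %.4g, u = %.4g  (log joint %.3f, n = %d)\n",
              x$params$beta, x$params$u, x$loglik, x$n_trials))
  if (x$cov_available)
    cat(sprintf("  Laplace SDs: beta %.3g, u %.3g\n",
                sqrt(x$laplace_cov[1, 1]), sqrt(x$laplace_cov[2, 2])))
  else cat("  Laplace covariance unavailable (degenerate Hessian)\n")
  invisible(x)
}

#' Simulate choices from the softmax expected-utility model
#'
#' Draws one Bernoulli choice (1 = safe, 0 = risky) per row of a stimulus
#' table under the model probabilities.
#'
#' @param stimuli Data frame with columns `P`, `a`, `A`.
#' @param params A `model_params` object.
#' @return `stimuli` with a `choice` column appended.
#' @export
simulate_choices <- function(stimuli, params) {
  ps <- p_safe_vec(stimuli$P, stimuli$a, stimuli$A, params$beta, params$u)
  stimuli$choice <- as.integer(stats::runif(nrow(stimuli)) < ps)
  stimuli
}
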