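#' Priming-session proportion test
#'
#' One-sample t-test of subject-level safe-choice proportions against the
#' 50% chance level. The test is one-sided in the group's designed
#' direction by default: a safe-default group is expected above 0.5
#' (`side = "greater"`), a risky-default group below (`side = "less"`).
#'
#' @param proportions Numeric vector, one safe-choice proportion per
#'   subject.
#' @param null Null value (default 0.5).
#' @param side `"greater"`, `"less"`, or `"two.sided"`.
#' @return List with `t`, `df`, `p`, `mean`, `se`, `side`.
#' @export
priming_proportion_test <- function(proportions,
                                    null = 0.5,
                                    side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  if (length(proportions) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (stats::sd(proportions) == 0)
    stop("degenerate sample: zero variance in proportions", call. = FALSE)
  tt <- stats::t.test(proportions, mu = null, alternative = side)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(proportions),
       se = stats::sd(proportions) / sqrt(length(proportions)),
       side = side)
}

#' Subject-level safe-choice proportions from a trial table
#'
#' @param trials A trial table.
#' @param session Which session to use (default `"priming"`).
#' @param group Optional group filter (`"safe_default"`/`"risky_default"`).
#' @return Named numeric vector of proportions, one per subject.
#' @export
safe_choice_proportions <- function(trials, session = "priming",
                                    group = NULL) {
  d <- trials[trials$session == session, ]
  if (!is.null(group)) d <- d[d$group == group, ]
  tapply(d$choice, d$subject, mean)
}

#' Mixed-model regression specification
#'
#' Fixed-effect terms are drawn from `TP`, `ToT`, `CP` and their
#' interactions; TP and ToT enter as cardinal codes (-1/0/+1) and CP as a
#' two-level +1 (safe-default) / -1 (risky-default) contrast. Every model
#' carries per-subject random intercepts plus random slopes for TP and ToT;
#' the random structure is held fixed across compared models so backward
#' selection varies fixed effects only.
#'
#' @param response `"choice"` (logit link) or `"rt"` (linear).
#' @param fixed Character vector of fixed terms, e.g.
#'   `c("TP", "ToT", "CP", "TP:ToT", "TP:ToT:CP")`.
#' @param random `"slopes"` (intercept + TP + ToT slopes, the default) or
#'   `"intercept"` (intercept only; useful for scaled-down simulation
#'   studies).
#' @param fast For the logit link, use the quick penalized-least-squares
#'   approximation (`nAGQ = 0`) instead of the Laplace approximation.
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(response = c("choice", "rt"),
                            fixed = c("TP", "ToT", "CP", "TP:ToT", "TP:CP",
                                      "ToT:CP", "TP:ToT:CP"),
                            random = c("slopes", "intercept"),
                            fast = FALSE) {
  response <- match.arg(response)
  random <- match.arg(random)
  ok <- vapply(strsplit(fixed, ":", fixed = TRUE), function(par)
    all(par %in% c("TP", "ToT", "CP")), logical(1))
  if (length(fixed) && !all(ok))
    stop("fixed terms must be built from TP, ToT, CP", call. = FALSE)
  structure(list(response = response, fixed = fixed, random = random,
                 fast = fast),
            class = "regression_spec")
}

# Model-ready frame: cardinal TP/ToT, +-1 CP contrast, seconds-scale RT.
prepare_model_frame <- function(trials) {
  d <- trials[trials$session == "experimental", ]
  if (nrow(d) == 0) stop("no experimental-session trials", call. = FALSE)
  data.frame(choice = d$choice,
             rt = d$rt_ms / 1000,
             TP = as.numeric(d$tp_code),
             ToT = as.numeric(d$tot_code),
             CP = ifelse(d$group == "safe_default", 1, -1),
             subject = factor(d$subject))
}

spec_formula <- function(spec) {
  lhs <- if (spec$response == "choice") "choice" else "rt"
  re <- if (spec$random == "slopes") "(1 + TP + ToT | subject)"
    else "(1 | subject)"
  rhs <- paste(c("1", spec$fixed, re), collapse = " + ")
  stats::as.formula(paste(lhs, "~", rhs))
}

#' Fit a mixed-effects model of choice or RT
#'
#' Choice models are mixed logistic regressions fitted by (approximate)
#' maximum marginal likelihood via `lme4::glmer`; RT models are linear mixed
#' models fitted by ML via `lmerTest::lmer` (Satterthwaite p-values).
#' Non-convergence or complete separation raises a diagnostic error rather
#' than returning a silent result; the error suggests dropping the random
#' slopes.
#'
#' @param trials A trial table (experimental session is used).
#' @param spec A `regression_spec`.
#' @return List of class `mixed_fit` with `model` (the fitted lme4 object),
#'   `coefficients` (estimate/SE/statistic/p data frame), `logLik`, `df`,
#'   `formula`, `spec`.
#' @export
fit_mixed_model <- function(trials, spec) {
  d <- prepare_model_frame(trials)
  if (spec$response == "choice" && length(unique(d$choice)) < 2)
    stop("both choice values must be present", call. = FALSE)
  form <- spec_formula(spec)
  fit <- withCallingHandlers(
    if (spec$response == "choice")
      lme4::glmer(form, data = d, family = stats::binomial(),
                  nAGQ = if (isTRUE(spec$fast)) 0L else 1L,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    else
      lmerTest::lmer(form, data = d, REML = FALSE),
    warning = function(w) {
      if (grepl("failed to converge|unable to evaluate|degenerate",
                conditionMessage(w)))
        stop("mixed-model fit did not converge for ",
             deparse(form), "; consider random = 'intercept' ",
             "(drop the random slopes). Original warning: ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  cf <- as.data.frame(stats::coef(summary(fit)))
  pcol <- grep("^Pr\\(", names(cf))
  coefs <- data.frame(term = rownames(cf),
                      estimate = cf[, 1], se = cf[, 2],
                      statistic = cf[, grep("value$", names(cf))[1]],
                      p = if (length(pcol)) cf[, pcol[1]]
                          else 2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])),
                      row.names = NULL)
  structure(list(model = fit, coefficients = coefs,
                 logLik = as.numeric(stats::logLik(fit)),
                 df = attr(stats::logLik(fit), "df"),
                 formula = form, spec = spec),
            class = "mixed_fit")
}

#' @rdname fit_mixed_model
#' @export
fit_mixed_logistic <- function(trials, spec = regression_spec("choice")) {
  if (spec$response != "choice")
    stop("fit_mixed_logistic requires a choice-response spec", call. = FALSE)
  fit_mixed_model(trials, spec)
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit>", deparse(x$formula), "\n")
  print(x$coefficients, digits = 3)
  cat(sprintf("logLik %.2f on %d parameters\n", x$logLik, x$df))
  invisible(x)
}

# Terms currently removable: highest interaction order present; a main
# effect only once no retained interaction contains it.
removable_terms <- function(fixed) {
  if (!length(fixed)) return(character(0))
  ord <- lengths(strsplit(fixed, ":", fixed = TRUE))
  if (max(ord) > 1) return(fixed[ord == max(ord)])
  fixed
}

# Wald p-value for a single-df term of a fitted model (coefficient z/t).
term_wald_p <- function(fit, term) {
  cf <- fit$coefficients
  # lme4 writes interactions in the order given; match on the sorted parts
  key <- function(x) paste(sort(strsplit(x, ":", fixed = TRUE)[[1]]),
                           collapse = ":")
  idx <- which(vapply(cf$term, key, "") == key(term))
  if (!length(idx)) return(NA_real_)
  cf$p[idx[1]]
}

#' Backward iterative model comparison
#'
#' Starting from the full factorial fixed-effects model (TP x ToT x CP),
#' repeatedly removes the least-significant removable term (largest Wald p;
#' interactions before main effects, and a main effect never leaves while a
#' retained interaction contains it), refits, and performs a likelihood-
#' ratio test of the simpler model against its parent. The procedure stops
#' — keeping the parent model — as soon as a removal significantly degrades
#' fit (LRT p < `alpha`). Ties on Wald p are broken by interaction order
#' (highest first), then lexicographically.
#'
#' @param trials A trial table.
#' @param spec A `regression_spec` giving the full model (default: choice
#'   response, full TP x ToT x CP factorial).
#' @param alpha Stopping threshold (default 0.05).
#' @return List of class `selection_trace`: `steps` (data frame with the
#'   removed term, log-likelihoods, LRT statistic, df, p, and whether the
#'   removal was accepted), `final` (the selected `mixed_fit`),
#'   `final_terms`, `alpha`.
#' @export
backward_select <- function(trials, spec = regression_spec("choice"),
                            alpha = 0.05) {
  current <- tryCatch(fit_mixed_model(trials, spec),
                      error = function(e)
                        stop("backward selection failed at the full model: ",
                             conditionMessage(e), call. = FALSE))
  fixed <- spec$fixed
  steps <- list()
  repeat {
    cand <- removable_terms(fixed)
    if (!length(cand)) break
    wald <- vapply(cand, function(tm) term_wald_p(current, tm), numeric(1))
    ordk <- lengths(strsplit(cand, ":", fixed = TRUE))
    pick <- cand[order(-wald, -ordk, cand)][1]
    reduced_fixed <- setdiff(fixed, pick)
    rspec <- spec
    rspec$fixed <- reduced_fixed
    reduced <- tryCatch(fit_mixed_model(trials, rspec),
                        error = function(e)
                          stop("backward selection failed at step ",
                               length(steps) + 1L, " (removing ", pick,
                               "): ", conditionMessage(e), call. = FALSE))
    lrt <- max(0, 2 * (current$logLik - reduced$logLik))
    df <- current$df - reduced$df
    p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
    accepted <- p >= alpha
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, removed = pick,
      loglik_full = current$logLik, loglik_reduced = reduced$logLik,
      lrt = lrt, df = df, p = p, accepted = accepted)
    if (!accepted) break
    current <- reduced
    fixed <- reduced_fixed
  }
  structure(list(steps = if (length(steps)) do.call(rbind, steps)
                   else data.frame(),
                 final = current, final_terms = fixed, alpha = alpha),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> alpha =", x$alpha, "\n")
  if (nrow(x$steps)) print(x$steps[, c("step", "removed", "lrt", "df", "p",
                                       "accepted")], digits = 3)
  cat("final fixed effects:",
      if (length(x$final_terms)) paste(x$final_terms, collapse = " + ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Response-time manipulation check
#'
#' Linear mixed model (ML) of RT in seconds on time pressure (plus any
#' further configured terms), with the standard random structure. On
#' simulator output the TP slope is negative: subjects speed up under
#' increasing time pressure.
#'
#' @param trials A trial table.
#' @param fixed Fixed terms (default `"TP"`).
#' @param random Random-effects structure, as in [regression_spec()].
#' @return A `mixed_fit`; the TP row of `$coefficients` is the check.
#' @export
rt_manipulation_check <- function(trials, fixed = "TP",
                                  random = c("slopes", "intercept")) {
  spec <- regression_spec("rt", fixed = fixed, random = match.arg(random))
  fit_mixed_model(trials, spec)
}
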