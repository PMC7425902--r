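#' Experimental design specification
#'
#' The two-session design: a self-paced priming session (72 trials by
#' default) that establishes each group's dominant choice from the first
#' trial, followed by an experimental session of 18 blocks of 18 trials in
#' which time pressure (TP: low/medium/high, coded -1/0/+1) is crossed
#' orthogonally with time on task (ToT: beginning/middle/end thirds of the
#' blocks, coded -1/0/+1) so that every stage contains exactly 2 blocks of
#' each TP level. Choice proportion (CP) is manipulated between subjects
#' (safe-default vs risky-default stimulus sets).
#'
#' @param n_subjects Subjects per group.
#' @param frame `"gain"` or `"loss"`.
#' @param priming_trials Priming-session length (default 72).
#' @param n_blocks Experimental blocks (default 18); must be divisible by
#'   `length(tp_levels) * length(tot_stages)`.
#' @param trials_per_block Trials per block (default 18).
#' @param tp_levels,tot_stages Cardinal codes for the within-subject
#'   factors (defaults -1, 0, 1).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_subjects = 19, frame = c("gain", "loss"),
                        priming_trials = 72, n_blocks = 18,
                        trials_per_block = 18,
                        tp_levels = c(-1L, 0L, 1L),
                        tot_stages = c(-1L, 0L, 1L)) {
  frame <- match.arg(frame)
  cells <- length(tp_levels) * length(tot_stages)
  if (n_blocks %% cells != 0)
    stop("design error: n_blocks (", n_blocks,
         ") must be divisible by |tp_levels| x |tot_stages| (", cells, ")",
         call. = FALSE)
  structure(list(n_subjects = n_subjects, frame = frame,
                 priming_trials = priming_trials, n_blocks = n_blocks,
                 trials_per_block = trials_per_block,
                 tp_levels = tp_levels, tot_stages = tot_stages),
            class = "design_spec")
}

#' Generative scenario specification
#'
#' Configures which hypothesis about endogenous default options drives the
#' simulated choices and response times:
#' \describe{
#'   \item{none}{pure softmax choice; the null scenario.}
#'   \item{natural}{time pressure adds a bias toward the frame's natural
#'     option (safe in gains, risky in losses) inside a single deliberative
#'     process: `logit = beta * deltaEU + natural_bias * tp * frame_sign`.}
#'   \item{dominant}{time pressure amplifies repetition of the subject's own
#'     running-majority option: a bias of `dominant_bias * tp` toward it.}
#'   \item{learned}{a dual-process mixture: with probability
#'     `m(tot) = clip(m0 + m1 * tot, 0, 1)` the trial is executed by a fast
#'     default process that simply repeats the running-majority option;
#'     otherwise by the deliberative softmax. Time pressure does not alter
#'     the mixture weight.}
#' }
#' Response times are shifted lognormals per generating process. The
#' deliberative meanlog decreases with time pressure
#' (`meanlog - rt_tp_slope * tp`) so the manipulation check passes under
#' every scenario; the default process is faster and TP-invariant. Under
#' `learned`, the marginal RT distribution at each ToT stage is therefore a
#' true binary mixture of two fixed base distributions with weight `m(tot)`
#' — the ground truth for fixed-point sensitivity tests. Under the
#' single-process scenarios TP shifts the one deliberative distribution, so
#' no fixed point should arise across TP levels.
#'
#' @param hypothesis One of `"none"`, `"natural"`, `"dominant"`, `"learned"`.
#' @param base_params `model_params` of the deliberative softmax.
#' @param natural_bias Logit bias per TP unit toward the natural option.
#' @param dominant_bias Logit bias per TP unit toward the running majority.
#' @param m0,m1 Intercept and ToT slope of the default-process mixture
#'   weight.
#' @param rt_deliberative Shifted-lognormal parameters of the deliberative
#'   process: list(shift_ms, meanlog, sdlog).
#' @param rt_default Same for the fast default process.
#' @param rt_tp_slope Decrement of the deliberative meanlog per TP unit.
#' @param subject_sd Between-subject heterogeneity applied by
#'   [simulate_experiment()]: `beta` and `u` are the SDs of truncated-normal
#'   subject-level draws around `base_params` (defaults 0.3 and 0.02,
#'   calibrated so that simulated priming-session choice proportions show
#'   the dispersion observed empirically, about +-0.06-0.07 across
#'   subjects), and `log_speed` is the SD of a subject-level shift applied
#'   to both processes' meanlog (a common log-speed factor, default 0.2).
#'   Set all three to 0 for homogeneous subjects.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(hypothesis = c("none", "natural", "dominant",
                                         "learned"),
                          base_params = model_params(4.38, 0.56),
                          natural_bias = 0.5, dominant_bias = 0.5,
                          m0 = 0.2, m1 = 0.2,
                          rt_deliberative = list(shift_ms = 300,
                                                 meanlog = 6.5, sdlog = 0.45),
                          rt_default = list(shift_ms = 200,
                                            meanlog = 5.8, sdlog = 0.4),
                          rt_tp_slope = 0.25,
                          subject_sd = list(beta = 0.3, u = 0.02,
                                            log_speed = 0.2)) {
  hypothesis <- match.arg(hypothesis)
  if (any(unlist(subject_sd) < 0))
    stop("subject_sd components must be >= 0", call. = FALSE)
  for (p in list(rt_deliberative, rt_default)) {
    if (p$shift_ms < 0) stop("RT shift must be >= 0", call. = FALSE)
    if (p$sdlog <= 0) stop("RT sdlog must be > 0", call. = FALSE)
  }
  structure(list(hypothesis = hypothesis, base_params = base_params,
                 natural_bias = natural_bias, dominant_bias = dominant_bias,
                 m0 = m0, m1 = m1,
                 rt_deliberative = rt_deliberative, rt_default = rt_default,
                 rt_tp_slope = rt_tp_slope, subject_sd = subject_sd),
            class = "scenario_spec")
}

# Subject-level realization of a scenario: truncated-normal draws of the
# softmax parameters around the base values and a common log-speed shift of
# both RT processes. Uses the current RNG stream.
draw_subject_scenario <- function(scenario) {
  sd <- scenario$subject_sd
  if (is.null(sd)) return(scenario)
  rtrunc <- function(mean, s, lower) {
    if (s == 0) return(mean)
    repeat {
      x <- stats::rnorm(1, mean, s)
      if (x >= lower) return(x)
    }
  }
  out <- scenario
  out$base_params <- model_params(
    rtrunc(scenario$base_params$beta, sd$beta, 0.2),
    rtrunc(scenario$base_params$u, sd$u, 0.05))
  if (sd$log_speed > 0) {
    shift <- stats::rnorm(1, 0, sd$log_speed)
    out$rt_deliberative$meanlog <- scenario$rt_deliberative$meanlog + shift
    out$rt_default$meanlog <- scenario$rt_default$meanlog + shift
  }
  out
}

# Mixture weight of the default process at a ToT stage, clipped to [0, 1].
mixture_weight <- function(scenario, tot_code) {
  pmin(pmax(scenario$m0 + scenario$m1 * tot_code, 0), 1)
}

#' Build the counterbalanced block schedule
#'
#' Assigns a (TP, ToT) label to every experimental block of every subject.
#' Each ToT stage (consecutive third of the blocks) contains each TP level
#' equally often (2 blocks each under the default 18-block design); the
#' order of TP levels within stages follows a Latin-square rotation over
#' subjects and stages, so that aggregated over any multiple-of-3 cohort
#' every TP level occupies every within-stage position equally often.
#'
#' @param spec A `design_spec`.
#' @return Data frame with columns `subject`, `block`, `tp_code`,
#'   `tot_code`.
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  n_tp <- length(spec$tp_levels)
  n_tot <- length(spec$tot_stages)
  blocks_per_stage <- spec$n_blocks / n_tot
  reps <- blocks_per_stage / n_tp  # TP repetitions per stage
  rows <- lapply(seq_len(spec$n_subjects), function(s) {
    tp <- unlist(lapply(seq_len(n_tot), function(t) {
      rot <- (s + t) %% n_tp
      order <- spec$tp_levels[((seq_len(n_tp) - 1 + rot) %% n_tp) + 1]
      rep(order, reps)
    }))
    data.frame(subject = s, block = seq_len(spec$n_blocks),
               tp_code = tp,
               tot_code = rep(spec$tot_stages, each = blocks_per_stage))
  })
  do.call(rbind, rows)
}

# One shifted-lognormal RT draw per element of tp_code for the given process.
draw_rt <- function(process, tp_code, scenario, n = length(tp_code)) {
  if (process == "deliberative") {
    p <- scenario$rt_deliberative
    p$shift_ms + stats::rlnorm(n, p$meanlog - scenario$rt_tp_slope * tp_code,
                               p$sdlog)
  } else {
    p <- scenario$rt_default
    p$shift_ms + stats::rlnorm(n, p$meanlog, p$sdlog)
  }
}

#' Simulate a response time for one trial
#'
#' Draws from the generating process's shifted lognormal. The deliberative
#' process speeds up under time pressure; the default process does not.
#'
#' @param generating_process `"deliberative"` or `"default"`.
#' @param tp_code TP code (-1/0/+1; use 0 for self-paced trials).
#' @param scenario A `scenario_spec`.
#' @return RT in milliseconds (> 0).
#' @export
simulate_rt <- function(generating_process, tp_code, scenario) {
  draw_rt(match.arg(generating_process, c("deliberative", "default")),
          tp_code, scenario)
}

#' Simulate one choice under a generative hypothesis
#'
#' @param pair A `lottery_pair` (or list with `P`, `a`, `A`).
#' @param tp_code,tot_code Cardinal factor codes (-1/0/+1; `NA` treated
#'   as 0 bias / deliberative-only, as in the priming session).
#' @param history List with `n_safe` and `n_trials`: the subject's running
#'   safe-choice tally. With an empty history (trial 1) or a tied majority,
#'   the dominant and learned mechanisms fall back to the plain softmax.
#' @param scenario A `scenario_spec`.
#' @return List with `choice` (1 safe / 0 risky) and `generating_process`.
#' @export
simulate_choice <- function(pair, tp_code, tot_code, history, scenario) {
  params <- scenario$base_params
  deu <- delta_eu(pair, params, validate = FALSE)
  tp <- if (is.na(tp_code)) 0 else tp_code
  tot <- if (is.na(tot_code)) NA else tot_code
  majority <- if (history$n_trials == 0 || history$n_safe * 2 == history$n_trials)
    NA_integer_ else as.integer(history$n_safe * 2 > history$n_trials)
  logit <- params$beta * deu
  process <- "deliberative"
  choice <- NULL
  switch(scenario$hypothesis,
    none = NULL,
    natural = {
      frame_sign <- if (pair$a > 0) 1 else -1
      logit <- logit + scenario$natural_bias * tp * frame_sign
    },
    dominant = {
      if (!is.na(majority))
        logit <- logit + scenario$dominant_bias * tp * (2 * majority - 1)
    },
    learned = {
      if (!is.na(majority) && !is.na(tot) &&
          stats::runif(1) < mixture_weight(scenario, tot)) {
        process <- "default"
        choice <- majority
      }
    })
  if (is.null(choice))
    choice <- as.integer(stats::runif(1) < stable_logistic(logit))
  list(choice = choice, generating_process = process)
}

# Vectorized within-subject simulation of an ordered trial stream. Keeps the
# per-trial sequential dependence (running majority) in one loop per subject;
# the softmax probabilities and bias terms are precomputed.
simulate_subject_stream <- function(stim, tp_code, tot_code, scenario,
                                    frame_sign) {
  n <- nrow(stim)
  params <- scenario$base_params
  deu <- stim$P * sign(stim$a) * abs(stim$a)^params$u -
    (1 - stim$P) * sign(stim$A) * abs(stim$A)^params$u
  base_logit <- params$beta * deu
  tp0 <- ifelse(is.na(tp_code), 0, tp_code)
  choice <- integer(n)
  process <- rep("deliberative", n)
  n_safe <- 0L
  mw <- ifelse(is.na(tot_code), 0, mixture_weight(scenario, tot_code))
  u_mix <- stats::runif(n)
  u_choice <- stats::runif(n)
  for (i in seq_len(n)) {
    majority <- if (i == 1L || 2L * n_safe == (i - 1L)) NA_integer_
      else as.integer(2L * n_safe > (i - 1L))
    logit <- base_logit[i]
    done <- FALSE
    if (scenario$hypothesis == "natural") {
      logit <- logit + scenario$natural_bias * tp0[i] * frame_sign
    } else if (scenario$hypothesis == "dominant") {
      if (!is.na(majority))
        logit <- logit + scenario$dominant_bias * tp0[i] * (2L * majority - 1L)
    } else if (scenario$hypothesis == "learned") {
      if (!is.na(majority) && u_mix[i] < mw[i]) {
        choice[i] <- majority
        process[i] <- "default"
        done <- TRUE
      }
    }
    if (!done) choice[i] <- as.integer(u_choice[i] < stable_logistic(logit))
    n_safe <- n_safe + choice[i]
  }
  rt <- numeric(n)
  del <- process == "deliberative"
  rt[del] <- draw_rt("deliberative", tp0[del], scenario, sum(del))
  rt[!del] <- draw_rt("default", tp0[!del], scenario, sum(!del))
  list(choice = choice, process = process, rt = rt)
}

#' Simulate a complete two-session experiment
#'
#' Builds the counterbalanced design, assigns each group its stimulus set
#' (priming trials first, then the experimental blocks), and simulates every
#' subject's choices and response times under the scenario. Per-subject RNG
#' substreams are derived deterministically from the master seed, so the
#' output is reproducible and invariant to subject order.
#'
#' @param design A `design_spec`.
#' @param scenario A `scenario_spec`.
#' @param stimuli Named list with elements `safe_default` and
#'   `risky_default`, each a stimulus table (columns `P`, `a`, `A`) with
#'   `priming_trials + n_blocks * trials_per_block` rows. `NULL` (default)
#'   generates both sets at the study targets (0.70 / 0.30) from the
#'   scenario's base parameters.
#' @param seed Master seed.
#' @return A trial table (data frame): one row per trial with columns
#'   `subject`, `group`, `frame`, `session`, `block`, `trial`, `tp_code`,
#'   `tot_code`, `P`, `a`, `A`, `choice`, `rt_ms`, `generating_process`.
#'   Priming rows carry `NA` TP/ToT codes (self-paced).
#' @export
simulate_experiment <- function(design, scenario, stimuli = NULL, seed = 1L) {
  stopifnot(inherits(design, "design_spec"), inherits(scenario, "scenario_spec"))
  n_exp <- design$n_blocks * design$trials_per_block
  n_per_subj <- design$priming_trials + n_exp
  # Deterministic, decorrelated substreams: all stage seeds are drawn from
  # the master stream, so different master seeds give independent
  # replicates and subject order never matters.
  rng <- local_rng(seed)
  stim_seeds <- sample.int(.Machine$integer.max, 2)
  subj_seeds <- matrix(sample.int(.Machine$integer.max, 2 * design$n_subjects),
                       nrow = 2)
  rng$restore()
  if (is.null(stimuli)) {
    stimuli <- list(
      safe_default = generate_stimulus_set(
        stimulus_spec(0.70, n_per_subj, frame = design$frame,
                      params = scenario$base_params),
        seed = stim_seeds[1]),
      risky_default = generate_stimulus_set(
        stimulus_spec(0.30, n_per_subj, frame = design$frame,
                      params = scenario$base_params),
        seed = stim_seeds[2]))
  }
  for (g in c("safe_default", "risky_default")) {
    if (is.null(stimuli[[g]]))
      stop("stimuli must contain a '", g, "' set", call. = FALSE)
    if (nrow(stimuli[[g]]) < n_per_subj)
      stop("stimulus/design size mismatch: '", g, "' has ",
           nrow(stimuli[[g]]), " rows, design needs ", n_per_subj,
           call. = FALSE)
  }
  schedule <- build_design(design)
  frame_sign <- if (design$frame == "gain") 1 else -1
  groups <- c("safe_default", "risky_default")
  out <- vector("list", 2L * design$n_subjects)
  k <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    stim <- stimuli[[g]][seq_len(n_per_subj), , drop = FALSE]
    for (s in seq_len(design$n_subjects)) {
      k <- k + 1L
      sid <- (gi - 1L) * design$n_subjects + s
      rng <- local_rng(subj_seeds[gi, s])
      sched <- schedule[schedule$subject == s, ]
      tp <- c(rep(NA_integer_, design$priming_trials),
              rep(sched$tp_code, each = design$trials_per_block))
      tot <- c(rep(NA_integer_, design$priming_trials),
               rep(sched$tot_code, each = design$trials_per_block))
      subj_scenario <- draw_subject_scenario(scenario)
      sim <- simulate_subject_stream(stim, tp, tot, subj_scenario, frame_sign)
      rng$restore()
      out[[k]] <- data.frame(
        subject = sid, group = g, frame = design$frame,
        session = rep(c("priming", "experimental"),
                      c(design$priming_trials, n_exp)),
        block = c(rep(NA_integer_, design$priming_trials),
                  rep(sched$block, each = design$trials_per_block)),
        trial = seq_len(n_per_subj),
        tp_code = tp, tot_code = tot,
        P = stim$P, a = stim$a, A = stim$A,
        choice = sim$choice, rt_ms = sim$rt,
        generating_process = sim$process)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
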