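test_that("priming proportion test matches a direct t-distribution oracle", {
  # 19 subject proportions centred on 0.67, as in a safe-default group
  set.seed(13)
  x <- 0.67 + scale(rnorm(19))[, 1] * 0.13
  x <- x - mean(x) + 0.67
  res <- priming_proportion_test(x, side = "greater")
  expect_equal(res$df, 18)
  t_direct <- (mean(x) - 0.5) / (sd(x) / sqrt(19))
  expect_equal(res$t, t_direct)
  expect_equal(res$p, pt(t_direct, df = 18, lower.tail = FALSE))
  # antisymmetry under sign flip about the null
  flipped <- 1 - x
  res2 <- priming_proportion_test(flipped, side = "less")
  expect_equal(res2$t, -res$t)
  expect_equal(res2$p, res$p)
})

test_that("degenerate priming samples are rejected, chance data give p = .5", {
  expect_error(priming_proportion_test(rep(0.5, 10)), "variance")
  expect_error(priming_proportion_test(0.6), "2 subjects")
  x <- c(0.45, 0.5, 0.55, 0.48, 0.52)
  x <- x - mean(x) + 0.5
  res <- priming_proportion_test(x, side = "greater")
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)
})

test_that("group proportions reflect the choice-proportion manipulation", {
  tr <- sim_experiment_small("none", n_subjects = 8, seed = 31)
  safe <- safe_choice_proportions(tr, group = "safe_default")
  risky <- safe_choice_proportions(tr, group = "risky_default")
  expect_length(safe, 8)
  expect_gt(priming_proportion_test(safe, side = "greater")$mean, 0.5)
  expect_lt(priming_proportion_test(risky, side = "less")$mean, 0.5)
})

test_that("mixed logistic collapses to ordinary logistic without heterogeneity", {
  tr <- sim_experiment_small("none", n_subjects = 6, seed = 33,
                             subject_sd = list(beta = 0, u = 0,
                                               log_speed = 0))
  spec <- regression_spec("choice", fixed = c("TP", "ToT", "CP"),
                          random = "intercept")
  mm <- fit_mixed_logistic(tr, spec)
  d <- riskdefaults:::prepare_model_frame(tr)
  gl <- glm(choice ~ TP + ToT + CP, data = d, family = binomial())
  expect_equal(mm$coefficients$estimate, unname(coef(gl)), tolerance = 0.05)
})

test_that("learned simulations recover a positive ToT x CP interaction", {
  tr <- simulate_experiment(design_spec(n_subjects = 19),
                            scenario_spec("learned"), seed = 35)
  fit <- fit_mixed_logistic(tr, regression_spec(
    "choice", fixed = c("TP", "ToT", "CP", "ToT:CP"), random = "intercept",
    fast = TRUE))
  est <- fit$coefficients
  expect_gt(est$estimate[est$term == "ToT:CP"], 0)
  expect_lt(est$p[est$term == "ToT:CP"], 0.05)
})

test_that("backward selection honours its stopping and hierarchy contracts", {
  tr <- sim_experiment_small("natural", n_subjects = 6, seed = 37)
  sel <- backward_select(tr, regression_spec("choice", random = "intercept",
                                             fast = TRUE))
  st <- sel$steps
  expect_true(all(st$p[st$accepted] >= sel$alpha))
  if (any(!st$accepted)) {
    expect_lt(st$p[!st$accepted], sel$alpha)
    expect_equal(which(!st$accepted), nrow(st))  # stopping ends the trace
  }
  expect_true(all(st$lrt >= 0))
  expect_true(all(st$df == 1))
  # hierarchy: no main effect removed while an interaction contained it
  removed <- st$removed[st$accepted]
  for (i in seq_along(removed)) {
    if (!grepl(":", removed[i])) {
      later_interactions <- grep(":", c(removed[-seq_len(i)],
                                        sel$final_terms), value = TRUE)
      expect_false(any(vapply(later_interactions, function(tm)
        removed[i] %in% strsplit(tm, ":")[[1]], TRUE)))
    }
  }
  # the trace is reproducible bit for bit on fixed input
  sel2 <- backward_select(tr, regression_spec("choice", random = "intercept",
                                              fast = TRUE))
  expect_identical(sel$steps, sel2$steps)
})

test_that("natural-gain simulations retain a positive TP effect", {
  tr <- simulate_experiment(design_spec(n_subjects = 10),
                            scenario_spec("natural"), seed = 39)
  sel <- backward_select(tr, regression_spec("choice", random = "intercept",
                                             fast = TRUE))
  expect_true("TP" %in% sel$final_terms ||
                any(grepl("TP", sel$final_terms)))
  fit <- sel$final
  tp_row <- fit$coefficients[fit$coefficients$term == "TP", ]
  expect_gt(tp_row$estimate, 0)
})

test_that("RT manipulation check finds the speed-up under time pressure", {
  tr <- sim_experiment_small("none", n_subjects = 6, seed = 41)
  fit <- rt_manipulation_check(tr, random = "intercept")
  tp <- fit$coefficients[fit$coefficients$term == "TP", ]
  expect_lt(tp$estimate, 0)
  expect_lt(tp$p, 0.001)
  # TP-invariant RTs: slope within 2 SE of zero; permuted labels attenuate
  tr0 <- sim_experiment_small("none", n_subjects = 6, seed = 43,
                              rt_tp_slope = 0)
  fit0 <- rt_manipulation_check(tr0, random = "intercept")
  tp0 <- fit0$coefficients[fit0$coefficients$term == "TP", ]
  expect_lt(abs(tp0$estimate), 2 * tp0$se)
  set.seed(7)
  trp <- tr
  idx <- trp$session == "experimental"
  trp$tp_code[idx] <- sample(trp$tp_code[idx])
  fitp <- rt_manipulation_check(trp, random = "intercept")
  tpp <- fitp$coefficients[fitp$coefficients$term == "TP", ]
  expect_lt(abs(tpp$estimate), abs(tp$estimate) / 2)
})

test_that("null simulations usually select an intercept-or-CP-only model", {
  hits <- vapply(1:12, function(i) {
    tr <- sim_experiment_small("none", n_subjects = 6, seed = 600 + i)
    sel <- backward_select(tr, regression_spec("choice",
                                               random = "intercept",
                                               fast = TRUE))
    !any(grepl("TP|ToT", sel$final_terms))
  }, TRUE)
  expect_gte(mean(hits), 0.5)
})
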