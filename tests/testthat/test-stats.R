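test_that("proportion summary uses the correct denominators", {
  outcomes <- data.frame(
    treatment = c(rep("control", 4), rep("constant", 6), rep("rearranged", 5)),
    response = c("desert", "accept", "accept", "accept",
                 "desert", "eject", "eject", "eject", "accept", NA,
                 "eject", "eject", "eject", "accept", "accept"))
  ps <- proportion_summary(outcomes)
  expect_equal(ps$desertion_pct, c(100 * 1 / 4, 100 * 1 / 6, 0))
  # ejection denominator counts only definitive eject/accept outcomes
  expect_equal(ps$ejection_pct, c(NA, 100 * 3 / 4, 100 * 3 / 5))
  expect_true(is.na(ps$ejection_pct[1]))  # control cannot eject

  all_accept <- data.frame(treatment = rep("constant", 5),
                           response = rep("accept", 5))
  expect_equal(proportion_summary(all_accept)$ejection_pct, 0)
  expect_error(proportion_summary(outcomes[0, ]), "empty")
})

test_that("Fisher enumeration p matches closed forms and fisher.test", {
  # observed cell at the conditional mode forces p = 1
  tab <- matrix(c(2, 17, 8, 52), 2, 2, byrow = TRUE)
  f <- fisher_exact(tab, n_reps = 1000, seed = 1)
  expect_equal(round(f$p_exact, 2), 1)

  # proportional rows: independence, p = 1 and conditional OR = 1
  f2 <- fisher_exact(matrix(c(5, 5, 10, 10), 2, 2, byrow = TRUE),
                     n_reps = 1000, seed = 1)
  expect_equal(f2$p_exact, 1)
  expect_equal(f2$odds_ratio, 1, tolerance = 1e-6)

  # perfectly discordant table, hand enumeration: p = 2 / C(20, 10)
  f3 <- fisher_exact(matrix(c(0, 10, 10, 0), 2, 2, byrow = TRUE),
                     n_reps = 1000, seed = 1)
  expect_equal(f3$p_exact, 2 / choose(20, 10), tolerance = 1e-12)

  # random tables agree with stats::fisher.test
  set.seed(77)
  for (rep in 1:20) {
    t4 <- matrix(rpois(4, 8) + 1, 2, 2)
    expect_equal(fisher_exact(t4, n_reps = 10)$p_exact,
                 fisher.test(t4)$p.value, tolerance = 1e-9)
  }

  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("Monte Carlo Fisher p agrees with enumeration within MC error", {
  tab <- matrix(c(4, 21, 13, 41), 2, 2, byrow = TRUE)
  f <- fisher_exact(tab, n_reps = 2e4, seed = 42)
  se <- sqrt(f$p_exact * (1 - f$p_exact) / 2e4)
  expect_lt(abs(f$p_mc - f$p_exact), 3 * se + 1e-4)
  expect_gt(f$p_mc, 0)
  expect_lte(f$p_mc, 1)
})

test_that("binomial GLM estimates match a hand-coded IRLS oracle", {
  set.seed(1234)
  n <- 60
  dat <- data.frame(
    treatment = rep(c("constant", "rearranged"), each = n / 2),
    nest_age = round(runif(n, 0, 10), 1),
    laying_date = round(runif(n, 1, 90)),
    clutch_size = rep(c(4L, 5L), n / 2))
  eta <- 0.5 + 1 * (dat$treatment == "rearranged") - 0.05 * dat$nest_age
  dat$response <- ifelse(runif(n) < plogis(eta), "eject", "accept")
  dat$latency_days <- ifelse(dat$response == "eject", 1, NA)

  res <- fit_response_model(dat)
  X <- model.matrix(~ treatment + nest_age + laying_date + factor(clutch_size),
                    dat)
  beta_oracle <- irls_logit(X, as.integer(dat$response == "eject"))
  expect_equal(res$terms$estimate, beta_oracle, tolerance = 1e-6)

  # result-table contracts
  expect_true(all(res$terms$ci_lo <= res$terms$estimate))
  expect_true(all(res$terms$ci_hi >= res$terms$estimate))
  expect_true(all(res$terms$p[-1] >= 0 & res$terms$p[-1] <= 1))
  expect_true(all(res$terms$vif[-1] >= 1))
  expect_gte(res$pseudo_r2, 0)

  # all-eject data raise the separation flag and a penalized refit
  sep <- dat; sep$response <- "eject"; sep$latency_days <- 1
  res_sep <- fit_response_model(sep)
  expect_true("separation" %in% res_sep$flags)
  expect_true(all(is.finite(res_sep$penalized)))
})

test_that("latency model estimates dispersion and falls back to Poisson", {
  set.seed(555)
  asg <- parasitized_assignments(500)
  oc <- simulate_outcomes(asg, behavior_config(desertion_prob = 0), seed = 6)
  res <- fit_latency_model(oc)
  expect_match(res$family, "negative binomial|poisson")
  cs <- res$terms[res$terms$term == "clutch_size5", ]
  expect_lt(cs$estimate, 0)  # larger clutches eject faster

  # constant latencies: treatment estimate ~ 0, fallback flagged
  const <- oc[oc$response == "eject", ]
  const$latency_days <- 2
  res_c <- fit_latency_model(const, predictors = "treatment")
  expect_lt(abs(res_c$terms$estimate[2]), 0.2)

  # all-zero latencies cannot support an NB dispersion estimate
  zed <- oc[oc$response == "eject", ]
  zed$latency_days <- 0
  res_z <- fit_latency_model(zed, predictors = "treatment")
  expect_true("poisson_fallback" %in% res_z$flags)

  # (near-)Poisson data push the dispersion to the Poisson limit
  pois <- oc[oc$response == "eject", ]
  set.seed(7)
  pois$latency_days <- rpois(nrow(pois), 2)
  res_p <- fit_latency_model(pois, predictors = "treatment")
  expect_true(is.null(res_p$theta) || res_p$theta > 5 ||
                length(res_p$flags) > 0)
})

test_that("VIF matches its closed form and rejects singular designs", {
  # orthogonal predictors
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-12)

  # exact sample correlation 0.8 -> VIF = 1/(1-0.64) = 2.7778
  x1 <- c(1, 1, -1, -1)
  z <- c(1, -1, 1, -1)
  x2 <- 0.8 * x1 + sqrt(1 - 0.8^2) * z
  v <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-9)

  expect_error(vif(cbind(x1, x1)), "singular")
  expect_error(vif(matrix(1:5)), "at least 2")
})

test_that("backward elimination protects treatment and honors alpha", {
  set.seed(31415)
  asg <- parasitized_assignments(300)
  # null everything: treatment must still be in the final model
  oc <- simulate_outcomes(asg, behavior_config(beta_treat = 0, gamma_clutch = 0,
                                               desertion_prob = 0), seed = 8)
  be <- backward_eliminate(oc, "response")
  expect_true(any(grepl("^treatment", be$final$terms$term)))
  expect_true(all(c("(Intercept)") %in% be$final$terms$term))

  # alpha = 1 keeps the full model
  be1 <- backward_eliminate(oc, "response", alpha = 1)
  expect_identical(be1$dropped, character(0))
  expect_identical(be1$final$terms$term, be1$full$terms$term)

  # a strong covariate survives elimination
  oc2 <- simulate_outcomes(asg, behavior_config(gamma_clutch = -1.5,
                                                desertion_prob = 0), seed = 9)
  bl <- backward_eliminate(oc2, "latency")
  expect_true(any(grepl("^clutch_size", bl$final$terms$term)))
  expect_true(any(grepl("^treatment", bl$final$terms$term)))

  expect_error(backward_eliminate(oc, "response", protected = "nest_age",
                                  predictors = "treatment"),
               "protected")
})
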