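test_that("null coefficients give uniform transition probabilities", {
  coef <- transition_coefficients(transition_structure(), 0)
  p <- transition_probabilities(coef, sex = 0, age = 30, current = 1)
  expect_equal(unname(p), rep(1 / 24, 24))
  M <- transition_matrix(coef, 1, 50)
  expect_equal(unname(M), matrix(1 / 24, 24, 24))
})

test_that("probabilities match brute-force enumeration of the linear predictor", {
  # hand-set coefficients, probabilities recomputed here by direct
  # enumeration over the 24 categories from the dummy codes
  str <- transition_structure(covariates = c("sex", "age"),
                              associations = 2)
  set.seed(21)
  vals <- rnorm(nrow(str$terms), 0, 0.5)
  coef <- transition_coefficients(str, vals)
  prof <- risk_profiles()
  for (case in list(list(sex = 0, age = 40), list(sex = 1, age = 62))) {
    eta <- numeric(24)
    for (c_i in 1:24) {
      dm <- c(w1 = as.numeric(prof$weight[c_i] == 1),
              w2 = as.numeric(prof$weight[c_i] == 2),
              p1 = prof$activity[c_i], f1 = prof$fruit[c_i],
              v1 = prof$vegetable[c_i])
      covs <- c("(1)" = 1, sex = case$sex, age = (case$age - 40) / 10)
      for (j in seq_len(nrow(str$terms))) {
        outcome_part <- prod(dm[str$dummies[[j]]])
        eta[c_i] <- eta[c_i] + vals[j] * outcome_part *
          covs[[str$terms$covariate[j]]]
      }
    }
    expected <- exp(eta) / sum(exp(eta))
    got <- transition_probabilities(coef, case$sex, case$age, 1)
    expect_equal(unname(got), expected, tolerance = 1e-12)
  }
})

test_that("probability vectors are strictly positive and sum to one", {
  set.seed(3)
  coef <- transition_coefficients(transition_structure(),
                                  rnorm(nrow(transition_structure()$terms), 0, 1))
  for (cur in c(1, 12, 24)) {
    p <- transition_probabilities(coef, 1, 55, cur)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_gt(min(p), 0)
  }
})

test_that("simulated panels are reproducible and converge to the model", {
  coef <- transition_coefficients(transition_structure(), 0)
  a <- simulate_panel(coef, 200, waves = 2, seed = 99)
  b <- simulate_panel(coef, 200, waves = 2, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 400)

  # null model: next-state frequencies uniform within 3 binomial SEs
  n <- 50000
  pan <- simulate_panel(coef, n, waves = 1, seed = 5)
  nxt <- profile_index(pan$w1, pan$p1, pan$f1, pan$v1)
  freq <- tabulate(nxt, 24) / n
  se <- sqrt((1 / 24) * (23 / 24) / n)
  expect_true(all(abs(freq - 1 / 24) < 3 * se))

  # non-null model: empirical conditional frequencies approach the model
  set.seed(8)
  coef2 <- transition_coefficients(transition_structure(),
                                   rnorm(nrow(transition_structure()$terms),
                                         0, 0.3))
  pan2 <- simulate_panel(coef2, 40000, waves = 1, seed = 6,
                         age_range = c(40L, 40L))
  sel <- pan2$sex == 0 & pan2$w0 == 0 & pan2$p0 == 0 & pan2$f0 == 0 &
    pan2$v0 == 0
  emp <- tabulate(profile_index(pan2$w1[sel], pan2$p1[sel], pan2$f1[sel],
                                pan2$v1[sel]), 24) / sum(sel)
  model <- transition_probabilities(coef2, 0, 40, 1)
  se <- sqrt(model * (1 - model) / sum(sel))
  expect_true(all(abs(emp - model) < 4 * se + 1e-12))
})

test_that("saturated intercept-only fit equals empirical frequencies", {
  # with no covariates and associations up to order 4 the outcome model is
  # saturated, so the MLE probabilities are the observed frequencies -- a
  # closed-form oracle for the optimiser
  set.seed(31)
  str <- transition_structure(covariates = character(0), associations = 2:4)
  expect_equal(nrow(str$terms), 23)  # 5 + 9 + 7 + 2: saturated in 24 cells
  true <- transition_coefficients(str, rnorm(23, 0, 0.4))
  pan <- simulate_panel(true, 5000, waves = 1, seed = 17)
  fit <- fit_joint_logit(pan, str)
  nxt <- profile_index(pan$w1, pan$p1, pan$f1, pan$v1)
  emp <- tabulate(nxt, 24) / nrow(pan)
  fitted <- transition_probabilities(fit, 0, 40, 1)
  expect_equal(unname(fitted), emp, tolerance = 1e-6)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("fitting recovers null coefficients within 3 SEs", {
  coef0 <- transition_coefficients(transition_structure(), 0)
  pan <- simulate_panel(coef0, 8000, waves = 1, seed = 12)
  fit <- fit_joint_logit(pan, transition_structure())
  expect_true(all(abs(fit$values / fit$se) < 3))
  expect_lt(fit$gradient_norm, 1e-6)
})

test_that("one-year matrices square back to the two-year model matrix", {
  params <- test_params(seed = 2, horizon = 84)
  for (age in c(20, 50, 80)) {
    M2 <- transition_matrix(params$coefficients, 0, age)
    M1 <- per_cycle_matrix(params$coefficients, 0, age, cycle_years = 1)
    expect_equal(rowSums(M1), rep(1, 24), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_true(all(M1 >= 0))
    expect_lt(max(abs(M1 %*% M1 - M2)), 1e-6)
  }
  M2 <- per_cycle_matrix(params$coefficients, 1, 30, cycle_years = 2)
  expect_equal(M2, transition_matrix(params$coefficients, 1, 30))
  # identity is its own root at any cycle
  expect_equal(unname(healmod:::stochastic_root(diag(24))), diag(24),
               ignore_attr = TRUE)
  expect_error(per_cycle_matrix(params$coefficients, 0, 30, 3), "1 or 2")
})
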