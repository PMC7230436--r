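test_that("discounting follows the present-value closed form", {
  expect_equal(discount_factor(0.015, 0), 1)
  expect_equal(round(50 * discount_factor(0.015, 1), 4), 49.2611)
  expect_equal(round(50 + 50 * discount_factor(0.015, 1), 2), 99.26)
  expect_equal(discount_factor(0, 10), 1)
  expect_error(discount_factor(-0.01, 1), "non-negative")
})

test_that("competing incidence allocates proportionally and conserves mass", {
  one <- competing_incidence(0.02, t = 1)
  expect_equal(one$probs, 1 - exp(-0.02))
  expect_equal(one$stay + sum(one$probs), 1)
  # symmetric rates split the total evenly
  two <- competing_incidence(c(0.01, 0.01), t = 2)
  expect_equal(two$probs[1], two$probs[2])
  expect_equal(two$stay + sum(two$probs), 1)
  # small-rate limit: close to independent per-disease transforms, O(rate^2)
  r <- c(2e-4, 5e-4, 1e-4)
  cc <- competing_incidence(r, t = 1)
  indep <- 1 - exp(-r)
  expect_lt(max(abs(cc$probs - indep)), sum(r)^2)
  expect_equal(competing_incidence(c(0, 0))$probs, c(0, 0))
})

test_that("occupancy is conserved and death is absorbing and monotone", {
  params <- test_params(seed = 1, horizon = 84)
  trace <- run_cohort(params, transitions = test_transitions(1, 84))
  sums <- rowSums(trace$occupancy)
  expect_true(all(abs(sums - 1) < 1e-10))
  dead <- trace$occupancy[, dead_state_index()]
  expect_true(all(diff(dead) >= -1e-14))
  expect_equal(dead[1], 0)
  # disease occupancy only accumulates from the disease-free block
  expect_true(all(trace$occupancy >= -1e-15))
})

test_that("identity program effect reproduces the baseline trace", {
  params <- test_params(seed = 1, horizon = 84)
  tr0 <- run_cohort(params, NULL, test_transitions(1, 84))
  tr1 <- run_cohort(params, program_effect(), test_transitions(1, 84))
  expect_equal(tr0$occupancy, tr1$occupancy, tolerance = 1e-15)
})

test_that("null parameters reduce the cohort to the life table", {
  params <- test_null_params(seed = 2)
  trace <- run_cohort(params)
  alive <- rowSums(trace$occupancy[, -dead_state_index()])
  expected <- life_table_survival(params)
  expect_equal(alive[seq_along(expected)], expected, tolerance = 1e-12)
  # discounted life expectancy in closed form
  disc <- discount_factor(params$discount_rate,
                          seq_along(expected) - 1)
  expect_equal(sum(trace$person_time[, -dead_state_index()]),
               sum(expected * disc), tolerance = 1e-12)
  # QALYs equal discounted life expectancy when all decrements are zero
  expect_equal(qaly_total(trace, params$weight_decrements,
                          params$diseases$utility_decrement),
               sum(expected * disc), tolerance = 1e-12)
  # any program effect is inert on the null set
  tr_eff <- run_cohort(params, program_effect(obesity_or = 0.5,
                                              activity_or = 2))
  expect_equal(qaly_total(tr_eff, params$weight_decrements,
                          params$diseases$utility_decrement),
               qaly_total(trace, params$weight_decrements,
                          params$diseases$utility_decrement),
               tolerance = 1e-12)
})

test_that("beneficial effects never reduce QALYs nor add disease-years", {
  for (seed in c(1, 3)) {
    params <- test_params(seed = seed, horizon = 84)
    trans <- test_transitions(seed, 84)
    base <- run_cohort(params, NULL, trans)
    q0 <- qaly_total(base, params$weight_decrements,
                     params$diseases$utility_decrement)
    d0 <- disease_years(base)
    effects <- list(
      program_effect(obesity_or = 0.7),
      program_effect(obesity_or = 0.7, overweight_or = 0.9),
      program_effect(activity_or = 1.5),
      program_effect(obesity_or = 0.7, activity_or = 2, fruit_or = 2,
                     vegetable_or = 2)
    )
    for (eff in effects) {
      tr <- run_cohort(params, eff, trans)
      expect_gte(qaly_total(tr, params$weight_decrements,
                            params$diseases$utility_decrement), q0)
      expect_lte(disease_years(tr), d0)
    }
  }
})

test_that("parameter validation catches broken inputs", {
  params <- test_params(seed = 1, horizon = 84)
  bad <- params
  bad$diseases$mortality_ratio[3] <- -1
  expect_error(validate_model_parameters <- healmod:::validate_model_parameters(bad),
               "positive")
  bad <- params
  bad$disease_rr$weight[21, 2] <- 1.5  # Larynx cancer is not weight-linked
  expect_error(healmod:::validate_model_parameters(bad), "not linked")
  bad <- params
  bad$horizon <- 83.5
  expect_error(healmod:::validate_model_parameters(bad), "multiple")
  bad <- params
  bad$life_table <- params$life_table[params$life_table$age < 50, ]
  expect_error(healmod:::validate_model_parameters(bad), "life table")
})
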