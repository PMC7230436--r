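test_that("standardisation re-references ratios to the population", {
  s <- standardize_ratios(category_ratios(c(1, 1), c(0.5, 0.5)))
  expect_equal(s$ratio, c(1, 1))
  s <- standardize_ratios(category_ratios(c(1, 2), c(0.5, 0.5)))
  expect_equal(s$ratio, c(2 / 3, 4 / 3))
  # population-weighted mean 1; idempotent
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:5, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    cr <- category_ratios(runif(k, 0.2, 5), p)
    s1 <- standardize_ratios(cr)
    expect_equal(sum(s1$proportion * s1$ratio), 1, tolerance = 1e-12)
    expect_equal(standardize_ratios(s1)$ratio, s1$ratio, tolerance = 1e-12)
  }
  expect_error(category_ratios(c(1, 0), c(0.5, 0.5)), "positive")
  expect_error(category_ratios(c(1, 2), c(0.5, 0.4)), "sum to 1")
})

test_that("combined hazard multiplies standardised ratios onto the baseline", {
  ratios <- list(weight = category_ratios(c(1, 1, 1), c(0.4, 0.35, 0.25)),
                 activity = category_ratios(c(1, 1), c(0.7, 0.3)),
                 fruit = category_ratios(c(1, 1), c(0.6, 0.4)),
                 vegetable = category_ratios(c(1, 1), c(0.7, 0.3)),
                 disease = category_ratios(rep(1, 33), rep(1 / 33, 33)))
  expect_equal(combined_hazard(0.01, ratios, 1, 0), 0.01)

  # two active binary dimensions with SMRs (2/3, 4/3), both in the high
  # category: h* = 0.01 * (4/3)^2
  ratios$activity <- category_ratios(c(1, 2), c(0.5, 0.5))
  ratios$fruit <- category_ratios(c(1, 2), c(0.5, 0.5))
  prof_high <- profile_index(0, 1, 1, 0)
  expect_equal(combined_hazard(0.01, ratios, prof_high, 0),
               0.01 * (4 / 3)^2, tolerance = 1e-12)
  # raw and pre-standardised ratios give the same hazard (idempotence)
  std <- ratios
  std$activity <- standardize_ratios(ratios$activity)
  std$fruit <- standardize_ratios(ratios$fruit)
  expect_equal(combined_hazard(0.01, std, prof_high, 0),
               combined_hazard(0.01, ratios, prof_high, 0), tolerance = 1e-12)
})

test_that("expected combined hazard under independence is the baseline", {
  set.seed(4)
  dims <- list(weight = 3, activity = 2, fruit = 2, vegetable = 2,
               disease = 33)
  ratios <- lapply(dims, function(k) {
    p <- rgamma(k, 2); p <- p / sum(p)
    category_ratios(runif(k, 0.5, 3), p)
  })
  H <- 0.02
  # expectation over the independent joint distribution of all five dims
  total <- 0
  prof <- risk_profiles()
  for (i in seq_len(24)) {
    for (d in 0:32) {
      pr <- ratios$weight$proportion[prof$weight[i] + 1] *
        ratios$activity$proportion[prof$activity[i] + 1] *
        ratios$fruit$proportion[prof$fruit[i] + 1] *
        ratios$vegetable$proportion[prof$vegetable[i] + 1] *
        ratios$disease$proportion[d + 1]
      total <- total + pr * combined_hazard(H, ratios, i, d)
    }
  }
  expect_equal(total, H, tolerance = 1e-10)
})

test_that("risk-adjusted incidence honours Eq-style arithmetic and conservation", {
  # one active factor, RR (1, 3), equal proportions, I = 0.02
  ratios <- list(activity = category_ratios(c(1, 3), c(0.5, 0.5)))
  i_low <- adjusted_incidence(0.02, ratios, profile_index(0, 0, 0, 0))
  i_high <- adjusted_incidence(0.02, ratios, profile_index(0, 1, 0, 0))
  expect_equal(i_low, 0.01, tolerance = 1e-12)
  expect_equal(i_high, 0.03, tolerance = 1e-12)
  expect_equal(0.5 * i_low + 0.5 * i_high, 0.02, tolerance = 1e-12)
  # all RR = 1 reduces to I
  null_ratios <- lapply(stats::setNames(nm = c("weight", "activity", "fruit",
                                               "vegetable")), function(f) {
    k <- if (f == "weight") 3 else 2
    category_ratios(rep(1, k), rep(1 / k, k))
  })
  expect_equal(adjusted_incidence(0.005, null_ratios, 13), 0.005)
  expect_error(adjusted_incidence(0.02, list(smoking = category_ratios(1, 1)),
                                  1), "unknown factor")
})

test_that("rate-to-probability transform is the exponential closed form", {
  expect_equal(incidence_to_probability(0, 1), 0)
  expect_equal(incidence_to_probability(0.01, 1), 1 - exp(-0.01))
  expect_equal(round(incidence_to_probability(0.01, 1), 6), 0.009950)
  expect_equal(round(incidence_to_probability(0.03, 2), 6), 0.058235)
  expect_lte(incidence_to_probability(100, 1), 1)
  expect_error(incidence_to_probability(-0.1, 1), "non-negative")
  expect_error(incidence_to_probability(0.1, 0), "positive")
})

test_that("solve_incidence recovers planted incidence against the forward oracle", {
  set.seed(11)
  grid <- expand.grid(i = c(0.002, 0.01, 0.04), pa = c(0.02, 0.1),
                      m = c(0.01, 0.04), mrr = c(1, 2.5))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    pb <- forward_prevalence(g$i, g$pa, g$m, g$mrr, interval = 5)
    est <- solve_incidence(g$pa, pb, g$m, g$mrr, 5)
    expect_lt(abs(est - g$i), 1e-6)
  }
})

test_that("solve_incidence handles stationarity and infeasible targets", {
  # equal mortality in both states and constant prevalence: the recovered
  # incidence reproduces the illness-death steady state
  pa <- 0.07
  est <- solve_incidence(pa, pa, 0.02, 1, 4)
  expect_equal(forward_prevalence(est, pa, 0.02, 1, 4), pa, tolerance = 1e-8)
  # prevalence below what zero incidence can reach: error
  expect_error(solve_incidence(0.3, 0.01, 0.02, 1, 2), "zero incidence")
  expect_error(solve_incidence(1.2, 0.5, 0.02, 1, 2), "\\[0, 1\\]")
})

test_that("per-case cost is expenditure share over prevalent cases", {
  expect_equal(per_case_cost(1000, 0.5, 0.25, 100), 20)
  expect_equal(per_case_cost(1000, 0, 0.25, 100), 0)
  expect_equal(per_case_cost(1000, 0.5, 0.25, 200),
               per_case_cost(1000, 0.5, 0.25, 100) / 2)
  expect_error(per_case_cost(1000, 0.5, 0, 100), "positive")
})
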