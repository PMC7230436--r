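# minimal hand-built trace: one row of person-time, all placed in chosen states
toy_trace <- function(person_time_by_state) {
  pt <- matrix(0, 1, 793)
  for (nm in names(person_time_by_state)) {
    pt[1, as.integer(nm)] <- person_time_by_state[[nm]]
  }
  structure(list(occupancy = rbind(pt, pt), person_time = pt,
                 person_time_undiscounted = pt, n_cycles = 1,
                 cycle_length = 1, start_age = 10, discount_rate = 0),
            class = "cohort_trace")
}

test_that("QALY accounting applies the larger of the two decrements", {
  # 1 person-year, obese (weight decrement 0.05) with disease 1 (0.10)
  st <- state_index(1, profile_index(2, 0, 0, 0))
  tr <- toy_trace(setNames(list(1), st))
  wdec <- c(0, 0.02, 0.05)
  ddec <- rep(0, 32); ddec[1] <- 0.10
  expect_equal(qaly_total(tr, wdec, ddec), 0.90)
  # when the weight decrement dominates it applies instead
  ddec[1] <- 0.03
  expect_equal(qaly_total(tr, wdec, ddec), 0.95)
  # zero decrements: QALYs equal life-years; full decrement: zero
  expect_equal(qaly_total(tr, c(0, 0, 0), rep(0, 32)), 1)
  expect_equal(qaly_total(tr, c(1, 1, 1), rep(1, 32)), 0)
  expect_error(qaly_total(tr, wdec, rep(0.1, 31)), "per disease")
})

test_that("disease-years and costs equal brute-force sums over the trace", {
  params <- test_params(seed = 1, horizon = 84)
  trace <- run_cohort(params, transitions = test_transitions(1, 84))
  ss <- build_state_space()
  in_disease <- !is.na(ss$disease) & ss$disease >= 1
  brute <- sum(trace$person_time[, ss$state[in_disease]])
  expect_equal(disease_years(trace), brute, tolerance = 1e-12)
  expect_gt(brute, 0)
  # flat-cost mode is cost x disease-years
  expect_equal(healthcare_costs(trace, 12174), 12174 * brute,
               tolerance = 1e-12)
  # per-disease mode equals flat mode at a shared cost
  expect_equal(healthcare_costs(trace, rep(137.5, 32)),
               healthcare_costs(trace, 137.5), tolerance = 1e-10)
  # per-disease brute force
  costs <- params$diseases$annual_cost
  brute_cost <- 0
  for (d in 1:32) {
    sel <- !is.na(ss$disease) & ss$disease == d
    brute_cost <- brute_cost + costs[d] * sum(trace$person_time[, ss$state[sel]])
  }
  expect_equal(healthcare_costs(trace, costs), brute_cost, tolerance = 1e-10)
  # QALYs can never exceed discounted life-years
  q <- qaly_total(trace, params$weight_decrements,
                  params$diseases$utility_decrement)
  expect_lte(q, sum(trace$person_time[, -793]))
})

test_that("ICER and ROI reproduce the published arithmetic", {
  expect_equal(round(icer(99.26, -0.02642)), 3757)
  expect_equal(icer(100, 0.05), 2000)
  expect_equal(icer(0, 0.05), 0)
  expect_warning(expect_true(is.na(icer(10, 0))), "undefined")
  expect_equal(round(roi(321.615, 99.26)), 324)
  expect_equal(round(roi(404.101, 99.26)), 407)
  expect_equal(roi(99.26, 99.26), 100)
  expect_error(roi(10, 0), "positive")
})

test_that("program cost discounts each program year", {
  expect_equal(round(program_cost(50, 2, 0.015), 2), 99.26)
  expect_equal(program_cost(50, 1, 0.015), 50)
  expect_equal(program_cost(10, 3, 0),  30)
})

test_that("null behavioural effects give ratios of exactly one", {
  for (seed in c(1, 3)) {
    params <- test_params(seed = seed, horizon = 84)
    cmp <- compare_scenarios(params,
                             program_effect(obesity_or = 0.7),
                             transitions = test_transitions(seed, 84))
    expect_equal(cmp$ratios$icer_qaly, 1)
    expect_equal(cmp$ratios$icer_disease_years, 1)
    expect_equal(cmp$ratios$roi, 1)
  }
})

test_that("beneficial behavioural effects push the ratios the expected way", {
  params <- test_params(seed = 1, horizon = 84)
  trans <- test_transitions(1, 84)
  for (eff in list(program_effect(obesity_or = 0.7, activity_or = 1.1),
                   program_effect(obesity_or = 0.7, activity_or = 2,
                                  fruit_or = 2, vegetable_or = 2))) {
    cmp <- compare_scenarios(params, eff, transitions = trans)
    expect_gte(cmp$ratios$icer_qaly, 1)
    expect_gte(cmp$ratios$icer_disease_years, 1)
    expect_lte(cmp$ratios$roi, 1)
    # a stronger multi-factor evaluation also means larger gains
    expect_gte(cmp$contrasts$incr_qalys[2], cmp$contrasts$incr_qalys[1])
  }
})

test_that("savings reconcile with the flat cost times disease-years prevented", {
  params <- test_params(seed = 1, horizon = 84)
  cmp <- compare_scenarios(params,
                           program_effect(obesity_or = 0.7, fruit_or = 1.5),
                           transitions = test_transitions(1, 84))
  expect_equal(cmp$contrasts$savings,
               -cmp$contrasts$incr_disease_years * 12174, tolerance = 1e-10)
  expect_equal(cmp$contrasts$roi,
               cmp$contrasts$savings / cmp$program_cost * 100)
})
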