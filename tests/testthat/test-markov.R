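# Transition matrices, cohort propagation, outcome accumulation, horizon.

test_that("treated rows multiply baseline switching by the relative risks", {
  Ms <- transition_matrix(default_params, "sildenafil")
  # FC II row: improve 0.125 * 4.23, worsen 0.127 * 0.43, death 0.013
  expect_equal(unname(Ms["fc2", ]),
               c(0.52875, 1 - 0.52875 - 0.05461 - 0.013, 0.05461, 0, 0.013),
               tolerance = 1e-12)
  Mb <- transition_matrix(default_params, "beraprost")
  # FC III row: improve 0.125 * 0.93, worsen 0.094 * 0.10, death 0.016
  expect_equal(unname(Mb["fc3", ]),
               c(0, 0.11625, 1 - 0.11625 - 0.0094 - 0.016, 0.0094, 0.016),
               tolerance = 1e-12)
})

test_that("matrices are row-stochastic, tridiagonal-plus-death, absorbing", {
  for (drug in c("sildenafil", "beraprost", "none")) {
    M <- transition_matrix(default_params, drug)
    expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["death", ]), c(0, 0, 0, 0, 1))
    # no jumps across more than one class
    expect_equal(M["fc1", "fc3"], 0)
    expect_equal(M["fc1", "fc4"], 0)
    expect_equal(M["fc2", "fc4"], 0)
    expect_equal(M["fc4", "fc1"], 0)
    expect_equal(M["fc4", "fc2"], 0)
  }
})

test_that("neutral relative risks reproduce standard treatment exactly", {
  p <- default_params
  for (id in c("effects.sildenafil.rr_worsening",
               "effects.sildenafil.rr_improvement")) {
    p$table$value[p$table$id == id] <- 1
  }
  M1 <- transition_matrix(p, "sildenafil")
  M0 <- transition_matrix(default_params, "none")
  expect_equal(unclass(M1), unclass(M0), ignore_attr = TRUE)
})

test_that("over-full rows are capped proportionally with death untouched", {
  p <- default_params
  p$table$value[p$table$id == "effects.sildenafil.rr_improvement"] <- 10
  expect_warning(M <- transition_matrix(p, "sildenafil"), "capped")
  expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
  expect_equal(M["fc2", "death"], 0.013)       # death anchored
  expect_equal(M["fc2", "fc2"], 0)             # no residual stay probability
  expect_gt(attr(M, "capped"), 0)
  # capping disabled -> error
  expect_error(transition_matrix(p, "sildenafil", cap = FALSE), "invalid")
})

test_that("cohort propagation conserves mass and absorbs into death", {
  M <- transition_matrix(default_params, "sildenafil")
  trace <- run_cohort(M, start_fc = 2, horizon_cycles = 120)
  occ <- as.matrix(trace[, c("fc1", "fc2", "fc3", "fc4", "death")])
  expect_equal(unname(rowSums(occ)), rep(1, 121), tolerance = 1e-10)
  expect_true(all(occ >= -1e-15))
  expect_true(all(diff(occ[, "death"]) >= -1e-15))       # monotone death
  expect_true(all(diff(rowSums(occ[, 1:4])) <= 1e-15))   # living shrink
  # row 0 is the unit vector at the start state
  expect_equal(unname(occ[1, ]), c(0, 1, 0, 0, 0))
  # one-step occupancy is exactly the start state's matrix row
  expect_equal(unname(occ[2, ]), unname(M["fc2", ]), tolerance = 1e-15)

  # identity dynamics: occupancy constant
  I5 <- diag(5)
  dimnames(I5) <- dimnames(M)
  tr <- run_cohort(structure(I5, drug = "none"), 3, 10)
  expect_true(all(tr$fc3 == 1))

  # certain death: whole cohort absorbed at cycle 1
  Md <- matrix(0, 5, 5, dimnames = dimnames(M))
  Md[, 5] <- 1
  trd <- run_cohort(structure(Md, drug = "none"), 2, 3)
  expect_equal(trd$death, c(0, 1, 1, 1))

  expect_error(run_cohort(M, 2, 0), "horizon")
  expect_error(run_cohort(M, 5, 10), "start_fc")
})

test_that("outcome accumulation matches hand sums and discounting identities", {
  # cohort frozen in FC II: no transitions, no death
  p <- frozen_params()
  p$settings$annual_discount_rate <- 0
  M <- transition_matrix(p, "sildenafil")
  trace <- run_cohort(M, 2, 4)
  out <- accumulate_outcomes(trace, p)
  expect_equal(out$life_years, 1.0)
  # 4 cycles x (direct medical FC II + non-medical 110 + drug 92)
  expect_equal(out$cost, 4 * (0.33 * 808 + 4.89 * 21 + 110 + 92))
  expect_equal(out$qalys, 0.71)              # utility-weighted
  expect_equal(out$cost, out$cost_disc)      # no discounting
  # government perspective drops the non-medical component
  gov <- accumulate_outcomes(trace, p, perspective = "government")
  expect_equal(gov$cost, 4 * (0.33 * 808 + 4.89 * 21 + 92))

  # utilities 1 and zero discount: QALYs equal life years exactly
  p1 <- default_params
  p1$settings$annual_discount_rate <- 0
  p1$table$value[match(paste0("utilities.fc", 1:4), p1$table$id)] <- 1
  tr <- run_cohort(transition_matrix(p1, "beraprost"), 3, 80)
  o1 <- accumulate_outcomes(tr, p1)
  expect_equal(o1$qalys, o1$life_years, tolerance = 1e-15)
  expect_equal(o1$qalys_disc, o1$life_years, tolerance = 1e-15)

  # positive discounting strictly shrinks every outcome
  o <- accumulate_outcomes(
    run_cohort(transition_matrix(default_params, "sildenafil"), 2,
               default_params$settings$horizon_cycles),
    default_params
  )
  expect_lt(o$life_years_disc, o$life_years)
  expect_lt(o$qalys_disc, o$qalys)
  expect_lt(o$cost_disc, o$cost)
  expect_lte(o$qalys, o$life_years)
})

test_that("engine agrees with brute-force path enumeration at short horizons", {
  p <- default_params
  util <- tidy(p)$value[match(paste0("utilities.fc", 1:4), tidy(p)$id)]
  for (drug in c("sildenafil", "beraprost")) {
    M <- transition_matrix(p, drug)
    cost <- direct_medical_cost(p)$direct_medical +
      tidy(p)$value[tidy(p)$id == paste0("costs.drug_per_cycle.", drug)] +
      tidy(p)$value[match(paste0("costs.nonmedical_per_cycle.fc", 1:4),
                          tidy(p)$id)]
    for (H in c(4, 8)) {
      oracle <- enumerate_outcomes(M, 2, H, util, cost,
                                   p$settings$annual_discount_rate, 0.25)
      got <- accumulate_outcomes(run_cohort(M, 2, H), p, drug)
      expect_equal(got$life_years, unname(oracle["ly"]), tolerance = 1e-9)
      expect_equal(got$life_years_disc, unname(oracle["ly_disc"]), tolerance = 1e-9)
      expect_equal(got$qalys_disc, unname(oracle["qaly_disc"]), tolerance = 1e-9)
      expect_equal(got$cost, unname(oracle["cost"]), tolerance = 1e-9)
      expect_equal(got$cost_disc, unname(oracle["cost_disc"]), tolerance = 1e-9)
    }
  }
})

test_that("horizon selection modes behave as specified", {
  p <- default_params
  expect_equal(choose_horizon(p, "calibrated"), 140L)
  expect_equal(choose_horizon(p, "fixed", n = 120), 120L)
  expect_error(choose_horizon(p, "extinction", epsilon = 0), "epsilon")
  # certain death from every state: extinct after one cycle
  pd <- p
  pd$table$value[match(paste0("deaths.fc", 1:4), pd$table$id)] <- 1
  expect_equal(suppressWarnings(
    choose_horizon(pd, "extinction", epsilon = 1e-4)), 1L)
  # extinction horizon is finite and longer for a smaller epsilon
  h1 <- choose_horizon(p, "extinction", epsilon = 1e-1)
  h2 <- choose_horizon(p, "extinction", epsilon = 1e-2)
  expect_true(is.finite(h1) && is.finite(h2) && h2 > h1)
})

test_that("the calibrated horizon minimizes deviation on its own grid", {
  cal <- calibrate_horizon(default_params)
  expect_equal(cal$horizon_cycles[cal$chosen],
               default_params$settings$horizon_cycles)
  expect_equal(min(cal$deviation), cal$deviation[cal$chosen])
})
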