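# Probabilistic, one-way and threshold sensitivity analyses.

test_that("degenerate sampling reproduces the base case draw for draw", {
  p <- zero_se_params()
  psa <- run_psa(p, 3, n_draws = 3, seed = 7)
  base <- tidy(run_base_case(p, 3))
  for (d in 1:3) {
    draw <- psa[psa$draw == d, ]
    expect_equal(draw$cost_disc, base$cost_disc, tolerance = 1e-12)
    expect_equal(draw$qalys_disc, base$qalys_disc, tolerance = 1e-12)
  }
})

test_that("PSA is reproducible from its seed", {
  a <- run_psa(default_params, 2, n_draws = 25, seed = 11)
  b <- run_psa(default_params, 2, n_draws = 25, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ceac_a <- compute_ceac(a, wtp_grid = seq(0, 6000, 500))
  ceac_b <- compute_ceac(b, wtp_grid = seq(0, 6000, 500))
  expect_identical(as.data.frame(ceac_a), as.data.frame(ceac_b))
})

test_that("sampled parameter means obey the central limit theorem", {
  set.seed(402)
  n <- 3000
  fitted <- fit_moments(default_params$table)
  draws <- replicate(n, sample_parameters(default_params, fitted)$table$value)
  for (id in c("utilities.fc1", "transitions.fc3_to_fc4",
               "costs.cost_per_admission", "effects.sildenafil.rr_worsening")) {
    i <- match(id, default_params$table$id)
    expect_lt(abs(mean(draws[i, ]) - default_params$table$mean[i]),
              4 * default_params$table$se[i] / sqrt(n))
  }
  # fixed parameters never move
  i <- match("costs.drug_per_cycle.sildenafil", default_params$table$id)
  expect_true(all(draws[i, ] == 92))
})

test_that("sampled transition rows stay valid probability vectors", {
  set.seed(403)
  fitted <- fit_moments(default_params$table)
  for (rep in 1:200) {
    realization <- sample_parameters(default_params, fitted)
    for (drug in c("sildenafil", "beraprost")) {
      M <- suppressWarnings(transition_matrix(realization, drug))
      expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
    }
  }
})

test_that("CEAC probabilities are complementary and have the right limits", {
  psa <- run_psa(default_params, 3, n_draws = 150, seed = 5)
  ceac <- compute_ceac(psa, wtp_grid = seq(0, 10000, 1000))
  sums <- dplyr::summarise(dplyr::group_by(ceac, wtp),
                           s = sum(probability), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))
  expect_true(all(ceac$probability >= 0 & ceac$probability <= 1))

  # independent oracles for the limiting grid points
  wide <- tidyr::pivot_wider(psa, id_cols = "draw", names_from = "drug",
                             values_from = c("cost_disc", "qalys_disc"))
  p_cheaper <- mean(wide$cost_disc_sildenafil < wide$cost_disc_beraprost)
  at0 <- ceac$probability[ceac$wtp == 0 & ceac$drug == "sildenafil"]
  expect_equal(at0, p_cheaper)
  p_more_qaly <- mean(wide$qalys_disc_sildenafil > wide$qalys_disc_beraprost)
  big <- compute_ceac(psa, wtp_grid = 1e9)
  expect_equal(big$probability[big$drug == "sildenafil"], p_more_qaly)

  expect_error(compute_ceac(psa[0, ]), "empty")
  expect_error(compute_ceac(psa, wtp_grid = -5), "nonnegative")
})

test_that("one-way analysis ranges respect parameter domains", {
  ids <- c("deaths.fc1", "utilities.fc3", "costs.cost_per_admission")
  # deaths.fc1 low bound 0.002 - 1.96 * 0.009 < 0 must clip with a warning
  expect_warning(
    ow <- one_way_analysis(default_params, 2, ids = ids),
    "clipped"
  )
  expect_equal(nrow(ow), 3)
  d1 <- ow[ow$id == "deaths.fc1", ]
  expect_equal(d1$low, 0)
  expect_true(all(ow$swing >= 0))
  expect_equal(ow$swing, sort(ow$swing, decreasing = TRUE))
  # a parameter the ICER genuinely depends on must swing
  expect_gt(ow$swing[ow$id == "utilities.fc3"], 0)
})

test_that("originator pricing multiplies the ICER far above the generic one", {
  ps2 <- price_scenario_analysis(default_params, 2)
  ps3 <- price_scenario_analysis(default_params, 3)
  expect_equal(ps2$ratio_to_generic[ps2$scenario == "generic"], 1)
  expect_gt(ps2$ratio_to_generic[ps2$scenario == "originator"], 5)
  expect_gt(ps3$ratio_to_generic[ps3$scenario == "originator"], 3)
  # FC II is more price-sensitive than FC III
  expect_gt(ps2$ratio_to_generic[ps2$scenario == "originator"],
            ps3$ratio_to_generic[ps3$scenario == "originator"])
})

test_that("threshold search lands on the willingness-to-pay boundary", {
  p <- set_price_scenario(default_params, "originator")
  th <- threshold_price(p)
  expect_true(th$multiplier > 0 && th$multiplier < 1)
  # re-evaluate from scratch at the returned multiplier
  icers <- vapply(2:3, function(fc) {
    glance(run_base_case(
      set_price_scenario(default_params, "originator", th$multiplier), fc))$icer
  }, numeric(1))
  expect_lt(abs(max(icers) - th$wtp), 1)

  # generic price is already cost-effective: no reduction needed
  th0 <- threshold_price(set_price_scenario(default_params, "generic"))
  expect_equal(th0$percent_reduction, 0)

  # a higher threshold needs a smaller price reduction (monotonicity)
  th_hi <- threshold_price(p, wtp = 2 * default_params$settings$wtp_per_qaly)
  expect_lt(th_hi$percent_reduction, th$percent_reduction)
})
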