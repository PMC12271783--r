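test_that("distribution specs pick the right family per parameter group", {
  specs <- psa_distributions(base_params())
  fam <- stats::setNames(specs$family, specs$parameter)
  expect_equal(unname(fam[c("p_obs", "p_na", "p_valve", "p_suction")]),
               rep("beta", 4))
  expect_equal(unname(fam[c("ed_visit", "vats_admission")]), rep("gamma", 2))
  expect_equal(unname(fam[c("resolved_psp", "invasive_lung_procedure")]),
               rep("beta", 2))
  # mean 1.0 sits on the beta boundary: uniform fallback
  expect_equal(unname(fam["baseline"]), "uniform")
  # settings are scenario choices, fixed by default
  expect_equal(unname(fam[c("discount_rate", "age", "life_expectancy")]),
               rep("fixed", 3))
  expect_equal(unname(psa_distributions(base_params(),
                                        settings = "uniform")$family[
    psa_distributions(base_params())$parameter == "discount_rate"]),
    "uniform")
})

test_that("sampled parameters match the moment-matched distributions", {
  params <- base_params()
  draws <- sample_parameters(params, n = 10000, seed = 11)
  # beta for p_obs: mean within 3 standard errors of the base value
  sd_obs <- (0.896 - 0.769) / (2 * qnorm(0.975))
  expect_lt(abs(mean(draws$p_obs) - 0.846), 3 * sd_obs / sqrt(10000))
  expect_true(all(draws$p_obs > 0 & draws$p_obs < 1))
  # gamma for a cost: positive support, mean near base
  sd_vats <- (103362.83 - 69908.55) / (2 * qnorm(0.975))
  expect_lt(abs(mean(draws$vats_admission) - 86135.69),
            3 * sd_vats / sqrt(10000))
  expect_true(all(draws$vats_admission > 0))
  # utilities stay inside [0, 1]
  expect_true(all(draws$baseline >= 0.9 & draws$baseline <= 1))
  # fixed settings never move
  expect_true(all(draws$discount_rate == 0.03))
  expect_true(all(draws$age == 25))
  expect_error(sample_parameters(params, n = 0, seed = 1), "domain error")
})

test_that("sampling is bit-for-bit reproducible by seed", {
  params <- base_params()
  expect_identical(sample_parameters(params, n = 50, seed = 3),
                   sample_parameters(params, n = 50, seed = 3))
  expect_false(identical(sample_parameters(params, n = 50, seed = 3),
                         sample_parameters(params, n = 50, seed = 4)))
})

test_that("one-way sensitivity endpoints equal fresh full-model evaluations", {
  params <- base_params()
  entry <- one_way_dsa("discount_rate", params)
  # independent two-run recomputation of the frontier NMB at each end
  frontier_at <- function(rate) {
    p <- params
    p$discount_rate$base <- rate
    out <- strategy_outcomes(build_psp_tree(p), p)
    obs <- out$nmb[out$strategy == "observation_only"]
    obs - max(out$nmb[out$strategy != "observation_only"])
  }
  expect_equal(entry$nmb_at_low, frontier_at(0.01), tolerance = 1e-12)
  expect_equal(entry$nmb_at_high, frontier_at(0.05), tolerance = 1e-12)
  expect_equal(entry$bar_width, abs(entry$nmb_at_high - entry$nmb_at_low))
})

test_that("a degenerate range yields a zero-width bar", {
  params <- base_params()
  params$probabilities$p_obs$low <- 0.846
  params$probabilities$p_obs$high <- 0.846
  entry <- one_way_dsa("p_obs", params)
  expect_equal(entry$bar_width, 0)
  expect_error(one_way_dsa("not_a_parameter", base_params()), "unknown")
})

test_that("tornado covers all ranged parameters, widest bar first", {
  tor <- tornado_analysis(base_params())
  expect_equal(nrow(tor), 16)
  expect_true(all(diff(tor$bar_width) <= 0))
  expect_true(all(tor$bar_width >= 0))
  # strategy-metric tornado: needle-aspiration success cannot move the
  # observation-only NMB
  tor_obs <- tornado_analysis(base_params(), metric = "strategy",
                              strategy = "observation_only")
  expect_equal(tor_obs$bar_width[tor_obs$parameter == "p_na"], 0)
})

test_that("PSA draws satisfy the per-sample NMB identity and seed contract", {
  params <- base_params()
  psa <- run_psa(params, n = 40, seed = 5)
  expect_equal(psa$samples$nmb,
               psa$wtp * psa$samples$effectiveness - psa$samples$cost,
               tolerance = 1e-9)
  expect_equal(nrow(psa$samples), 40 * 4)
  again <- run_psa(params, n = 40, seed = 5)
  expect_identical(psa$samples, again$samples)
  expect_identical(psa$draws, again$draws)
})

test_that("all-fixed distributions reproduce the deterministic base case", {
  params <- base_params()
  specs <- psa_distributions(params)
  specs$family <- "fixed"
  specs$par1 <- specs$base
  specs$par2 <- specs$base
  psa <- run_psa(params, specs = specs, n = 25, seed = 9)
  base <- strategy_outcomes(params = params)
  for (s in base$strategy) {
    rows <- psa$samples[psa$samples$strategy == s, ]
    expect_equal(rows$cost,
                 rep(base$expected_cost[base$strategy == s], 25))
    expect_equal(rows$effectiveness,
                 rep(base$effectiveness[base$strategy == s], 25))
    expect_equal(rows$nmb, rep(base$nmb[base$strategy == s], 25))
  }
  expect_equal(psa$summary$p_optimal,
               as.numeric(base$strategy == rank_by_nmb(base)[1]))
})

test_that("acceptability curve is a partition and matches a direct recount", {
  params <- base_params()
  psa <- run_psa(params, n = 300, seed = 21)
  grid <- c(0, 50000, 100000)
  cc <- ceac(psa, grid)
  for (w in grid)
    expect_equal(sum(cc$p_optimal[cc$wtp == w]), 1, tolerance = 1e-9)
  # independent recount from the stored samples
  recount <- function(w, strat) {
    wins <- 0
    for (d in seq_len(psa$n)) {
      rows <- psa$samples[psa$samples$draw == d, ]
      nmb_d <- w * rows$effectiveness - rows$cost
      best <- rows$strategy[which(nmb_d == max(nmb_d))[1]]
      wins <- wins + (best == strat)
    }
    wins / psa$n
  }
  for (w in c(50000, 100000))
    expect_equal(cc$p_optimal[cc$wtp == w & cc$strategy == "observation_only"],
                 recount(w, "observation_only"))
  # at wtp = 0 the cheapest strategy in each draw wins
  expect_equal(cc$p_optimal[cc$wtp == 0 & cc$strategy == "observation_only"],
               recount(0, "observation_only"))
  expect_error(ceac(psa, numeric(0)), "domain error")
})

test_that("CEAC results do not depend on the order of the WTP grid", {
  psa <- run_psa(base_params(), n = 100, seed = 33)
  cc1 <- ceac(psa, c(0, 50000))
  cc2 <- ceac(psa, c(50000, 0))
  expect_equal(cc1$p_optimal[cc1$wtp == 50000],
               cc2$p_optimal[cc2$wtp == 50000])
  expect_equal(cc1$p_optimal[cc1$wtp == 0], cc2$p_optimal[cc2$wtp == 0])
})
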