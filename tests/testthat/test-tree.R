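test_that("default tree has 4 strategy subtrees and 11 terminal pathways", {
  tree <- build_psp_tree(base_params())
  expect_identical(tree$root$kind, "decision")
  expect_named(tree$root$children,
               c("observation_only", "needle_aspiration", "valve", "suction"))
  paths <- enumerate_paths(tree)
  expect_equal(nrow(paths), 11)
  # 3 pathways each for observation/aspiration/valve, 2 for suction
  expect_equal(unname(table(paths$strategy)[psp_strategies()]),
               array(c(3, 3, 3, 2)))
  # pathway probabilities partition each strategy
  mass <- tapply(paths$probability, paths$strategy, sum)
  expect_equal(as.vector(mass), rep(1, 4), tolerance = 1e-12)
  expect_true(all(paths$terminal_state %in% terminal_states()))
})

test_that("pathway costs are the summed service costs along the route", {
  params <- base_params()
  tree <- build_psp_tree(params)
  paths <- enumerate_paths(tree, "observation_only")
  success <- paths[grepl("observation_success", paths$path), ]
  # ED visit + chest radiograph
  expect_equal(success$cost, 1097.43 + 94.00)
  # failed observation -> suction -> VATS: ED + radiograph + catheter +
  # admission + VATS admission
  vats <- paths[paths$terminal_state == "resolved_post_vats", ]
  expect_equal(vats$cost,
               1097.43 + 94.00 + 1931.00 + 28858.84 + 86135.69)
  # path_cost on the reconstructed node sequence agrees
  for (i in seq_len(nrow(paths))) {
    nodes <- nodes_along(tree, "observation_only", paths$path[i])
    expect_equal(path_cost(nodes, params), paths$cost[i])
  }
})

test_that("path_cost contract: empty service path is 0, non-terminal leaf errors", {
  leaf <- terminal_node("t", "resolved_no_vats")
  expect_equal(path_cost(list(leaf), base_params()), 0)
  branch <- chance_node("c", list(list(prob = 1, node = leaf)))
  expect_error(path_cost(list(branch), base_params()), "structural error")
})

test_that("structural options change the affected pathways only", {
  params <- base_params()
  rebill <- build_psp_tree(params, psp_structure(valve_failure = "rebill_catheter"))
  default <- build_psp_tree(params)
  pv_d <- enumerate_paths(default, "valve")
  pv_r <- enumerate_paths(rebill, "valve")
  # second catheter billed on both valve-failure pathways
  expect_equal(pv_r$cost - pv_d$cost, c(0, 1931, 1931))

  replace <- build_psp_tree(params, psp_structure(vats_billing = "replace"))
  pr <- enumerate_paths(replace)
  pd <- enumerate_paths(default)
  is_vats <- pd$terminal_state == "resolved_post_vats"
  expect_equal(pr$cost[is_vats], pd$cost[is_vats] - 28858.84)
  expect_equal(pr$cost[!is_vats], pd$cost[!is_vats])

  expect_error(psp_structure(valve_failure = "amputate"),
               "configuration error")
  expect_error(psp_structure(observation_failure = "discharge"),
               "configuration error")
  expect_error(build_psp_tree(params, structure = list()),
               "configuration error")
})

test_that("rollback reproduces forced expectations on degenerate trees", {
  lone <- structure(list(
    root = decision_node("root", list(
      only = terminal_node("t", "resolved_no_vats", cost = 100))),
    strategies = "only", structure = psp_structure()), class = "psp_tree")
  rb <- rollback(lone)
  expect_equal(rb$expected_cost, 100)
  expect_equal(rb$p_resolved_no_vats, 1)

  coin <- structure(list(
    root = decision_node("root", list(
      only = chance_node("c", list(
        list(prob = 0.75, node = terminal_node("a", "resolved_no_vats", cost = 100)),
        list(prob = 0.25, node = terminal_node("b", "resolved_post_vats", cost = 1000)))))),
    strategies = "only", structure = psp_structure()), class = "psp_tree")
  expect_equal(rollback(coin)$expected_cost, 325)
})

test_that("rollback equals exhaustive path enumeration on the PSP tree", {
  tree <- build_psp_tree(base_params())
  rb <- rollback(tree)
  oracle <- oracle_rollback(tree)
  for (i in seq_len(nrow(rb))) {
    s <- rb$strategy[i]
    expect_equal(rb$expected_cost[i], oracle[[s]]$cost, tolerance = 1e-9)
    expect_equal(rb$p_resolved_no_vats[i],
                 unname(oracle[[s]]$dist["resolved_no_vats"]),
                 tolerance = 1e-12)
  }
  # terminal-state distribution partitions each strategy
  expect_equal(rb$p_resolved_no_vats + rb$p_resolved_post_vats,
               rep(1, 4), tolerance = 1e-12)
})

test_that("rollback equals path enumeration on random small trees", {
  withr::local_seed(42)
  for (rep in seq_len(200)) {
    tree <- random_tree()
    rb <- rollback(tree)
    oracle <- oracle_expectation(tree$root$children$only)
    expect_equal(rb$expected_cost, oracle$cost, tolerance = 1e-9)
    expect_equal(rb$p_resolved_no_vats,
                 unname(oracle$dist["resolved_no_vats"]), tolerance = 1e-9)
    expect_equal(rb$p_resolved_no_vats + rb$p_resolved_post_vats, 1,
                 tolerance = 1e-12)
  }
})

test_that("expected cost is monotone in every service cost", {
  params <- base_params()
  base_cost <- rollback(build_psp_tree(params))$expected_cost
  for (nm in names(params$costs)) {
    bumped <- params
    bumped$costs[[nm]]$base <- bumped$costs[[nm]]$base + 500
    bumped$costs[[nm]]$high <- bumped$costs[[nm]]$high + 500
    up <- rollback(build_psp_tree(bumped))$expected_cost
    expect_true(all(up >= base_cost),
                info = paste("cost bump in", nm, "lowered an expected cost"))
  }
})

test_that("certain initial success collapses a strategy to its success path", {
  params <- base_params()
  params$probabilities$p_obs$base <- 1
  params$probabilities$p_obs$high <- 1
  rb <- rollback(build_psp_tree(params))
  expect_identical(rb$expected_cost[rb$strategy == "observation_only"],
                   1097.43 + 94.00)
  expect_identical(rb$p_resolved_no_vats[rb$strategy == "observation_only"], 1)
})

test_that("malformed chance nodes are rejected", {
  expect_error(chance_node("bad", list(
    list(prob = 0.6, node = terminal_node("a", "resolved_no_vats", cost = 0)),
    list(prob = 0.3, node = terminal_node("b", "resolved_no_vats", cost = 0)))),
    "sum to")
  expect_error(chance_node("bad", list(
    list(prob = 1.2, node = terminal_node("a", "resolved_no_vats", cost = 0)),
    list(prob = -0.2, node = terminal_node("b", "resolved_no_vats", cost = 0)))),
    "\\[0, 1\\]")
})
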