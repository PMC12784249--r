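r3_net <- build_egpr_network(
  build_egpr_rules("r3", toy$model, toy$layers, depth = 1L))

test_that("the worked-example reaction yields exactly the two printed cut sets", {
  for (eng in c("dual", "closure")) {
    sol <- enumerate_mcs(r3_net, engine = eng)
    expect_length(sol, 2L)
    expect_equal(sol[[1]], c("g3-", "g4-"))
    expect_equal(sol[[2]], c("g3-", "g6+", "g7-"))
  }
})

test_that("trivial rule shapes give the expected cut sets", {
  # single input gene: the only cut is its knock-out
  expect_same_sets(enumerate_mcs(net_for("g"), engine = "dual"),
                   list("g-"))
  # AND of inputs: each single knock-out cuts
  expect_same_sets(enumerate_mcs(net_for("g1 and g2"), engine = "dual"),
                   list("g1-", "g2-"))
  # OR of inputs: only the joint knock-out cuts
  expect_same_sets(enumerate_mcs(net_for("g1 or g2"), engine = "dual"),
                   list(c("g1-", "g2-")))
  # negated input: the knock-in is the only (singleton) cut
  expect_same_sets(enumerate_mcs(net_for("not g"), engine = "dual"),
                   list("g+"))
})

test_that("dual MILP engine and brute-force closure oracle agree on random rule sets", {
  for (seed in 1:30) {
    rs <- random_rule_set(n_genes = 2 + (seed %% 5), inhibition = 0.4,
                          seed = seed)
    net <- build_egpr_network(rs)
    a <- enumerate_mcs(net, engine = "dual")
    b <- enumerate_mcs(net, engine = "closure")
    expect_same_sets(a, b)
  }
})

test_that("solutions are sound, minimal, valid and antichain", {
  for (seed in c(3, 7, 11, 19)) {
    rs <- random_rule_set(n_genes = 6, inhibition = 0.5, seed = seed)
    net <- build_egpr_network(rs)
    sol <- enumerate_mcs(net, engine = "dual")
    for (s in sol) {
      v <- verify_interventions(net, s)
      expect_true(v$blocks)
      expect_true(v$minimal)
      # no gene appears with both directions
      expect_equal(anyDuplicated(gmisr:::atom_gene(s)), 0L)
    }
    for (i in seq_along(sol)) for (j in seq_along(sol)) {
      if (i != j) expect_false(all(sol[[i]] %in% sol[[j]]))
    }
  }
})

test_that("disabling knock-ins reproduces the knock-out-only behaviour", {
  for (seed in c(2, 9, 14)) {
    rs <- random_rule_set(n_genes = 5, inhibition = 0.5, seed = seed)
    net <- build_egpr_network(rs)
    full <- enumerate_mcs(net, engine = "dual")
    restricted <- enumerate_mcs(net, engine = "dual", ko_only = TRUE)
    expect_true(all(vapply(restricted, function(s)
      all(gmisr:::atom_dir(s) == "KO"), NA)))
    # the restricted run's solutions are exactly the KO-only minimal cuts:
    # they block, and their KO-only minimality is direction-preserved
    ko_from_full <- Filter(function(s) all(gmisr:::atom_dir(s) == "KO"),
                           full)
    for (s in ko_from_full)
      expect_true(any(vapply(restricted, identical, NA, s)))
  }
})

test_that("verify_interventions applies the definition checks", {
  v <- verify_interventions(r3_net, c("g3-", "g4-"))
  expect_true(v$blocks)
  expect_true(v$minimal)
  # proper subset of a printed minimal set cannot block
  v <- verify_interventions(r3_net, "g3-")
  expect_false(v$blocks)
  # a blocking superset is flagged non-minimal
  v <- verify_interventions(r3_net, c("g3-", "g4-", "g6-"))
  expect_true(v$blocks)
  expect_false(v$minimal)
  # knocking out and in the same gene is invalid
  expect_error(verify_interventions(r3_net, c("g3-", "g3+")),
               "at the same time")
})

test_that("the closure engine refuses oversized instances", {
  net <- net_for("g1 or g2 or g3")
  expect_error(enumerate_mcs(net, engine = "closure", guard = 10),
               "exceed the guard")
})

test_that("solution caps truncate with a flag", {
  sol <- enumerate_mcs(r3_net, params = milp_params(max_solutions = 1))
  expect_length(sol, 1L)
  expect_true(attr(sol, "truncated"))
  sol1 <- enumerate_mcs(r3_net, params = milp_params(max_size = 2))
  expect_same_sets(sol1, list(c("g3-", "g4-")))
})
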