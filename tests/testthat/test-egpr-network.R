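test_that("a single-input-gene network has the forced structure", {
  net <- net_for("g")
  # entities: g, y, u, e (x ON/OFF) plus target ON/OFF
  expect_equal(length(net$H), 1L)
  expect_equal(length(unlist(net$H)), 4L)       # |H(k)| = 4 |B(k)|
  expect_length(net$exch_out, 2L)
  # every y/u/e node carries exactly one input exchange
  expect_equal(anyDuplicated(net$exch_in), 0L)
  expect_setequal(net$exch_in,
                  c(unlist(net$H), "e@g_ON", "e@g_OFF"))
})

test_that("knock-out machinery follows the exchange-removal semantics", {
  net <- net_for("g")
  on <- paste0(net$target, "_ON")
  off <- paste0(net$target, "_OFF")
  # free input: both sides derivable
  cl <- forward_closure(net, character())
  expect_true(all(c(on, off) %in% cl))
  # knock-out: ON side lost, OFF side kept
  cl <- forward_closure(net, "g-")
  expect_false(on %in% cl)
  expect_true(off %in% cl)
  # knock-in: OFF side lost, ON side kept
  cl <- forward_closure(net, "g+")
  expect_true(on %in% cl)
  expect_false(off %in% cl)
})

test_that("negation compiles through De Morgan to the opposite node", {
  net <- net_for("not g")
  on_gates <- Filter(function(gt) gt$output == paste0(net$target, "_ON"),
                     net$gates)
  expect_true(any(vapply(on_gates, function(gt) "g_OFF" %in% gt$inputs, NA)))
  off_gates <- Filter(function(gt) gt$output == paste0(net$target, "_OFF"),
                      net$gates)
  expect_true(any(vapply(off_gates, function(gt) "g_ON" %in% gt$inputs, NA)))
  # blocking a negated-input target needs the knock-in
  expect_true(blocks_target(net, "g+"))
  expect_false(blocks_target(net, "g-"))
})

test_that("spontaneous reactions cannot be compiled", {
  m <- single_reaction_model("g1")
  er <- build_egpr_rules("rOUT", m, depth = 0L)
  expect_error(build_egpr_network(er), "spontaneous")
})

test_that("gate count equals the number of OR branches (construction audit)", {
  for (seed in 1:10) {
    rs <- random_rule_set(n_genes = 5, seed = seed)
    net <- build_egpr_network(rs)
    expect_equal(length(net$gates), net$n_or_branches)
    # gate outputs are single nodes; all gates consume at least one node
    expect_true(all(vapply(net$gates, function(g) length(g$inputs) >= 1, NA)))
  }
})

test_that("closure is a unique monotone fixpoint", {
  rs <- random_rule_set(n_genes = 5, inhibition = 0.5, seed = 42)
  net <- build_egpr_network(rs)
  cl1 <- forward_closure(net, character())
  cl2 <- forward_closure(net, character())
  expect_identical(cl1, cl2)
  # committed sides only, for intervened genes
  g <- net$genes[[1]]
  cl <- forward_closure(net, paste0(g, "-"))
  expect_true(paste0("y@", g, "_OFF") %in% cl)
  expect_false(paste0("y@", g, "_ON") %in% cl)
})

test_that("interventions outside B(k) are rejected", {
  net <- net_for("g")
  expect_error(forward_closure(net, "zz-"), "outside the network")
})

test_that("stoichiometry matches the gate/exchange structure", {
  net <- net_for("g1 and g2")
  S <- egpr_stoichiometry(net)
  expect_equal(nrow(S), length(net$nodes))
  expect_equal(ncol(S), length(net$gates) + length(net$exch_in) +
                 length(net$exch_out))
  # every gate column produces exactly one node
  gate_cols <- seq_along(net$gates)
  expect_true(all(Matrix::colSums(S[, gate_cols, drop = FALSE] > 0) == 1))
})

test_that("the network serialises to a JSON debug dump", {
  net <- net_for("g1 or g2")
  path <- withr::local_tempfile(fileext = ".json")
  write_egpr_network(net, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$reaction, "rT")
  expect_length(j$gates, length(net$gates))
})

test_that("augmented gene semantics match the intervention contract", {
  # for any gene state: no intervention leaves both rule-driven sides,
  # KO forces (OFF, not ON), KI forces (ON, not OFF) -- the two augmentation
  # readings (e OR'd late vs gated early) coincide on this feasible space
  net <- net_for("g1 or not g2")
  for (g in net$genes) {
    cl_ko <- forward_closure(net, paste0(g, "-"))
    expect_false(paste0(g, "_ON") %in% cl_ko)
    expect_true(paste0(g, "_OFF") %in% cl_ko)
    cl_ki <- forward_closure(net, paste0(g, "+"))
    expect_true(paste0(g, "_ON") %in% cl_ki)
    expect_false(paste0(g, "_OFF") %in% cl_ki)
    cl0 <- forward_closure(net, character())
    expect_true(all(paste0(g, c("_ON", "_OFF")) %in% cl0))
  }
})
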