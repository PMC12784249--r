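toy_fit <- gmis(toy$model, toy$layers)

test_that("the worked example yields six gMIS, four of them knock-out-only", {
  expect_length(toy_fit$sets, 6L)
  ko_only <- vapply(toy_fit$sets, function(s)
    all(gmisr:::atom_dir(s) == "KO"), NA)
  expect_equal(sum(ko_only), 4L)
  expect_setequal(
    vapply(toy_fit$sets, paste, "", collapse = ";"),
    c("g1-", "g2-", "g5-", "g7+", "g3-;g4-", "g3-;g6+;g7-"))
})

test_that("a knock-out-only run recovers exactly the four gMCS", {
  fit_ko <- gmis(toy$model, toy$layers, ko_only = TRUE)
  expect_length(fit_ko$sets, 4L)
  expect_setequal(vapply(fit_ko$sets, paste, "", collapse = ";"),
                  c("g1-", "g2-", "g5-", "g3-;g4-"))
  # identical to the KO-only members of the full catalogue
  full_ko <- Filter(function(s) all(gmisr:::atom_dir(s) == "KO"),
                    toy_fit$sets)
  expect_setequal(vapply(fit_ko$sets, paste, "", collapse = ";"),
                  vapply(full_ko, paste, "", collapse = ";"))
})

test_that("intervention sets classify by composition", {
  expect_equal(classify_interventions("gA-"), "essential-gene")
  expect_equal(classify_interventions(c("gA-", "gB-")), "SL")
  expect_equal(classify_interventions("gA+"), "TSG")
  expect_equal(classify_interventions(c("gA-", "gB+")), "SDL")
  expect_equal(classify_interventions(c("gA+", "gB+")), "TSGC")
  expect_equal(classify_interventions(c("gA-", "gB-", "gC+")), "mixed")
  cats <- stats::setNames(toy_fit$category,
                          vapply(toy_fit$sets, paste, "", collapse = ";"))
  expect_equal(unname(cats[["g7+"]]), "TSG")
  expect_equal(unname(cats[["g3-;g4-"]]), "SL")
  expect_equal(unname(cats[["g3-;g6+;g7-"]]), "mixed")
})

test_that("every emitted gMIS is lethal and subset-minimal", {
  for (i in seq_along(toy_fit$sets)) {
    s <- toy_fit$sets[[i]]
    expect_lte(max_biomass(toy$model,
                           blocked_reactions(toy_fit$gf, s)), 1e-6)
    if (length(s) > 1) {
      for (j in seq_along(s)) {
        expect_gt(max_biomass(toy$model,
                              blocked_reactions(toy_fit$gf, s[-j])), 1e-6)
      }
    }
    expect_equal(anyDuplicated(gmisr:::atom_gene(s)), 0L)
  }
  # antichain
  for (i in seq_along(toy_fit$sets)) for (j in seq_along(toy_fit$sets)) {
    if (i != j)
      expect_false(all(toy_fit$sets[[i]] %in% toy_fit$sets[[j]]))
  }
})

test_that("primal and dual gMIS engines agree on random toys", {
  for (seed in 1:12) {
    rim <- random_imr_model(n_metabolites = 2, n_layers = 1 + (seed %% 2),
                            inhibition = 0.4, p_regulated = 0.5,
                            regulators_per_target = 1.2, seed = seed)
    pp <- milp_params(max_size = 3)
    mcs <- lapply(rim$model$reactions, function(r) {
      if (rim$model$gpr[[r]]$op == "true") return(list())
      enumerate_mcs(build_egpr_network(
        build_egpr_rules(r, rim$model, rim$layers, depth = 2L)),
        params = pp, engine = "dual")
    })
    names(mcs) <- rim$model$reactions
    gf <- build_gf(mcs)
    a <- enumerate_gmis(rim$model, gf, max_length = 3, engine = "exhaustive")
    b <- enumerate_gmis(rim$model, gf, max_length = 3, engine = "dual")
    expect_equal(lapply(a, `[[`, "interventions"),
                 lapply(b, `[[`, "interventions"))
  }
})

test_that("negation-free models admit no knock-in interventions", {
  for (seed in 1:8) {
    rim <- random_imr_model(n_metabolites = 2, n_layers = 1,
                            inhibition = 0, seed = seed)
    fit <- gmis(rim$model, rim$layers, depth = 2L, max_length = 3)
    expect_true(all(vapply(fit$sets, function(s)
      all(gmisr:::atom_dir(s) == "KO"), NA)))
    fit_ko <- gmis(rim$model, rim$layers, depth = 2L, max_length = 3,
                   ko_only = TRUE)
    expect_equal(vapply(fit$sets, paste, "", collapse = ";"),
                 vapply(fit_ko$sets, paste, "", collapse = ";"))
  }
})

test_that("atoms outside F cannot contribute to any gMIS", {
  # an atom absent from every F row never changes blocked_reactions, so
  # restricting candidates to F atoms is lossless
  gf <- toy_fit$gf
  outside <- "g9-"
  expect_false(outside %in% gf$atoms)
  for (s in toy_fit$sets) {
    expect_equal(blocked_reactions(gf, c(s, outside)),
                 blocked_reactions(gf, s))
  }
})

test_that("gmis objects support the standard methods", {
  expect_output(print(toy_fit), "6 gMIS")
  sm <- summary(toy_fit)
  expect_equal(sm$n, 6L)
  expect_equal(sm$n_gmcs, 4L)
  df <- as.data.frame(toy_fit)
  expect_equal(nrow(df), 6L)
  expect_true(all(c("id", "length", "category", "interventions") %in%
                    names(df)))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_silent(plot(toy_fit))
  grDevices::dev.off()
})
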