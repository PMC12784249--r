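test_that("the worked-example fixture has the documented shape", {
  expect_length(toy$model$metabolites, 3L)
  expect_length(toy$model$reactions, 4L)
  # seven genes across GPRs and regulation
  all_genes <- union(toy$model$genes,
                     unique(c(toy$layers[[1]]$source,
                              toy$layers[[1]]$target)))
  expect_length(all_genes, 7L)
  expect_equal(sum(toy$layers[[1]]$sign == -1), 2L)  # inhibition present
})

test_that("random models are deterministic: same seed, identical serialisation", {
  a <- random_imr_model(seed = 7)
  b <- random_imr_model(seed = 7)
  fa <- withr::local_tempfile(fileext = ".json")
  fb <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(a$model, fa)
  write_metabolic_model(b$model, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_equal(lapply(a$layers, as.data.frame),
               lapply(b$layers, as.data.frame))
  # different seeds diverge
  c <- random_imr_model(seed = 8)
  expect_false(identical(vapply(a$model$gpr, format_rule, ""),
                         vapply(c$model$gpr, format_rule, "")))
})

test_that("every drawn model sustains biomass production", {
  for (seed in 1:10) {
    rim <- random_imr_model(n_metabolites = 1 + seed %% 3,
                            n_layers = seed %% 3, seed = seed)
    expect_gt(max_biomass(rim$model), 1e-6)
  }
})

test_that("zero regulatory layers degenerate to a purely metabolic run", {
  rim <- random_imr_model(n_layers = 0, seed = 3)
  expect_length(rim$layers, 0L)
  fit <- gmis(rim$model, rim$layers, depth = 1L, max_length = 3)
  fit_ko <- gmis(rim$model, rim$layers, depth = 1L, max_length = 3,
                 ko_only = TRUE)
  expect_equal(vapply(fit$sets, paste, "", collapse = ";"),
               vapply(fit_ko$sets, paste, "", collapse = ";"))
})

test_that("random rule sets are acyclic, seeded and within the gene budget", {
  for (seed in 1:20) {
    rs <- random_rule_set(n_genes = 2 + seed %% 5, seed = seed)
    expect_s3_class(rs, "egpr_rules")
    expect_lte(length(rs$genes), 6L)
    expect_silent(gmisr:::check_rules_acyclic(rs))
    rs2 <- random_rule_set(n_genes = 2 + seed %% 5, seed = seed)
    expect_equal(format_rule(rs$gpr), format_rule(rs2$gpr))
  }
})

test_that("random expression is seeded, bounded and mixes HIGH with LOW", {
  m1 <- random_expression(toy$model, n_samples = 3, seed = 5)
  m2 <- random_expression(toy$model, n_samples = 3, seed = 5)
  expect_identical(m1, m2)
  expect_true(all(m1 >= 0))
  st <- binarize_expression(m1[, 1])
  expect_true(any(unclass(st) == "HIGH") || any(unclass(st) == "LOW"))
  # across a few seeds both states occur
  states <- unlist(lapply(1:5, function(s)
    unclass(binarize_expression(random_expression(toy$model, 2, seed = s)[, 1]))))
  expect_setequal(unique(states), c("HIGH", "LOW"))
  # all-silent mixture produces no essential-gene calls downstream
  silent <- random_expression(toy$model, n_samples = 1, p_silent = 1,
                              seed = 9)
  expect_true(all(silent < 1))
  fit <- gmis(toy$model, toy$layers)
  preds <- predict(fit, silent)
  expect_equal(sum(preds$role == "essential"), 0L)
})

test_that("single-column expression matrices round-trip through TSV", {
  m <- random_expression(toy$model, n_samples = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  m2 <- read_expression(path)
  expect_equal(m2, m)
})
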