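test_that("expression binarisation follows the threshold and missing policy", {
  st <- binarize_expression(c(a = 5.0, b = 0.2), threshold = 1.0)
  expect_equal(unclass(st)[["a"]], "HIGH")
  expect_equal(unclass(st)[["b"]], "LOW")
  # unmeasured genes resolve LOW by default, HIGH when configured
  expect_equal(gmisr:::state_of(st, "zz"), "LOW")
  st_hi <- binarize_expression(c(a = 5.0), missing = "HIGH")
  expect_equal(gmisr:::state_of(st_hi, "zz"), "HIGH")
  # TPM-scale inputs must be non-negative
  expect_error(binarize_expression(c(a = -1)), "negative")
  # pluggable rule: upper-quartile threshold
  st_q <- binarize_expression(c(a = 1, b = 2, c = 3, d = 10),
                              threshold = function(v) v >= quantile(v, .75))
  expect_equal(sum(unclass(st_q) == "HIGH"), 1L)
})

ezh2_set <- c("EZH2-", "JUN-", "RELA+")

test_that("essential-gene calls require a unique HIGH knock-out and HIGH knock-ins", {
  # call made: EZH2 the only HIGH knock-out, knock-in partner RELA HIGH
  st <- binarize_expression(c(EZH2 = 5, JUN = 0.1, RELA = 4))
  rec <- predict_essential_genes(list(ezh2_set), st)
  expect_equal(rec$gene, "EZH2")
  expect_equal(rec$role, "essential")
  expect_equal(rec$gmis, "EZH2-;JUN-;RELA+")
  # withdrawn: the knock-in gene is LOW
  st2 <- binarize_expression(c(EZH2 = 5, JUN = 0.1, RELA = 0.2))
  expect_equal(nrow(predict_essential_genes(list(ezh2_set), st2)), 0L)
  # withdrawn: knock-out uniqueness fails (JUN also HIGH)
  st3 <- binarize_expression(c(EZH2 = 5, JUN = 5, RELA = 4))
  expect_equal(nrow(predict_essential_genes(list(ezh2_set), st3)), 0L)
})

test_that("tumor-suppressor calls mirror the essential-gene rule", {
  # SDL pair: DUSP4 knock-in called when its knock-out partner is LOW
  sdl <- c("DUSP4+", "GADD45B-")
  st <- binarize_expression(c(DUSP4 = 0.3, GADD45B = 0.2))
  rec <- predict_tumor_suppressors(list(sdl), st)
  expect_equal(rec$gene, "DUSP4")
  expect_equal(rec$role, "tumor-suppressor")
  # all-knock-in complex: the one LOW member is the call
  tsgc <- c("CDK5RAP3+", "SHC1+")
  st2 <- binarize_expression(c(CDK5RAP3 = 4, SHC1 = 0.1))
  rec2 <- predict_tumor_suppressors(list(tsgc), st2)
  expect_equal(rec2$gene, "SHC1")
  # withdrawn when a knock-out partner is HIGH
  st3 <- binarize_expression(c(DUSP4 = 0.3, GADD45B = 5))
  expect_equal(nrow(predict_tumor_suppressors(list(sdl), st3)), 0L)
  # withdrawn when knock-in uniqueness fails (both LOW)
  st4 <- binarize_expression(c(CDK5RAP3 = 0.1, SHC1 = 0.1))
  expect_equal(nrow(predict_tumor_suppressors(list(tsgc), st4)), 0L)
})

test_that("essential and tumor-suppressor rules are HIGH/LOW, KO/KI mirror images", {
  flip_atoms <- function(s) {
    d <- gmisr:::atom_dir(s)
    paste0(gmisr:::atom_gene(s), ifelse(d == "KO", "+", "-"))
  }
  for (seed in 1:20) {
    rs <- with(list(), {
      set.seed(seed)
      genes <- paste0("G", 1:4)
      n <- sample(2:4, 1)
      atoms <- paste0(sample(genes, n), sample(c("-", "+"), n, TRUE))
      vals <- stats::setNames(sample(c(0.1, 5), 4, TRUE), genes)
      list(set = atoms, vals = vals)
    })
    st <- binarize_expression(rs$vals)
    mirrored <- binarize_expression(5.1 - rs$vals)  # HIGH <-> LOW
    a <- predict_essential_genes(list(rs$set), st)
    b <- predict_tumor_suppressors(list(flip_atoms(rs$set)), mirrored)
    expect_equal(a$gene, b$gene)
  }
})

test_that("calls only cite gMIS the gene belongs to, with re-checkable support", {
  sets <- list(c("A-", "B-"), c("C-", "D+"))
  st <- binarize_expression(c(A = 5, B = 0.1, C = 5, D = 4))
  rec <- predict_essential_genes(sets, st)
  for (i in seq_len(nrow(rec))) {
    support <- strsplit(rec$gmis[i], "|", fixed = TRUE)[[1]]
    for (sup in support) {
      atoms <- strsplit(sup, ";", fixed = TRUE)[[1]]
      expect_true(paste0(rec$gene[i], "-") %in% atoms)
    }
  }
})

test_that("adaptation check catches repressor-release and passes inert cases", {
  # partner activates when its repressor is removed: JUN = not EZH2
  fam <- list(JUN = rule_not(rule_gene("EZH2")))
  st <- binarize_expression(c(EZH2 = 5, JUN = 0.1, RELA = 4))
  expect_equal(adaptation_check(fam, st, "EZH2-", c("JUN-", "RELA+")),
               "failed")
  # no regulatory path from the intervention to any partner
  fam2 <- list(OTHER = rule_gene("EZH2"))
  expect_equal(adaptation_check(fam2, st, "EZH2-", c("JUN-", "RELA+")),
               "passed")
  # knock-in partner deactivated by the intervention: RELA = EZH2
  fam3 <- list(RELA = rule_gene("EZH2"))
  expect_equal(adaptation_check(fam3, st, "EZH2-", c("JUN-", "RELA+")),
               "failed")
  # cyclic rule families are unsupported
  fam_cyc <- list(A = rule_gene("B"), B = rule_gene("A"))
  expect_error(adaptation_check(fam_cyc, st, "A-", "B-"), "cyclic")
})

test_that("adaptation propagation is idempotent", {
  fam <- list(b = rule_not(rule_gene("a")), c = rule_gene("b"))
  st <- binarize_expression(c(a = 5, b = 0.1, c = 0.1))
  first <- adaptation_check(fam, st, "a-", c("b-", "c-"))
  second <- adaptation_check(fam, st, "a-", c("b-", "c-"))
  expect_identical(first, second)
  expect_equal(first, "failed")   # removing a releases b, which activates c
})

test_that("dependency scores flag essentiality below -0.6", {
  expect_true(depmap_essential(-0.7))
  expect_false(depmap_essential(-0.5))
  expect_true(is.na(depmap_essential(NA)))
  expect_equal(depmap_essential(c(-1, -0.6, 0, NA)),
               c(TRUE, FALSE, FALSE, NA))
})

test_that("predict.gmis maps expression onto the catalogue per sample", {
  toy_fit <- gmis(toy$model, toy$layers)
  expr <- matrix(c(5, 5, 0.1, 5, 5, 0.2, 0.2), ncol = 1,
                 dimnames = list(c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
                                 "s1"))
  preds <- predict(toy_fit, expr)
  # HIGH singleton knock-outs g1/g2/g5 are called, plus g4 as the unique
  # HIGH knock-out of {g3-, g4-} (g3 is LOW)
  ess <- preds[preds$role == "essential", ]
  expect_setequal(ess$gene, c("g1", "g2", "g4", "g5"))
  # g7 via the singleton knock-in {g7+} (g7 LOW); g6 via {g3-, g6+, g7-}
  # (g6 the unique LOW knock-in, knock-out partners g3/g7 LOW)
  ts <- preds[preds$role == "tumor-suppressor", ]
  expect_setequal(ts$gene, c("g6", "g7"))
  expect_true(all(preds$adaptation %in% c("passed", "failed")))
  # singleton support {g2-} has no partners, so no adaptation can fail it
  expect_equal(ess$adaptation[ess$gene == "g2"], "passed")
})
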