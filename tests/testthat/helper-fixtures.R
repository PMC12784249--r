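# shared fixtures for the suite: everything is built in code

toy <- toy_imr_model()

# a model whose only reaction network is R = <gpr> over free input genes
single_reaction_model <- function(gpr) {
  S <- matrix(c(1, -1), 1, 2,
              dimnames = list("X", c("rT", "rOUT")))
  metabolic_model(S, 0, 1000, biomass = "rOUT",
                  gpr = list(rT = gpr), id = "single")
}

# eGPR network for a bare rule string with no regulation
net_for <- function(gpr, layers = list(), depth = 0L) {
  m <- single_reaction_model(gpr)
  build_egpr_network(build_egpr_rules("rT", m, layers, depth = depth))
}

# intervention lists as canonical sorted character sets for comparison
setlist <- function(sol) unname(lapply(sol, as.character))

expect_same_sets <- function(a, b) {
  expect_equal(setlist(a), setlist(b))
}
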