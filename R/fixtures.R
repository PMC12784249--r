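# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' The bundled worked-example iMR model
#'
#' A small integrated metabolic-regulatory model used throughout the
#' package's documentation and tests: three metabolites (A, B, C), four
#' reactions and seven genes, with one signed regulatory layer.
#'
#' Metabolic layer (all reactions irreversible, bounds \[0, 1000\]):
#' * `r1`: `-> A`, GPR `g1`
#' * `r2`: `A -> B`, GPR `g2`
#' * `r3`: `A -> C`, GPR `g3 or g4`
#' * `rBIO`: `B + C ->` (biomass), GPR `g5`
#'
#' Regulatory layer: `g6 -| g4` (inhibition), `g7 -> g4` (activation),
#' `g7 -| g2` (inhibition). Under the default combination convention the
#' regulated rules are `g4 = g7 or not g6` and `g2 = not g7`.
#'
#' This transcription of the worked example is pinned down by the outcomes
#' it must reproduce rather than by a canonical drawing: the per-reaction
#' minimal cut sets of `r3` are exactly `{g3-, g4-}` and `{g3-, g6+, g7-}`,
#' and the full pipeline yields six gMIS blocking the biomass reaction, of
#' which four are knock-out-only gMCS. Where a different arrangement of the
#' same arcs would also be drawable, the one reproducing those outcomes was
#' adopted.
#'
#' @return List with elements `model` (a `metabolic_model`) and `layers`
#'   (list with one `regulatory_layer`).
#' @examples
#' toy <- toy_imr_model()
#' fit <- gmis(toy$model, toy$layers)
#' length(fit$sets)
#' @export
toy_imr_model <- function() {
  S <- matrix(c(1, 0, 0,
                -1, 1, 0,
                -1, 0, 1,
                0, -1, -1),
              nrow = 3, ncol = 4,
              dimnames = list(c("A", "B", "C"),
                              c("r1", "r2", "r3", "rBIO")))
  model <- metabolic_model(S, lower = 0, upper = 1000, biomass = "rBIO",
                           gpr = list(r1 = "g1", r2 = "g2",
                                      r3 = "g3 or g4", rBIO = "g5"),
                           id = "toy_imr")
  layer <- regulatory_layer(
    data.frame(source = c("g6", "g7", "g7"),
               target = c("g4", "g4", "g2"),
               sign = c(-1, 1, -1)),
    layer_index = 1L)
  list(model = model, layers = list(layer))
}

#' Generate a random iMR model
#'
#' Draws a connected substrate-to-biomass metabolic toy with random GPR
#' rules and random signed acyclic regulatory layers, for property-style
#' testing. The metabolic layer is a chain of metabolite pools with one or
#' two parallel conversion reactions per step, an import reaction and a
#' biomass sink; every reaction receives a GPR over fresh genes (single
#' gene, `and` pair, or `or` pair). Regulators are drawn as a random DAG:
#' each layer adds fresh upstream source genes wired onto current targets,
#' with inhibition signs drawn as Bernoulli(`inhibition`). An identical
#' specification yields a byte-identical serialised model. Specifications
#' whose random draw happens to abolish the biomass path are regenerated
#' deterministically with an incremented sub-seed (bounded retries).
#'
#' @param n_metabolites number of internal metabolite pools (default 3).
#' @param n_layers number of regulatory layers (0, 1 or 2).
#' @param inhibition probability that a regulatory edge is inhibitory.
#' @param regulators_per_target mean number of regulators wired onto each
#'   regulated gene (1 or 2 drawn per target).
#' @param p_regulated probability that a gene becomes regulated.
#' @param seed integer seed (required: fixtures are deterministic).
#' @return List with elements `model` and `layers`.
#' @export
random_imr_model <- function(n_metabolites = 3, n_layers = 1,
                             inhibition = 0.3, regulators_per_target = 1.5,
                             p_regulated = 0.6, seed) {
  stopifnot(n_metabolites >= 1, n_layers %in% 0:2,
            inhibition >= 0, inhibition <= 1)
  for (try in 0:24) {
    out <- with_seed(seed * 131L + try, {
      draw_imr_model(n_metabolites, n_layers, inhibition,
                     regulators_per_target, p_regulated,
                     id = paste0("random_imr_seed", seed))
    })
    if (max_biomass(out$model) > 1e-6) return(out)
  }
  stop("failed to draw a feasible model in 25 attempts", call. = FALSE)
}

draw_imr_model <- function(n_metabolites, n_layers, inhibition,
                           regulators_per_target, p_regulated, id) {
  mets <- paste0("M", seq_len(n_metabolites))
  gene_counter <- 0L
  fresh_genes <- function(n) {
    gene_counter <<- gene_counter + n
    paste0("g", seq_len(n) + gene_counter - n)
  }
  new_gpr <- function() {
    k <- sample(3L, 1L)           # 1: single, 2: and-pair, 3: or-pair
    gs <- fresh_genes(if (k == 1L) 1L else 2L)
    switch(k, gs, paste(gs, collapse = " and "), paste(gs, collapse = " or "))
  }
  rxns <- list(list(id = "rIN", stoich = stats::setNames(1, mets[1]),
                    gpr = new_gpr()))
  if (n_metabolites > 1) {
    for (i in seq_len(n_metabolites - 1L)) {
      for (p in seq_len(sample(2L, 1L))) {
        rxns[[length(rxns) + 1L]] <- list(
          id = paste0("r", i, letters[p]),
          stoich = stats::setNames(c(-1, 1), mets[c(i, i + 1L)]),
          gpr = new_gpr())
      }
    }
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = "rBIO", stoich = stats::setNames(-1, mets[n_metabolites]),
    gpr = new_gpr())

  rids <- vapply(rxns, `[[`, "", "id")
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rids))
  gpr <- list()
  for (k in seq_along(rxns)) {
    S[names(rxns[[k]]$stoich), k] <- rxns[[k]]$stoich
    gpr[[rids[k]]] <- rxns[[k]]$gpr
  }
  model <- metabolic_model(S, lower = 0, upper = 1000, biomass = "rBIO",
                           gpr = gpr, id = id)

  layers <- list()
  targets <- model$genes
  for (l in seq_len(n_layers)) {
    src_all <- character(); tgt_all <- character(); sgn_all <- numeric()
    next_targets <- character()
    for (tgt in targets) {
      if (stats::runif(1) > p_regulated) next
      nreg <- 1L + (stats::runif(1) < (regulators_per_target - 1))
      regs <- fresh_genes(nreg)
      src_all <- c(src_all, regs)
      tgt_all <- c(tgt_all, rep(tgt, nreg))
      sgn_all <- c(sgn_all, ifelse(stats::runif(nreg) < inhibition, -1, 1))
      next_targets <- c(next_targets, regs)
    }
    if (!length(src_all)) break
    layers[[l]] <- regulatory_layer(
      data.frame(source = src_all, target = tgt_all, sign = sgn_all),
      layer_index = l)
    targets <- next_targets
  }
  list(model = model, layers = layers)
}

#' Generate a random acyclic Boolean rule set
#'
#' Draws a seeded random `egpr_rules` instance for oracle-equivalence
#' testing of the cut-set engines. Genes are arranged in at most three
#' levels (GPR genes, their regulators, the regulators' regulators — i.e.
#' regulatory depth at most two): the target reaction rule combines one to
#' three level-0 genes with random `and`/`or`; each gene of a level is
#' regulated with probability `p_regulated` by one or two genes of the next
#' level, with negation drawn as Bernoulli(`inhibition`). Level structure
#' guarantees acyclicity; genes unreachable from the target are pruned so
#' `B(k)` is the connected rule support.
#'
#' @param n_genes number of genes to draw from (at least 1).
#' @param inhibition probability of a negated regulator.
#' @param p_regulated probability that a gene carries a rule.
#' @param seed integer seed.
#' @return An `egpr_rules` object.
#' @export
random_rule_set <- function(n_genes = 5, inhibition = 0.4,
                            p_regulated = 0.6, seed) {
  stopifnot(n_genes >= 1)
  with_seed(seed * 257L + 11L, {
    genes <- paste0("g", seq_len(n_genes))
    n0 <- min(n_genes, sample(3L, 1L))
    pool <- genes[seq_len(n_genes) > n0]
    level <- list(genes[seq_len(n0)])
    rules <- list()
    for (l in 1:2) {
      if (!length(pool)) break
      nxt <- character()
      for (tgt in level[[l]]) {
        if (!length(pool) || stats::runif(1) > p_regulated) next
        regs <- pool[seq_len(min(length(pool), sample(2L, 1L)))]
        pool <- setdiff(pool, regs)
        nxt <- c(nxt, regs)
        lits <- lapply(regs, function(g) {
          if (stats::runif(1) < inhibition) rule_not(rule_gene(g))
          else rule_gene(g)
        })
        rules[[tgt]] <- if (length(lits) == 1L) lits[[1L]]
          else if (stats::runif(1) < 0.5) nary("and", lits)
          else nary("or", lits)
      }
      if (!length(nxt)) break
      level[[l + 1L]] <- nxt
    }
    lits <- lapply(level[[1L]], rule_gene)
    gpr <- if (length(lits) == 1L) lits[[1L]]
      else if (stats::runif(1) < 0.5) nary("and", lits)
      else nary("or", lits)

    # restrict to genes reachable from the target rule
    reach <- rule_genes(gpr)
    repeat {
      more <- unique(unlist(lapply(reach, function(g)
        if (!is.null(rules[[g]])) rule_genes(rules[[g]]))))
      new <- setdiff(more, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    reach <- sort(reach)
    rules <- rules[names(rules) %in% reach]

    out <- structure(
      list(reaction = "rT", gpr = gpr, rules = if (length(rules)) rules[order(names(rules))] else rules,
           genes = reach, input_genes = sort(setdiff(reach, names(rules))),
           dropped_edges = data.frame(), depth = 2L, convention = "or"),
      class = "egpr_rules")
    check_rules_acyclic(out)
    out
  })
}

#' Generate a random expression matrix for an iMR model
#'
#' Draws log2(TPM+1)-scale values from a two-component mixture per
#' gene/sample cell: silent (near zero) with probability `p_silent`, else
#' expressed with log-normal-like magnitudes, so both HIGH and LOW states
#' occur under the default absolute threshold. Seeded and deterministic.
#'
#' @param model a `metabolic_model` (genes taken from the model), or a
#'   character vector of gene symbols.
#' @param n_samples number of samples (columns).
#' @param p_silent probability of a silent (near-zero) value.
#' @param seed integer seed.
#' @return Numeric matrix, genes x samples.
#' @export
random_expression <- function(model, n_samples = 4, p_silent = 0.35, seed) {
  genes <- if (is.character(model)) model else model$genes
  stopifnot(length(genes) >= 1, n_samples >= 1)
  with_seed(seed * 613L + 7L, {
    n <- length(genes) * n_samples
    silent <- stats::runif(n) < p_silent
    expressed <- log2(exp(stats::rnorm(n, mean = 1.2, sd = 0.8)) + 1)
    vals <- ifelse(silent, stats::runif(n, 0, 0.2), pmax(expressed, 0))
    matrix(vals, nrow = length(genes), ncol = n_samples,
           dimnames = list(genes, paste0("s", seq_len(n_samples))))
  })
}

#' Write an expression matrix as the TSV dialect used by the loaders
#'
#' Genes as rows (first column `gene`), samples as columns.
#'
#' @param mat genes x samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression (or dependency-score) TSV
#'
#' @param path TSV with genes as rows (first column) and samples as columns.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
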