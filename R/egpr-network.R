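#' Compile eGPR rules into an ON/OFF artificial reaction network
#'
#' Turns the Boolean rule set of one target reaction into the artificial
#' irreversible reaction network on which minimal cut sets are computed:
#'
#' 1. every gene rule `rho_i` is augmented with knock-out and knock-in
#'    machinery, `g_i = (rho_i and y_i) or u_i`, where `rho_i` is the free
#'    external input `e_i` for input genes;
#' 2. every entity is split into ON and OFF nodes, the OFF rule being the
#'    De Morgan negation of the ON rule (so no negation survives);
#' 3. each OR branch becomes one gate reaction producing the node, each AND
#'    a single multi-substrate gate; nested sub-expressions get
#'    content-addressed intermediate nodes so identical sub-rules share one
#'    node;
#' 4. input exchange reactions are added for all `e`/`y`/`u` ON and OFF
#'    nodes, and output exchanges for the target's ON and OFF nodes. The
#'    `y`/`u` input exchanges form the intervention set `H(k)`: removing the
#'    `y_iON` exchange knocks gene *i* out, removing `u_iOFF` knocks it in.
#'
#' @param rules an `egpr_rules` object (see [build_egpr_rules()]).
#' @return An `egpr_network`: `reaction`, `genes`, `input_genes`, `nodes`,
#'   `gates` (list of `inputs`/`output`), `exch_in` (nodes with input
#'   exchanges), `exch_out` (target ON/OFF nodes), `H` (named list: per gene
#'   the four intervention exchange nodes), `n_or_branches` (audit count).
#' @export
build_egpr_network <- function(rules) {
  stopifnot(inherits(rules, "egpr_rules"))
  if (rules$gpr$op == "true")
    stop("reaction '", rules$reaction,
         "' is spontaneous (empty GPR): it has no eGPR network and cannot ",
         "be blocked by gene interventions", call. = FALSE)

  genes <- rules$genes
  target <- paste0("rx@", rules$reaction)

  # --- step 1: augment gene rules with y/u (and e for input genes) ---------
  aug <- list()
  for (g in genes) {
    rho <- if (g %in% names(rules$rules)) rules$rules[[g]]
           else rule_gene(paste0("e@", g))
    aug[[g]] <- rule_or(rule_and(rho, rule_gene(paste0("y@", g))),
                        rule_gene(paste0("u@", g)))
  }
  aug[[target]] <- rules$gpr

  # --- step 2: ON/OFF split under De Morgan --------------------------------
  to_nodespace <- function(r) {
    # NNF rule over entities -> monotone rule over ON/OFF node literals
    switch(r$op,
      gene = rule_gene(paste0(r$gene, "_ON")),
      not  = {
        if (r$arg$op != "gene")
          stop("internal error: negation survived De Morgan push",
               call. = FALSE)
        rule_gene(paste0(r$arg$gene, "_OFF"))
      },
      and  = nary("and", lapply(r$args, to_nodespace)),
      or   = nary("or",  lapply(r$args, to_nodespace)),
      stop("internal error: TRUE inside a compiled rule", call. = FALSE)
    )
  }
  split_rules <- list()
  for (ent in names(aug)) {
    split_rules[[paste0(ent, "_ON")]]  <- to_nodespace(push_negations(aug[[ent]]))
    split_rules[[paste0(ent, "_OFF")]] <- to_nodespace(negate_rule(aug[[ent]]))
  }

  # --- step 3: compile to gate reactions with shared intermediates ---------
  gates <- list()
  aux_map <- character()      # canonical sub-rule text -> aux node name
  n_branches <- 0L

  leaf_or_aux <- function(r) {
    if (r$op == "gene") return(r$gene)
    key <- format_rule(r)
    if (!is.na(match(key, names(aux_map)))) return(aux_map[[key]])
    nm <- paste0("aux", length(aux_map) + 1L, "@", rules$reaction)
    aux_map[[key]] <<- nm
    compile_node(nm, r)
    nm
  }
  compile_node <- function(out, r) {
    branches <- if (r$op == "or") r$args else list(r)
    n_branches <<- n_branches + length(branches)
    for (b in branches) {
      ins <- if (b$op == "and") vapply(b$args, leaf_or_aux, "")
             else leaf_or_aux(b)
      gates[[length(gates) + 1L]] <<-
        list(inputs = unique(ins), output = out)
    }
  }
  for (nd in names(split_rules)) compile_node(nd, split_rules[[nd]])

  # --- step 4: exchanges ----------------------------------------------------
  exch_in <- character()
  H <- list()
  for (g in genes) {
    yu <- c(paste0("y@", g, "_ON"), paste0("y@", g, "_OFF"),
            paste0("u@", g, "_ON"), paste0("u@", g, "_OFF"))
    H[[g]] <- yu
    exch_in <- c(exch_in, yu)
    if (g %in% rules$input_genes)
      exch_in <- c(exch_in, paste0("e@", g, "_ON"), paste0("e@", g, "_OFF"))
  }
  exch_out <- c(paste0(target, "_ON"), paste0(target, "_OFF"))

  nodes <- unique(c(
    unlist(lapply(gates, function(g) c(g$inputs, g$output))),
    exch_in, exch_out))

  structure(
    list(reaction = rules$reaction, genes = genes,
         input_genes = rules$input_genes, target = target,
         nodes = nodes, gates = gates, exch_in = exch_in,
         exch_out = exch_out, H = H, n_or_branches = n_branches),
    class = "egpr_network")
}

#' @export
print.egpr_network <- function(x, ...) {
  cat("<eGPR network> reaction ", x$reaction, "\n", sep = "")
  cat("  ", length(x$nodes), " nodes, ", length(x$gates), " gate reactions, ",
      length(x$exch_in), " input / ", length(x$exch_out),
      " output exchanges\n", sep = "")
  cat("  genes B(k): ", paste(x$genes, collapse = ", "), "\n", sep = "")
  cat("  |H(k)| = ", 4L * length(x$genes), " intervention exchanges\n",
      sep = "")
  invisible(x)
}

#' Stoichiometric matrix of an eGPR network
#'
#' Rows are nodes, columns are reactions (gate reactions, then input
#' exchanges, then the two output exchanges); all coefficients are +-1.
#'
#' @param net an `egpr_network`.
#' @return A sparse `dgCMatrix` with dimnames.
#' @export
egpr_stoichiometry <- function(net) {
  stopifnot(inherits(net, "egpr_network"))
  gate_ids <- vapply(seq_along(net$gates), function(i)
    paste0(net$gates[[i]]$output, "~", i), "")
  ex_in_ids <- paste0("EXi_", net$exch_in)
  ex_out_ids <- paste0("EXo_", net$exch_out)
  cols <- c(gate_ids, ex_in_ids, ex_out_ids)
  ii <- integer(); jj <- integer(); xx <- numeric()
  ni <- stats::setNames(seq_along(net$nodes), net$nodes)
  for (i in seq_along(net$gates)) {
    g <- net$gates[[i]]
    ii <- c(ii, ni[g$inputs], ni[[g$output]])
    jj <- c(jj, rep(i, length(g$inputs) + 1L))
    xx <- c(xx, rep(-1, length(g$inputs)), 1)
  }
  off <- length(net$gates)
  ii <- c(ii, ni[net$exch_in])
  jj <- c(jj, off + seq_along(net$exch_in))
  xx <- c(xx, rep(1, length(net$exch_in)))
  off <- off + length(net$exch_in)
  ii <- c(ii, ni[net$exch_out])
  jj <- c(jj, off + seq_along(net$exch_out))
  xx <- c(xx, rep(-1, length(net$exch_out)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(net$nodes), length(cols)),
                       dimnames = list(net$nodes, cols))
}

#' Dump an eGPR network to a JSON file for inspection
#'
#' @param net an `egpr_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_egpr_network <- function(net, path) {
  jsonlite::write_json(
    list(reaction = net$reaction, genes = net$genes,
         input_genes = net$input_genes, nodes = net$nodes,
         gates = lapply(net$gates, function(g)
           list(inputs = g$inputs, output = g$output)),
         input_exchanges = net$exch_in, output_exchanges = net$exch_out,
         H = net$H),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- intervention atoms -----------------------------------------------------

#' Intervention-set atoms
#'
#' Intervention sets are plain character vectors of atoms in the `gene-`
#' (knock-out) / `gene+` (knock-in) notation. `parse_interventions()`
#' validates and canonicalises a set (sorted, unique, no gene carrying both
#' directions — a gene cannot be knocked out and knocked in at once).
#'
#' @param atoms character vector of atoms, e.g. `c("g3-", "g6+")`.
#' @param genes optional gene universe to validate against.
#' @return Canonicalised atom vector (sorted, unique).
#' @export
parse_interventions <- function(atoms, genes = NULL) {
  stopifnot(is.character(atoms))
  atoms <- unique(atoms)
  if (!length(atoms)) return(character())
  ok <- grepl("[+-]$", atoms)
  if (!all(ok))
    stop("malformed intervention atom(s): ",
         paste(atoms[!ok], collapse = ", "),
         " (expected 'gene-' or 'gene+')", call. = FALSE)
  g <- atom_gene(atoms)
  if (anyDuplicated(g))
    stop("a gene cannot be knocked out and knocked in at the same time: ",
         paste(unique(g[duplicated(g)]), collapse = ", "), call. = FALSE)
  if (!is.null(genes) && !all(g %in% genes))
    stop("intervention on gene(s) outside the network: ",
         paste(setdiff(g, genes), collapse = ", "), call. = FALSE)
  sort(atoms)
}

atom_gene <- function(atoms) sub("[+-]$", "", atoms)
atom_dir <- function(atoms) ifelse(grepl("\\+$", atoms), "KI", "KO")

#' Forward closure: the derivability oracle of an eGPR network
#'
#' Computes the least fixpoint of derivable nodes under an intervention set.
#' Base facts follow the exactly-one-exchange-per-pair regime: for every
#' gene, `y_OFF` is available iff the gene is knocked out (else `y_ON`),
#' `u_ON` iff knocked in (else `u_OFF`); the free inputs `e_ON`/`e_OFF` are
#' always available. A node is then derivable iff some gate producing it has
#' all substrates derivable. The network blocks its target under the
#' interventions iff the target ON node is not in the returned set.
#'
#' @param net an `egpr_network`.
#' @param interventions atom vector (see [parse_interventions()]).
#' @return Character vector of derivable nodes.
#' @export
forward_closure <- function(net, interventions = character()) {
  stopifnot(inherits(net, "egpr_network"))
  interventions <- parse_interventions(interventions, genes = net$genes)
  base <- closure_base_nodes(net, interventions)
  ni <- stats::setNames(seq_along(net$nodes), net$nodes)
  derivable <- logical(length(net$nodes))
  derivable[ni[base]] <- TRUE
  gi <- lapply(net$gates, function(g) list(ins = unname(ni[g$inputs]),
                                           out = ni[[g$output]]))
  repeat {
    changed <- FALSE
    for (g in gi) {
      if (!derivable[g$out] && all(derivable[g$ins])) {
        derivable[g$out] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  net$nodes[derivable]
}

closure_base_nodes <- function(net, interventions) {
  g <- atom_gene(interventions)
  d <- atom_dir(interventions)
  ko <- g[d == "KO"]; ki <- g[d == "KI"]
  base <- character()
  for (gn in net$genes) {
    base <- c(base,
      paste0("y@", gn, if (gn %in% ko) "_OFF" else "_ON"),
      paste0("u@", gn, if (gn %in% ki) "_ON" else "_OFF"))
    if (gn %in% net$input_genes)
      base <- c(base, paste0("e@", gn, "_ON"), paste0("e@", gn, "_OFF"))
  }
  base
}

#' Does an intervention set block the network's target?
#'
#' Convenience wrapper around [forward_closure()]: `TRUE` iff the target ON
#' node is not derivable under the interventions.
#'
#' @inheritParams forward_closure
#' @return Logical scalar.
#' @export
blocks_target <- function(net, interventions = character()) {
  !(paste0(net$target, "_ON") %in% forward_closure(net, interventions))
}
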