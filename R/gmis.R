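#' Classify an intervention set
#'
#' Taxonomy of lethal genetic interactions by composition: a single
#' knock-out is a (context-free) *essential gene*; two or more knock-outs
#' are *synthetic lethality* (SL); a single knock-in is a *tumor suppressor
#' gene* (TSG); one knock-out plus one knock-in is *synthetic dosage
#' lethality* (SDL); two or more knock-ins with no knock-out form a *tumor
#' suppressor gene complex* (TSGC); everything else is *mixed*.
#'
#' @param interventions atom vector (`gene-`/`gene+`).
#' @return One of `"essential-gene"`, `"SL"`, `"TSG"`, `"SDL"`, `"TSGC"`,
#'   `"mixed"`.
#' @export
classify_interventions <- function(interventions) {
  interventions <- parse_interventions(interventions)
  if (!length(interventions)) stop("empty intervention set", call. = FALSE)
  d <- atom_dir(interventions)
  nko <- sum(d == "KO"); nki <- sum(d == "KI")
  if (nko == 1 && nki == 0) return("essential-gene")
  if (nko >= 2 && nki == 0) return("SL")
  if (nko == 0 && nki == 1) return("TSG")
  if (nko == 1 && nki == 1) return("SDL")
  if (nko == 0 && nki >= 2) return("TSGC")
  "mixed"
}

#' Enumerate genome-level minimal intervention sets (gMIS)
#'
#' Finds every minimal intervention set `I` (within `max_length`) whose
#' induced reaction deletions — the reactions blocked through the G/F
#' matrices — abolish biomass production. Candidate atoms are restricted to
#' atoms occurring in `F`: an atom absent from every `F` row cannot change
#' the blocked reaction set, so the restriction loses no solution.
#' Candidates are visited in (size, lexicographic) order with superset
#' elimination, which yields exactly the subset-minimal lethal sets over the
#' full atom-subset lattice.
#'
#' Two interchangeable engines certify lethality:
#' * `"exhaustive"` — the primal reference engine: biomass maximum under the
#'   induced deletions computed by [max_biomass()] (simplex), lethal iff the
#'   maximum is at or below `tol`;
#' * `"dual"` — Farkas infeasibility certificate of the biomass flux system
#'   under the induced deletions, solved as a strictly convex QP.
#'
#' Certificates are memoised per distinct blocked-reaction set.
#'
#' @param model a `metabolic_model`.
#' @param gf a `gf_matrices` built from the same model.
#' @param max_length cap on intervention set size (default 5).
#' @param engine `"exhaustive"` (primal FBA) or `"dual"` (Farkas).
#' @param ko_only restrict atoms to knock-outs (pure gMCS run).
#' @param tol biomass blocking tolerance.
#' @param guard refuse instances with more candidates than this.
#' @return List of `gmis` records: each has `interventions`, `category` and
#'   `blocked` (reaction identifiers).
#' @export
enumerate_gmis <- function(model, gf, max_length = 5L,
                           engine = c("exhaustive", "dual"),
                           ko_only = FALSE, tol = 1e-6, guard = 2e5) {
  stopifnot(inherits(model, "metabolic_model"), inherits(gf, "gf_matrices"))
  engine <- match.arg(engine)
  atoms <- gf$atoms
  if (ko_only) atoms <- atoms[atom_dir(atoms) == "KO"]
  genes <- sort(unique(atom_gene(atoms)))
  atom_by_gene <- split(atoms, atom_gene(atoms))

  smax <- min(max_length, length(genes))
  total <- 0
  for (s in seq_len(max(smax, 0L))) {
    total <- total + choose(length(genes), s) * max(lengths(atom_by_gene))^s
  }
  if (total > guard)
    stop("candidate space too large for exhaustive enumeration (",
         format(total, big.mark = ","), " > ", guard, ")", call. = FALSE)

  lethal_memo <- new.env(parent = emptyenv())
  is_lethal <- function(blocked) {
    if (!length(blocked)) return(FALSE)
    key <- paste(blocked, collapse = ";")
    hit <- get0(key, envir = lethal_memo)
    if (!is.null(hit)) return(hit)
    val <- if (engine == "exhaustive") {
      max_biomass(model, deleted = blocked) <= tol
    } else {
      biomass_blocked_dual(model, deleted = blocked)
    }
    assign(key, val, envir = lethal_memo)
    val
  }

  # index-based candidate scan: rows and candidates as atom indices, subset
  # tests through a logical scratch mask
  row_idx <- lapply(gf$sets, function(a) {
    idx <- match(a, atoms)
    if (anyNA(idx)) NULL else idx      # rows touching excluded atoms
  })
  live_rows <- which(!vapply(row_idx, is.null, NA))
  mask <- logical(length(atoms))
  found <- list()
  found_idx <- list()
  blocked_list <- list()
  if (length(genes)) {
    for (s in seq_len(smax)) {
      combos <- utils::combn(genes, s, simplify = FALSE)
      for (cmb in combos) {
        alts <- atom_by_gene[cmb]
        grid <- expand.grid(alts, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
        grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
        for (r in seq_len(nrow(grid))) {
          cand <- sort(as.character(unlist(grid[r, ])))
          ci <- match(cand, atoms)
          mask[ci] <- TRUE
          dominated <- FALSE
          for (f in found_idx) if (all(mask[f])) { dominated <- TRUE; break }
          if (!dominated) {
            hit <- live_rows[vapply(live_rows, function(i)
              all(mask[row_idx[[i]]]), NA)]
            blocked <- sort(unique(unlist(gf$blocked[hit])))
            if (is_lethal(blocked)) {
              found[[length(found) + 1L]] <- cand
              found_idx[[length(found)]] <- ci
              blocked_list[[length(found)]] <- blocked
            }
          }
          mask[ci] <- FALSE
        }
      }
    }
  }
  ord <- order(lengths(found),
               vapply(found, classify_interventions, ""),
               vapply(found, paste, "", collapse = ","))
  out <- lapply(ord, function(i)
    list(interventions = found[[i]],
         category = classify_interventions(found[[i]]),
         blocked = blocked_list[[i]]))
  attr(out, "engine") <- engine
  attr(out, "ko_only") <- ko_only
  out
}

#' Compute the gMIS catalogue of an iMR model
#'
#' The top-level interface: integrates a metabolic model with signed
#' acyclic regulatory layers, compiles per-reaction extended GPR networks,
#' enumerates per-reaction minimal cut sets, integrates them into G/F
#' matrices, and enumerates the genome-level minimal intervention sets that
#' abolish biomass production, classified by composition. The returned
#' object supports `print()`, `summary()`, `as.data.frame()`, `plot()` and
#' `predict()` (context-specific essentiality and tumor-suppressor calls
#' from expression data).
#'
#' @param model a `metabolic_model` (or path readable by
#'   [read_metabolic_model()]).
#' @param layers list of `regulatory_layer` objects (or TSV paths).
#' @param depth regulatory depth merged into eGPR rules (0, 1 or 2).
#' @param convention regulator-combination convention (see
#'   [build_egpr_rules()]).
#' @param max_length cap on gMIS size (default 5).
#' @param row_cap G/F row cap in genes (default 5).
#' @param ko_only knock-outs only (a pure gMCS run).
#' @param mcs_engine per-reaction cut-set engine, `"dual"` or `"closure"`.
#' @param gmis_engine genome-level engine, `"dual"` or `"exhaustive"`.
#' @param params a [milp_params()] list.
#' @return A `gmis` object: `sets` (list of atom vectors), `category`,
#'   `blocked`, `gf`, `per_reaction_mcs`, `rules` (per-reaction eGPR rule
#'   sets), `rule_family` (gene-level regulatory rules used by the
#'   adaptation check), `model`, and the run metadata.
#' @examples
#' toy <- toy_imr_model()
#' fit <- gmis(toy$model, toy$layers)
#' fit
#' summary(fit)
#' @export
gmis <- function(model, layers = list(), depth = 1L,
                 convention = c("or", "and"), max_length = 5L,
                 row_cap = 5L, ko_only = FALSE,
                 mcs_engine = c("dual", "closure"),
                 gmis_engine = c("dual", "exhaustive"),
                 params = milp_params()) {
  if (is.character(model)) model <- read_metabolic_model(model)
  stopifnot(inherits(model, "metabolic_model"))
  convention <- match.arg(convention)
  mcs_engine <- match.arg(mcs_engine)
  gmis_engine <- match.arg(gmis_engine)
  if (inherits(layers, "regulatory_layer")) layers <- list(layers)
  layers <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    if (is.character(l)) read_regulatory_layer(l, layer_index = i) else l
  })

  rules <- list()
  mcs <- list()
  truncated <- FALSE
  for (rxn in model$reactions) {
    if (model$gpr[[rxn]]$op == "true") {
      mcs[[rxn]] <- list()      # spontaneous: unblockable
      next
    }
    er <- build_egpr_rules(rxn, model, layers, depth = depth,
                           convention = convention)
    rules[[rxn]] <- er
    net <- build_egpr_network(er)
    sol <- enumerate_mcs(net, params = params, engine = mcs_engine,
                         ko_only = ko_only)
    truncated <- truncated || isTRUE(attr(sol, "truncated"))
    mcs[[rxn]] <- sol
  }
  gf <- build_gf(mcs, max_row_size = row_cap)
  gl <- enumerate_gmis(model, gf, max_length = max_length,
                       engine = if (gmis_engine == "dual") "dual"
                                else "exhaustive",
                       ko_only = ko_only, tol = params$tol)
  structure(
    list(sets = lapply(gl, `[[`, "interventions"),
         category = vapply(gl, `[[`, "", "category"),
         blocked = lapply(gl, `[[`, "blocked"),
         gf = gf, per_reaction_mcs = mcs, rules = rules,
         rule_family = build_rule_family(model, layers, depth, convention),
         model = model,
         meta = list(depth = depth, convention = convention,
                     max_length = max_length, row_cap = row_cap,
                     ko_only = ko_only, mcs_engine = mcs_engine,
                     gmis_engine = gmis_engine, params = params,
                     truncated = truncated),
         call = match.call()),
    class = "gmis")
}

# gene-level regulatory rule family over the whole model (used by the
# adaptation check): same layer expansion as build_egpr_rules, seeded from
# every model gene at once
build_rule_family <- function(model, layers, depth, convention) {
  if (!length(layers) || depth < 1L) return(list())
  genes <- model$genes
  rules <- list()
  for (level in seq_len(depth)) {
    layer <- layers[[min(level, length(layers))]]
    frontier <- setdiff(genes, names(rules))
    for (tgt in frontier) {
      hit <- which(layer$target == tgt)
      if (!length(hit)) next
      acts <- layer$source[hit][layer$sign[hit] > 0]
      reps <- layer$source[hit][layer$sign[hit] < 0]
      # edges from genes that already depend on tgt would close a cycle;
      # the rule family mirrors the per-reaction dropping rule
      ok <- !vapply(c(acts, reps), function(s)
        family_reaches(rules, s, tgt), NA)
      keep <- c(acts, reps)[ok]
      acts <- intersect(acts, keep); reps <- intersect(reps, keep)
      if (!length(acts) && !length(reps)) next
      rules[[tgt]] <- combine_regulators(acts, reps, convention)
      genes <- union(genes, c(acts, reps))
    }
  }
  if (length(rules)) rules[order(names(rules))] else rules
}

family_reaches <- function(rules, from, to) {
  seen <- character()
  stack <- from
  while (length(stack)) {
    g <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (g == to) return(TRUE)
    if (g %in% seen) next
    seen <- c(seen, g)
    if (!is.null(rules[[g]])) stack <- c(stack, rule_genes(rules[[g]]))
  }
  FALSE
}

#' @export
print.gmis <- function(x, ...) {
  cat("Genetic minimal intervention sets (gMIS)\n")
  cat("  model: ", x$model$id, " (", length(x$model$reactions),
      " reactions, ", length(x$model$genes), " genes, depth ",
      x$meta$depth, ")\n", sep = "")
  nko <- sum(vapply(x$sets, function(s) all(atom_dir(s) == "KO"), NA))
  cat("  ", length(x$sets), " gMIS blocking biomass (", nko,
      " knock-out-only gMCS)\n", sep = "")
  for (i in seq_along(x$sets))
    cat(sprintf("  %2d. {%s}  [%s]\n", i,
                paste(x$sets[[i]], collapse = ", "), x$category[i]))
  invisible(x)
}

#' @export
summary.gmis <- function(object, ...) {
  df <- as.data.frame(object)
  out <- list(
    n = length(object$sets),
    n_gmcs = sum(vapply(object$sets,
                        function(s) all(atom_dir(s) == "KO"), NA)),
    by_category = table(object$category),
    by_length = table(lengths(object$sets)),
    truncated = object$meta$truncated,
    table = df)
  class(out) <- "summary.gmis"
  out
}

#' @export
print.summary.gmis <- function(x, ...) {
  cat("gMIS catalogue: ", x$n, " sets (", x$n_gmcs,
      " knock-out-only)\n", sep = "")
  cat("by category:\n")
  print(x$by_category)
  cat("by length:\n")
  print(x$by_length)
  if (x$truncated) cat("note: enumeration was truncated\n")
  invisible(x)
}

#' @export
as.data.frame.gmis <- function(x, ...) {
  data.frame(
    id = if (length(x$sets)) paste0("gmis", seq_along(x$sets)) else character(),
    length = lengths(x$sets),
    category = x$category,
    interventions = vapply(x$sets, paste, "", collapse = ";"),
    blocked_reactions = vapply(x$blocked, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
}

#' @export
plot.gmis <- function(x, ...) {
  tab <- table(factor(x$category,
                      levels = c("essential-gene", "SL", "TSG", "SDL",
                                 "TSGC", "mixed")))
  graphics::barplot(tab, ylab = "number of gMIS",
                    main = "gMIS catalogue by category", las = 2, ...)
  invisible(x)
}
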