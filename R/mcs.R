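#' Parameters of the dual cut-set program
#'
#' Collects the numerical constants and run limits of the dual
#' mixed-integer program used for minimal-cut-set enumeration: `alpha` and
#' `M` are the small/large positive constants linking the binary
#' intervention indicators `z` to their dual variables `v`
#' (`alpha * z <= v <= M * z`), `r_star` is the flux demanded through the
#' target reaction, and `c` the positive constant forcing the target dual
#' `w` away from zero. `max_size` caps solution length, matching the
#' downstream discard of intervention rows involving more than five genes.
#' `time_limit` is the per-solution time budget in seconds (the study
#' default is 5 minutes per solution).
#'
#' @param alpha small positive constant (default `1e-3`).
#' @param M large positive constant (default `1e3`).
#' @param r_star required target flux (default `1`).
#' @param c positive constant forcing a non-zero target dual (default `1e-3`).
#' @param max_size cap on solution length (default `5`).
#' @param max_solutions cap on the number of solutions (default `Inf`).
#' @param time_limit seconds allowed per solution (default `300`).
#' @param tol numeric blocking tolerance (default `1e-6`).
#' @param seed optional integer seed recorded with the run.
#' @return A `milp_params` list.
#' @export
milp_params <- function(alpha = 1e-3, M = 1e3, r_star = 1, c = 1e-3,
                        max_size = 5L, max_solutions = Inf,
                        time_limit = 300, tol = 1e-6, seed = NULL) {
  stopifnot(alpha > 0, M > alpha, r_star > 0, c > 0, max_size >= 1)
  structure(list(alpha = alpha, M = M, r_star = r_star, c = c,
                 max_size = as.integer(max_size),
                 max_solutions = max_solutions,
                 time_limit = time_limit, tol = tol, seed = seed),
            class = "milp_params")
}

# ---------------------------------------------------------------------------
# Dual feasibility certificate.
#
# For a fixed binary assignment z (one cut per y pair and per u pair,
# Eqs. 11-12-style), the remaining program is a linear feasibility system in
# the duals: find u free (one per node), v >= alpha (one per active
# intervention exchange, v <= M) and w >= c / r_star such that
#
#     S^T u + E_active v - t w >= 0        (one row per network reaction)
#
# where t marks the target ON output exchange. The system is feasible iff
# the primal flux problem (flux through the target with the cut exchanges
# closed) is infeasible, i.e. iff the interventions block the target
# (Farkas' lemma). Feasibility is certified by a strictly convex QP
# (min ||x||^2 subject to the constraints) solved with quadprog.
# ---------------------------------------------------------------------------

dual_certificate_env <- function(net, params) {
  S <- egpr_stoichiometry(net)
  tS <- as.matrix(Matrix::t(S))            # n x m
  cols <- colnames(S)
  tvec <- as.numeric(cols == paste0("EXo_", net$target, "_ON"))
  list(tS = tS, cols = cols, tvec = tvec, n = ncol(S), m = nrow(S),
       params = params)
}

# active H-exchange columns for an intervention set: per gene the kept-out
# exchange of the y pair (y_ON if knocked out, else y_OFF) and of the u pair
# (u_OFF if knocked in, else u_ON)
active_cut_columns <- function(net, interventions) {
  g <- atom_gene(interventions)
  d <- atom_dir(interventions)
  ko <- g[d == "KO"]; ki <- g[d == "KI"]
  unlist(lapply(net$genes, function(gn) c(
    paste0("EXi_y@", gn, if (gn %in% ko) "_ON" else "_OFF"),
    paste0("EXi_u@", gn, if (gn %in% ki) "_OFF" else "_ON"))))
}

dual_blocks <- function(net, env, interventions) {
  act <- match(active_cut_columns(net, interventions), env$cols)
  stopifnot(!anyNA(act))
  p <- env$params
  nact <- length(act)
  nvar <- env$m + nact + 1L
  # constraint rows: n network reactions
  E <- matrix(0, env$n, nact)
  E[cbind(act, seq_len(nact))] <- 1
  A <- cbind(env$tS, E, -p$r_star * env$tvec)
  b <- rep(0, env$n)
  # bounds: v >= alpha, v <= M, w >= c / r_star
  vb <- cbind(matrix(0, 2L * nact + 1L, env$m),
              rbind(diag(nact), -diag(nact), 0),
              c(rep(0, 2L * nact), 1))
  bb <- c(rep(p$alpha, nact), rep(-p$M, nact), p$c / p$r_star)
  ok <- tryCatch({
    quadprog::solve.QP(Dmat = diag(nvar), dvec = rep(0, nvar),
                       Amat = t(rbind(A, vb)), bvec = c(b, bb))
    TRUE
  }, error = function(e) {
    if (grepl("inconsistent", conditionMessage(e))) FALSE else stop(e)
  })
  ok
}

# ---------------------------------------------------------------------------
# candidate generation: valid intervention sets in (size, lexicographic)
# order under the no-two-directions-per-gene rule
# ---------------------------------------------------------------------------

iterate_candidates <- function(genes, max_size, ko_only, visit) {
  genes <- sort(genes)
  ng <- length(genes)
  dirs <- if (ko_only) "-" else c("-", "+")
  for (s in seq_len(min(max_size, ng))) {
    combos <- utils::combn(genes, s, simplify = FALSE)
    grid <- expand.grid(rep(list(dirs), s), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    # lexicographic over direction patterns, KO before KI
    grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
    for (cmb in combos) {
      for (r in seq_len(nrow(grid))) {
        atoms <- sort(paste0(cmb, as.character(grid[r, ])))
        if (!isTRUE(visit(atoms))) return(invisible(FALSE))
      }
    }
  }
  invisible(TRUE)
}

is_superset_of_any <- function(atoms, sets) {
  for (s in sets) if (all(s %in% atoms)) return(TRUE)
  FALSE
}

#' Enumerate minimal cut sets of one eGPR network
#'
#' Enumerates the minimal knock-out/knock-in intervention sets that block
#' the network's target reaction, in increasing size with lexicographic
#' tie-break.
#'
#' Two engines with identical contracts are provided:
#'
#' * `"dual"` — the production algorithm: exact implicit enumeration of the
#'   dual mixed-integer program. The binary intervention indicators are
#'   enumerated in objective order under the pairing and mutual-exclusion
#'   constraints (exactly one cut per `y` pair and per `u` pair; never
#'   knock-out and knock-in of the same gene; at least one intervention),
#'   previously found solutions are excluded through no-good cuts
#'   (superset elimination), and each assignment is certified by solving
#'   the remaining dual linear feasibility system (see [milp_params()]) with
#'   a strictly convex QP.
#' * `"closure"` — the independent brute-force oracle: the same candidate
#'   order, but blocking decided by the Boolean derivability fixpoint of
#'   [forward_closure()]. Guarded: refuses instances whose candidate count
#'   exceeds `guard`.
#'
#' Size-ordered enumeration with superset elimination returns exactly the
#' minimal blocking sets: any proper blocking subset of a candidate would
#' have been found (or dominated) at a smaller size, which excludes the
#' candidate.
#'
#' @param net an `egpr_network`.
#' @param params a [milp_params()] list.
#' @param engine `"dual"` or `"closure"`.
#' @param ko_only if `TRUE`, knock-ins are disabled (the knock-in binaries
#'   are pinned to "no intervention"), reproducing pure knock-out cut-set
#'   enumeration.
#' @param guard candidate-count guard for the closure engine.
#' @return List of intervention sets (sorted atom vectors), ordered by
#'   (size, lexicographic), with attributes `engine` and `truncated`.
#' @export
enumerate_mcs <- function(net, params = milp_params(),
                          engine = c("dual", "closure"),
                          ko_only = FALSE, guard = 1e6) {
  stopifnot(inherits(net, "egpr_network"))
  engine <- match.arg(engine)
  ng <- length(net$genes)
  smax <- min(params$max_size, ng)
  if (engine == "closure") {
    ndirs <- if (ko_only) 1 else 2
    total <- sum(vapply(seq_len(smax), function(s)
      choose(ng, s) * ndirs^s, 0))
    if (total > guard)
      stop("closure engine refused: ", format(total, big.mark = ","),
           " candidate intervention sets exceed the guard (", guard,
           "); use the dual engine", call. = FALSE)
  }
  env <- if (engine == "dual") dual_certificate_env(net, params)
  found <- list()
  truncated <- FALSE
  t_last <- proc.time()[["elapsed"]]
  visit <- function(atoms) {
    if (is_superset_of_any(atoms, found)) return(TRUE)
    blocked <- if (engine == "dual") dual_blocks(net, env, atoms)
               else blocks_target(net, atoms)
    if (blocked) {
      found[[length(found) + 1L]] <<- atoms
      t_last <<- proc.time()[["elapsed"]]
      if (length(found) >= params$max_solutions) {
        truncated <<- TRUE
        return(FALSE)
      }
    } else if (proc.time()[["elapsed"]] - t_last > params$time_limit) {
      truncated <<- TRUE
      return(FALSE)
    }
    TRUE
  }
  iterate_candidates(net$genes, smax, ko_only, visit)
  found <- found[order(lengths(found),
                       vapply(found, paste, "", collapse = ","))]
  attr(found, "engine") <- engine
  attr(found, "truncated") <- truncated
  found
}

#' Verify an intervention set against an eGPR network
#'
#' Definition check for a minimal cut set: `blocks` is `TRUE` iff the target
#' ON node is underivable under the interventions; `minimal` additionally
#' requires every proper subset one atom smaller to fail to block.
#'
#' @param net an `egpr_network`.
#' @param interventions atom vector (see [parse_interventions()]).
#' @return List with logical fields `blocks` and `minimal`.
#' @export
verify_interventions <- function(net, interventions) {
  interventions <- parse_interventions(interventions, genes = net$genes)
  if (!length(interventions))
    stop("empty intervention set", call. = FALSE)
  blocks <- blocks_target(net, interventions)
  minimal <- blocks
  if (blocks && length(interventions) > 1L) {
    for (i in seq_along(interventions)) {
      if (blocks_target(net, interventions[-i])) {
        minimal <- FALSE
        break
      }
    }
  }
  list(blocks = blocks, minimal = minimal)
}
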