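# ---------------------------------------------------------------------------
# Flux balance primitives.
#
# All linear systems here are solved through exact feasibility checks with
# quadprog (min ||x||^2 subject to the constraints: a strictly convex QP
# whose solver either returns a feasible point or certifies inconsistency).
# The biomass maximum is recovered by bisection on the demanded target flux,
# which is monotone in feasibility; this avoids fragile dense-simplex
# pivoting on the degenerate (all-zero right-hand side) mass-balance rows.
# ---------------------------------------------------------------------------

# feasibility of { S v = 0, lb <= v <= ub, v_bio >= target }
flux_feasible <- function(S, lb, ub, bio_idx, target = NULL) {
  n <- ncol(S)
  Aeq <- S
  A <- rbind(diag(n), -diag(n))
  b <- c(lb, -ub)
  if (!is.null(target)) {
    tv <- rep(0, n)
    tv[bio_idx] <- 1
    A <- rbind(A, tv)
    b <- c(b, target)
  }
  tryCatch({
    quadprog::solve.QP(Dmat = diag(n), dvec = rep(0, n),
                       Amat = t(rbind(Aeq, A)),
                       bvec = c(rep(0, nrow(Aeq)), b), meq = nrow(Aeq))
    TRUE
  }, error = function(e) {
    if (grepl("inconsistent", conditionMessage(e))) FALSE else stop(e)
  })
}

#' Maximum biomass flux under reaction deletions
#'
#' Flux balance analysis primitive: maximises flux through the biomass
#' reaction subject to steady-state mass balance `S v = 0` and flux bounds,
#' with the deleted reactions forced to zero. The maximum is located by
#' bisection on the demanded biomass flux with an exact feasibility check
#' per step, to absolute precision `precision`.
#'
#' @param model a `metabolic_model`.
#' @param deleted character vector of reactions forced to zero flux.
#' @param precision absolute bisection precision (default `1e-9`).
#' @return The maximal biomass flux (numeric scalar). A value at or below
#'   the blocking tolerance (`1e-6` by convention) means biomass production
#'   is abolished.
#' @export
max_biomass <- function(model, deleted = character(), precision = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  validate_metabolic_model(model)
  bad <- setdiff(deleted, model$reactions)
  if (length(bad))
    stop("cannot delete unknown reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lb <- model$lower
  ub <- model$upper
  lb[deleted] <- 0
  ub[deleted] <- 0
  if (any(lb > ub))
    stop("contradictory bounds after deletion", call. = FALSE)
  S <- as.matrix(model$stoichiometry)
  bio_idx <- match(model$biomass, model$reactions)

  if (!flux_feasible(S, lb, ub, bio_idx))
    stop("flux balance LP infeasible: the model's bounds admit no ",
         "steady state", call. = FALSE)

  hi <- ub[[model$biomass]]
  if (hi <= 0) return(min(hi, 0))
  # quick exits: blocked, or fully open
  if (!flux_feasible(S, lb, ub, bio_idx, target = precision)) return(0)
  if (flux_feasible(S, lb, ub, bio_idx, target = hi)) return(hi)
  lo <- precision
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (flux_feasible(S, lb, ub, bio_idx, target = mid)) lo <- mid
    else hi <- mid
  }
  lo
}

# ---------------------------------------------------------------------------
# Dual (Farkas) certificate that biomass production is abolished: the system
# {S v = 0, lb <= v <= ub, v_bio >= r_star} is infeasible iff there exist
# u free, p >= 0, q >= 0, w >= 0 with
#   S^T u + p - q - w e_bio = 0   and   ub' p - lb' q - r_star w <= -c .
# Certified by a strictly convex QP; used by the dual engine of
# enumerate_gmis() as a route independent of the primal search.
# ---------------------------------------------------------------------------
biomass_blocked_dual <- function(model, deleted = character(),
                                 r_star = 1e-4, c = 1e-7) {
  lb <- model$lower
  ub <- model$upper
  lb[deleted] <- 0
  ub[deleted] <- 0
  S <- as.matrix(model$stoichiometry)
  m <- nrow(S); n <- ncol(S)
  ebio <- as.numeric(model$reactions == model$biomass)
  nvar <- m + 2L * n + 1L
  # equality rows: S^T u + p - q - w e_bio = 0
  Aeq <- cbind(t(S), diag(n), -diag(n), -ebio)
  # inequality rows (>=): -ub'p + lb'q + r_star w >= c ; p,q,w >= 0
  Aineq <- rbind(c(rep(0, m), -ub, lb, r_star),
                 cbind(matrix(0, 2L * n + 1L, m), diag(2L * n + 1L)))
  bineq <- c(c, rep(0, 2L * n + 1L))
  tryCatch({
    quadprog::solve.QP(Dmat = diag(nvar), dvec = rep(0, nvar),
                       Amat = t(rbind(Aeq, Aineq)),
                       bvec = c(rep(0, n), bineq), meq = n)
    TRUE
  }, error = function(e) {
    if (grepl("inconsistent", conditionMessage(e))) FALSE else stop(e)
  })
}
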