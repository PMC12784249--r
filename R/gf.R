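#' Integrate per-reaction cut sets into paired G/F matrices
#'
#' Builds the paired sparse binary matrices at the heart of the approach:
#' each row of `F` is a minimal intervention set (columns are intervention
#' atoms, `gene-`/`gene+`), and the matching row of `G` marks the reactions
#' that the set blocks. Identical intervention sets arising from different
#' reactions merge into one row whose `G` entries mark all those reactions.
#' Rows involving more than `max_row_size` genes are discarded (the
#' contribution of longer sets to genetic vulnerabilities is negligible)
#' and counted in the discard report. Rows whose atom set contains another
#' row with at least the same blocked reactions are dominated and pruned
#' when `prune_dominated` is on; pruning provably never changes
#' [blocked_reactions()] on any input.
#'
#' @param mcs_by_reaction named list: reaction identifier to list of
#'   intervention sets (atom vectors).
#' @param max_row_size maximum number of genes per row (default 5).
#' @param prune_dominated drop dominated rows (default `TRUE`).
#' @return A `gf_matrices` object: sparse `F` (rows x atoms) and `G`
#'   (rows x reactions), `atoms`, `reactions`, `sets` (row atom lists),
#'   `blocked` (row reaction lists), and a `discarded` report.
#' @export
build_gf <- function(mcs_by_reaction, max_row_size = 5L,
                     prune_dominated = TRUE) {
  stopifnot(is.list(mcs_by_reaction), !is.null(names(mcs_by_reaction)))
  reactions <- names(mcs_by_reaction)
  rows <- list()      # key -> list(atoms, reactions)
  n_discarded <- 0L
  discarded_examples <- character()
  for (rxn in reactions) {
    for (set in mcs_by_reaction[[rxn]]) {
      atoms <- parse_interventions(set)
      if (!length(atoms))
        stop("empty intervention set supplied for reaction ", rxn,
             call. = FALSE)
      if (length(atoms) > max_row_size) {
        n_discarded <- n_discarded + 1L
        if (length(discarded_examples) < 5L)
          discarded_examples <- c(discarded_examples,
                                  paste(atoms, collapse = ";"))
        next
      }
      key <- paste(atoms, collapse = ";")
      if (is.null(rows[[key]])) {
        rows[[key]] <- list(atoms = atoms, reactions = rxn)
      } else {
        rows[[key]]$reactions <- union(rows[[key]]$reactions, rxn)
      }
    }
  }
  # deterministic row order: size, then lexicographic key
  keys <- names(rows)
  ord <- order(lengths(lapply(rows, `[[`, "atoms")), keys)
  rows <- rows[ord]

  if (prune_dominated && length(rows) > 1L) {
    dominated <- logical(length(rows))
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i == j || dominated[j]) next
        if (all(rows[[j]]$atoms %in% rows[[i]]$atoms) &&
            length(rows[[j]]$atoms) < length(rows[[i]]$atoms) &&
            all(rows[[i]]$reactions %in% rows[[j]]$reactions)) {
          dominated[i] <- TRUE
          break
        }
      }
    }
    rows <- rows[!dominated]
  }

  atoms <- sort(unique(unlist(lapply(rows, `[[`, "atoms"))))
  nr <- length(rows)
  Fi <- integer(); Fj <- integer(); Gi <- integer(); Gj <- integer()
  for (i in seq_along(rows)) {
    Fi <- c(Fi, rep(i, length(rows[[i]]$atoms)))
    Fj <- c(Fj, match(rows[[i]]$atoms, atoms))
    Gi <- c(Gi, rep(i, length(rows[[i]]$reactions)))
    Gj <- c(Gj, match(rows[[i]]$reactions, reactions))
  }
  rn <- if (nr) paste0("mis", seq_len(nr)) else character()
  structure(
    list(F = Matrix::sparseMatrix(i = Fi, j = Fj, x = 1,
                                  dims = c(nr, length(atoms)),
                                  dimnames = list(rn, atoms)),
         G = Matrix::sparseMatrix(i = Gi, j = Gj, x = 1,
                                  dims = c(nr, length(reactions)),
                                  dimnames = list(rn, reactions)),
         atoms = atoms, reactions = reactions,
         sets = lapply(rows, `[[`, "atoms"),
         blocked = lapply(rows, `[[`, "reactions"),
         discarded = list(n = n_discarded, examples = discarded_examples,
                          max_row_size = as.integer(max_row_size))),
    class = "gf_matrices")
}

#' @export
print.gf_matrices <- function(x, ...) {
  cat("<G/F matrices> ", nrow(x$F), " intervention rows, ",
      length(x$atoms), " atoms, ", length(x$reactions), " reactions\n",
      sep = "")
  if (x$discarded$n)
    cat("  discarded ", x$discarded$n, " row(s) larger than ",
        x$discarded$max_row_size, " genes\n", sep = "")
  invisible(x)
}

#' Reactions blocked by an intervention set
#'
#' The union of `G` rows over all `F` rows whose atom set is contained in
#' the interventions. Monotone: a superset of interventions blocks a
#' superset of reactions. Unknown atoms simply never match.
#'
#' @param gf a `gf_matrices` object.
#' @param interventions atom vector.
#' @return Character vector of blocked reaction identifiers.
#' @export
blocked_reactions <- function(gf, interventions) {
  stopifnot(inherits(gf, "gf_matrices"))
  interventions <- parse_interventions(interventions)
  hit <- vapply(gf$sets, function(a) all(a %in% interventions), NA)
  out <- unlist(gf$blocked[hit])
  if (is.null(out)) character() else sort(unique(out))
}

#' Write / read G and F matrices
#'
#' Persists the pair as Matrix Market files (`F.mtx`, `G.mtx`) plus TSV
#' index files for the atom and reaction columns and the row identifiers.
#' `read_gf()` restores an equivalent `gf_matrices` object; the round trip
#' is exact.
#'
#' @param gf a `gf_matrices` object.
#' @param dir directory for the files (created if missing).
#' @return `dir` (write) or a `gf_matrices` (read).
#' @export
write_gf <- function(gf, dir) {
  stopifnot(inherits(gf, "gf_matrices"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(gf$F, file.path(dir, "F.mtx"))
  Matrix::writeMM(gf$G, file.path(dir, "G.mtx"))
  utils::write.table(data.frame(atom = gf$atoms),
                     file.path(dir, "atoms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(reaction = gf$reactions),
                     file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_gf
#' @export
read_gf <- function(dir) {
  # writeMM stores all-ones matrices in pattern (and possibly symmetric)
  # form; normalise back to numeric general CSC
  norm <- function(m) methods::as(methods::as(methods::as(
    m, "generalMatrix"), "dMatrix"), "CsparseMatrix")
  Fm <- norm(Matrix::readMM(file.path(dir, "F.mtx")))
  Gm <- norm(Matrix::readMM(file.path(dir, "G.mtx")))
  atoms <- utils::read.delim(file.path(dir, "atoms.tsv"),
                             stringsAsFactors = FALSE)$atom
  reactions <- utils::read.delim(file.path(dir, "reactions.tsv"),
                                 stringsAsFactors = FALSE)$reaction
  atoms <- as.character(atoms)
  reactions <- as.character(reactions)
  nr <- nrow(Fm)
  rn <- if (nr) paste0("mis", seq_len(nr)) else character()
  dimnames(Fm) <- list(rn, atoms)
  dimnames(Gm) <- list(rn, reactions)
  sets <- lapply(seq_len(nr), function(i) sort(atoms[Fm[i, ] != 0]))
  blocked <- lapply(seq_len(nr), function(i) reactions[Gm[i, ] != 0])
  structure(list(F = Fm, G = Gm, atoms = atoms, reactions = reactions,
                 sets = sets, blocked = blocked,
                 discarded = list(n = NA_integer_, examples = character(),
                                  max_row_size = NA_integer_)),
            class = "gf_matrices")
}
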