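#' Binarise expression values into HIGH/LOW states
#'
#' Maps numeric expression values (log2(TPM+1) convention) to the
#' two-state HIGH/LOW representation used by the context-specific
#' prediction rules. The default rule is an absolute cutoff: HIGH iff
#' `value >= threshold` (default 1, i.e. TPM >= 1). The rule is pluggable:
#' `threshold` may instead be a function mapping the numeric vector to a
#' logical HIGH indicator, so distribution-based thresholds can be swapped
#' in. Genes absent from `values` but queried later resolve through the
#' `missing` policy (default LOW, conservative for essentiality calls).
#'
#' @param values named numeric vector of expression values for one sample.
#' @param threshold numeric cutoff, or a function of the value vector
#'   returning a logical vector.
#' @param missing state assigned to unmeasured genes, `"LOW"` or `"HIGH"`.
#' @param sample sample identifier carried in the result.
#' @return An `expression_state`: named character vector of `"HIGH"`/
#'   `"LOW"`, with `sample`, `method` and `missing` attributes.
#' @export
binarize_expression <- function(values, threshold = 1, missing = c("LOW", "HIGH"),
                                sample = "sample") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  missing <- match.arg(missing)
  if (any(values < 0, na.rm = TRUE))
    stop("negative expression values: inputs must be on the log2(TPM+1) ",
         "scale", call. = FALSE)
  if (is.function(threshold)) {
    high <- threshold(values)
    method <- "custom"
  } else {
    high <- values >= threshold
    method <- paste0("absolute>=", threshold)
  }
  high[is.na(high)] <- missing == "HIGH"
  st <- ifelse(high, "HIGH", "LOW")
  names(st) <- names(values)
  structure(st, sample = sample, method = method, missing = missing,
            class = "expression_state")
}

state_of <- function(state, gene) {
  v <- unclass(state)[gene]
  miss <- attr(state, "missing")
  if (is.null(miss)) miss <- "LOW"
  v[is.na(v)] <- miss
  unname(v)
}

#' Predict context-specific essential genes from a gMIS catalogue
#'
#' A knocked-out gene of a gMIS is called *potentially essential* in a
#' sample iff it is the unique highly expressed gene among the gMIS's
#' knock-outs and every gene to be knocked in within that gMIS is highly
#' expressed. Blocking the set then only requires losing the one highly
#' expressed knock-out gene: all other required interventions are already
#' mimicked by the expression context.
#'
#' @param sets list of intervention sets (atom vectors), e.g. the `sets`
#'   field of a [gmis()] fit.
#' @param state an `expression_state` (see [binarize_expression()]).
#' @return Data frame with columns `sample`, `gene`, `role`, `gmis`
#'   (supporting sets, `;`-joined atoms, `|`-separated).
#' @export
predict_essential_genes <- function(sets, state) {
  records <- list()
  for (set in sets) {
    ko <- set[atom_dir(set) == "KO"]
    ki <- set[atom_dir(set) == "KI"]
    if (!length(ko)) next
    ko_g <- atom_gene(ko); ki_g <- atom_gene(ki)
    if (length(ki_g) && !all(state_of(state, ki_g) == "HIGH")) next
    high_ko <- ko_g[state_of(state, ko_g) == "HIGH"]
    if (length(high_ko) != 1L) next
    records[[length(records) + 1L]] <-
      data.frame(gene = high_ko, gmis = paste(set, collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  collapse_records(records, "essential", attr(state, "sample"))
}

#' Predict context-specific tumor suppressors from a gMIS catalogue
#'
#' Mirror image of [predict_essential_genes()]: a knocked-in gene of a gMIS
#' is called a *possible tumor suppressor* in a sample iff it is the unique
#' lowly expressed gene among the gMIS's knock-ins and every gene to be
#' knocked out within that gMIS is lowly expressed.
#'
#' @inheritParams predict_essential_genes
#' @return Data frame with columns `sample`, `gene`, `role`, `gmis`.
#' @export
predict_tumor_suppressors <- function(sets, state) {
  records <- list()
  for (set in sets) {
    ko <- set[atom_dir(set) == "KO"]
    ki <- set[atom_dir(set) == "KI"]
    if (!length(ki)) next
    ko_g <- atom_gene(ko); ki_g <- atom_gene(ki)
    if (length(ko_g) && !all(state_of(state, ko_g) == "LOW")) next
    low_ki <- ki_g[state_of(state, ki_g) == "LOW"]
    if (length(low_ki) != 1L) next
    records[[length(records) + 1L]] <-
      data.frame(gene = low_ki, gmis = paste(set, collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  collapse_records(records, "tumor-suppressor", attr(state, "sample"))
}

collapse_records <- function(records, role, sample) {
  if (!length(records))
    return(data.frame(sample = character(), gene = character(),
                      role = character(), gmis = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, records)
  agg <- stats::aggregate(gmis ~ gene, df,
                          FUN = function(x) paste(x, collapse = "|"))
  data.frame(sample = sample, gene = agg$gene, role = role,
             gmis = agg$gmis, stringsAsFactors = FALSE)
}

#' Check for regulatory adaptation mechanisms
#'
#' Before trusting a context-specific call, the remaining genes of the
#' supporting gMIS must keep their required states once the intervention is
#' applied: a knocked-out partner gene must not become active, and a
#' knocked-in partner must not become inactive, through the regulatory
#' rules. Unregulated genes are fixed at their observed state, the
#' intervention overrides its gene, and the acyclic Boolean rules are
#' propagated in topological order (exact on acyclic rule sets; cyclic rule
#' families are rejected).
#'
#' @param rule_family named list of Boolean rules (gene to rule), e.g. the
#'   `rule_family` field of a [gmis()] fit.
#' @param state an `expression_state`.
#' @param intervention single atom applied (e.g. `"EZH2-"`).
#' @param partners remaining atoms of the gMIS under scrutiny.
#' @return `"passed"` or `"failed"`.
#' @export
adaptation_check <- function(rule_family, state, intervention, partners) {
  stopifnot(length(intervention) == 1L)
  genes <- unique(c(names(rule_family),
                    unlist(lapply(rule_family, rule_genes)),
                    atom_gene(c(intervention, partners)),
                    names(unclass(state))))
  order <- rule_topo_order(rule_family, genes)
  base <- stats::setNames(state_of(state, genes) == "HIGH", genes)
  propagate <- function(values) {
    for (g in order) {
      if (!is.null(rule_family[[g]]))
        values[[g]] <- eval_rule(rule_family[[g]], values)
      if (g == atom_gene(intervention))
        values[[g]] <- atom_dir(intervention) == "KI"
    }
    values
  }
  after <- propagate(base)
  after[[atom_gene(intervention)]] <- atom_dir(intervention) == "KI"
  after <- propagate(after)   # idempotent on acyclic rules; re-run settles
  for (p in partners) {
    pg <- atom_gene(p)
    if (atom_dir(p) == "KO" && isTRUE(after[[pg]])) return("failed")
    if (atom_dir(p) == "KI" && !isTRUE(after[[pg]])) return("failed")
  }
  "passed"
}

#' Dependency-score essentiality flag
#'
#' A gene counts as essential in a knock-out screen when its dependency
#' score falls below the conventional cutoff of -0.6. Missing scores are
#' returned as `NA` and should be excluded from downstream metrics.
#'
#' @param score numeric dependency score(s); `NA` allowed.
#' @param cutoff essentiality cutoff (default `-0.6`).
#' @return Logical vector (`NA` where the score is missing).
#' @export
depmap_essential <- function(score, cutoff = -0.6) {
  ifelse(is.na(score), NA, score < cutoff)
}

#' Context-specific predictions from a gMIS catalogue
#'
#' Maps an expression matrix onto the catalogue: per sample, expression is
#' binarised, essential-gene and tumor-suppressor calls are made, and each
#' call is screened for regulatory adaptation mechanisms via
#' [adaptation_check()] on the fit's rule family.
#'
#' @param object a `gmis` fit.
#' @param newdata numeric matrix (genes x samples) of log2(TPM+1) values,
#'   or a named numeric vector for a single sample.
#' @param threshold expression cutoff or function
#'   (see [binarize_expression()]).
#' @param missing state for unmeasured genes.
#' @param adaptation run the adaptation check (default `TRUE`).
#' @param ... unused.
#' @return Data frame with columns `sample`, `gene`, `role`, `gmis`,
#'   `adaptation` (`"passed"`/`"failed"`/`"skipped"`).
#' @export
predict.gmis <- function(object, newdata, threshold = 1,
                         missing = c("LOW", "HIGH"), adaptation = TRUE,
                         ...) {
  missing <- match.arg(missing)
  if (is.vector(newdata) && !is.null(names(newdata)))
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample"))
  stopifnot(is.matrix(newdata) || is.data.frame(newdata))
  newdata <- as.matrix(newdata)
  out <- list()
  for (smp in colnames(newdata)) {
    state <- binarize_expression(stats::setNames(newdata[, smp],
                                                 rownames(newdata)),
                                 threshold = threshold, missing = missing,
                                 sample = smp)
    df <- rbind(predict_essential_genes(object$sets, state),
                predict_tumor_suppressors(object$sets, state))
    if (!nrow(df)) next
    df$adaptation <- "skipped"
    if (adaptation) {
      for (i in seq_len(nrow(df))) {
        dir <- if (df$role[i] == "essential") "-" else "+"
        atom <- paste0(df$gene[i], dir)
        supports <- strsplit(df$gmis[i], "|", fixed = TRUE)[[1L]]
        verdicts <- vapply(supports, function(sup) {
          partners <- setdiff(strsplit(sup, ";", fixed = TRUE)[[1L]], atom)
          adaptation_check(object$rule_family, state, atom, partners)
        }, "")
        df$adaptation[i] <- if (any(verdicts == "passed")) "passed"
                            else "failed"
      }
    }
    out[[smp]] <- df
  }
  if (!length(out))
    return(data.frame(sample = character(), gene = character(),
                      role = character(), gmis = character(),
                      adaptation = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
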