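#' Construct a metabolic model
#'
#' The container for the metabolic layer of an iMR model: a stoichiometric
#' matrix `S` (metabolites x reactions), per-reaction flux bounds, a
#' designated biomass reaction, and one Boolean gene-protein-reaction (GPR)
#' rule per reaction (the `true` rule marks a spontaneous reaction).
#'
#' @param stoichiometry metabolites x reactions matrix (dense or sparse),
#'   with metabolite and reaction identifiers as dimnames.
#' @param lower,upper numeric flux bounds, one per reaction (recycled if
#'   scalar).
#' @param biomass identifier of the biomass reaction.
#' @param gpr named list of `boolean_rule` (or GPR strings), one entry per
#'   reaction; missing entries default to the `true` rule.
#' @param id optional model identifier.
#' @return A `metabolic_model` object with fields `metabolites`, `reactions`,
#'   `stoichiometry` (a `dgCMatrix`), `lower`, `upper`, `biomass`, `gpr`,
#'   `genes` and `id`.
#' @examples
#' S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("r_in", "r_out")))
#' metabolic_model(S, 0, 10, biomass = "r_out", gpr = list(r_out = "g1"))
#' @export
metabolic_model <- function(stoichiometry, lower, upper, biomass,
                            gpr = list(), id = "model") {
  S <- Matrix::Matrix(as(stoichiometry, "CsparseMatrix"), sparse = TRUE)
  mets <- rownames(S)
  rxns <- colnames(S)
  if (is.null(mets) || is.null(rxns))
    stop("stoichiometry must carry metabolite and reaction dimnames",
         call. = FALSE)
  mets <- trimws(mets); rxns <- trimws(rxns)
  dimnames(S) <- list(mets, rxns)
  if (anyDuplicated(mets)) stop("duplicated metabolite identifiers", call. = FALSE)
  if (anyDuplicated(rxns)) stop("duplicated reaction identifiers", call. = FALSE)
  lower <- rep_len(as.numeric(lower), length(rxns))
  upper <- rep_len(as.numeric(upper), length(rxns))
  names(lower) <- names(upper) <- rxns
  biomass <- trimws(biomass)
  if (!biomass %in% rxns)
    stop("biomass reaction '", biomass, "' is not a model reaction",
         call. = FALSE)
  rules <- stats::setNames(rep(list(rule_true()), length(rxns)), rxns)
  for (r in names(gpr)) {
    rn <- trimws(r)
    if (!rn %in% rxns)
      stop("GPR given for unknown reaction '", r, "'", call. = FALSE)
    rules[[rn]] <- if (is_boolean_rule(gpr[[r]])) gpr[[r]] else parse_gpr(gpr[[r]])
  }
  genes <- sort(unique(unlist(lapply(rules, rule_genes))))
  out <- structure(
    list(metabolites = mets, reactions = rxns, stoichiometry = S,
         lower = lower, upper = upper, biomass = biomass, gpr = rules,
         genes = genes, id = id),
    class = "metabolic_model")
  validate_metabolic_model(out)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: stoichiometry dimensions match the
#' metabolite/reaction lists, the biomass reaction is a model reaction,
#' bounds are ordered, and every GPR gene is in the model gene list.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly usable in pipelines; errors on violation.
#' @export
validate_metabolic_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- model$stoichiometry
  if (!identical(rownames(S), model$metabolites) ||
      !identical(colnames(S), model$reactions))
    stop("stoichiometry dimnames disagree with metabolite/reaction lists",
         call. = FALSE)
  if (!model$biomass %in% model$reactions)
    stop("biomass reaction missing from reaction list", call. = FALSE)
  if (any(model$lower > model$upper))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(model$reactions[model$lower > model$upper], collapse = ", "),
         call. = FALSE)
  gg <- unlist(lapply(model$gpr, rule_genes))
  if (!all(gg %in% model$genes))
    stop("GPR references genes outside the model gene list", call. = FALSE)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic model> ", x$id, "\n", sep = "")
  cat("  ", length(x$metabolites), " metabolites, ", length(x$reactions),
      " reactions, ", length(x$genes), " genes\n", sep = "")
  cat("  biomass reaction: ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' Read a metabolic model from JSON or SBML
#'
#' Dispatches on file extension: `.json` uses the package's JSON dialect
#' (see Details), anything else is parsed as SBML Level 3 with the `fbc`
#' extension (GPRs taken from `fbc:geneProductAssociation`, bounds resolved
#' through `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters, biomass
#' from the active `fbc` objective).
#'
#' @details The JSON dialect is
#' `{"id": ..., "metabolites": [...], "biomass": ...,`
#' `"reactions": [{"id", "lb", "ub", "stoich": {met: coef}, "gpr"}]}`.
#'
#' @param path path to a model file.
#' @return A `metabolic_model`.
#' @export
read_metabolic_model <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_model_json(path)
  } else {
    read_model_sbml(path)
  }
}

read_model_json <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- vapply(j$metabolites, as.character, "")
  rxns <- vapply(j$reactions, function(r) as.character(r$id), "")
  S <- Matrix::Matrix(0, length(mets), length(rxns),
                      dimnames = list(mets, rxns), sparse = TRUE)
  lb <- ub <- numeric(length(rxns))
  gpr <- list()
  for (k in seq_along(j$reactions)) {
    r <- j$reactions[[k]]
    for (m in names(r$stoich)) S[m, k] <- as.numeric(r$stoich[[m]])
    lb[k] <- as.numeric(r$lb)
    ub[k] <- as.numeric(r$ub)
    gpr[[rxns[k]]] <- if (is.null(r$gpr)) "" else as.character(r$gpr)
  }
  metabolic_model(S, lb, ub, biomass = as.character(j$biomass), gpr = gpr,
                  id = if (is.null(j$id)) "model" else as.character(j$id))
}

#' Write a metabolic model to the JSON dialect
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path) {
  S <- model$stoichiometry
  rx <- lapply(model$reactions, function(r) {
    col <- S[, r]
    nz <- which(col != 0)
    list(id = r, lb = model$lower[[r]], ub = model$upper[[r]],
         stoich = as.list(stats::setNames(as.numeric(col[nz]),
                                          model$metabolites[nz])),
         gpr = format_rule(model$gpr[[r]]))
  })
  jsonlite::write_json(
    list(id = model$id, metabolites = model$metabolites,
         biomass = model$biomass, reactions = rx),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- minimal SBML L3 + fbc reader -------------------------------------------

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  # fbc-prefixed element names survive xml_ns_strip, so all element lookups
  # go through local-name(); attribute prefixes are stripped
  xml2::xml_ns_strip(doc)
  ln <- function(...) paste0(vapply(c(...), function(n)
    sprintf("/*[local-name()='%s']", n), ""), collapse = "")
  xall <- function(node, ...) xml2::xml_find_all(node, paste0(".", ln(...)))
  xone <- function(node, ...) xml2::xml_find_first(node, paste0(".", ln(...)))

  species <- xall(doc, "model", "listOfSpecies", "species")
  mets <- xml2::xml_attr(species, "id")

  # fbc gene products: map internal id -> label (gene symbol)
  gps <- xall(doc, "model", "listOfGeneProducts", "geneProduct")
  gp_id <- xml2::xml_attr(gps, "id")
  gp_label <- xml2::xml_attr(gps, "label")
  gp_label[is.na(gp_label)] <- gp_id[is.na(gp_label)]
  gpmap <- stats::setNames(gp_label, gp_id)

  params <- xall(doc, "model", "listOfParameters", "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rnodes <- xall(doc, "model", "listOfReactions", "reaction")
  rxns <- xml2::xml_attr(rnodes, "id")
  S <- Matrix::Matrix(0, length(mets), length(rxns),
                      dimnames = list(mets, rxns), sparse = TRUE)
  lb <- ub <- numeric(length(rxns))
  gpr <- list()
  for (k in seq_along(rnodes)) {
    rn <- rnodes[[k]]
    for (sr in xall(rn, "listOfReactants", "speciesReference")) {
      st <- xml2::xml_attr(sr, "stoichiometry")
      S[xml2::xml_attr(sr, "species"), k] <-
        S[xml2::xml_attr(sr, "species"), k] -
        (if (is.na(st)) 1 else as.numeric(st))
    }
    for (sr in xall(rn, "listOfProducts", "speciesReference")) {
      st <- xml2::xml_attr(sr, "stoichiometry")
      S[xml2::xml_attr(sr, "species"), k] <-
        S[xml2::xml_attr(sr, "species"), k] +
        (if (is.na(st)) 1 else as.numeric(st))
    }
    lbid <- xml2::xml_attr(rn, "lowerFluxBound")
    ubid <- xml2::xml_attr(rn, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb[k] <- if (!is.na(lbid) && lbid %in% names(pvals)) pvals[[lbid]]
             else if (rev) -1000 else 0
    ub[k] <- if (!is.na(ubid) && ubid %in% names(pvals)) pvals[[ubid]] else 1000
    gpa <- xone(rn, "geneProductAssociation")
    gpr[[rxns[k]]] <- if (inherits(gpa, "xml_missing")) rule_true()
                      else sbml_association(xml2::xml_children(gpa)[[1L]], gpmap)
  }

  bio <- xml2::xml_attr(
    xone(doc, "model", "listOfObjectives", "objective",
         "listOfFluxObjectives", "fluxObjective"),
    "reaction")
  if (is.na(bio)) {
    hit <- grep("biomass", rxns, ignore.case = TRUE, value = TRUE)
    if (length(hit) != 1L)
      stop("cannot identify the biomass reaction in ", path, call. = FALSE)
    bio <- hit
  }

  metabolic_model(S, lb, ub, biomass = bio, gpr = gpr,
                  id = xml2::xml_attr(xone(doc, "model"), "id"))
}

sbml_association <- function(node, gpmap) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- if (ref %in% names(gpmap)) gpmap[[ref]] else ref
    return(rule_gene(lab))
  }
  kids <- lapply(xml2::xml_children(node), sbml_association, gpmap = gpmap)
  if (nm == "and") return(nary("and", kids))
  if (nm == "or")  return(nary("or", kids))
  stop("unsupported geneProductAssociation node <", nm, ">", call. = FALSE)
}
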