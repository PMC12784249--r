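#' Boolean rules over genes
#'
#' Rules are represented as a small expression DAG built from five node kinds:
#' `and`, `or`, `not`, `gene` (a literal) and `true` (the empty rule of a
#' spontaneous reaction). `and`/`or` take arbitrary fan-in, `not` exactly one
#' child. Constructors normalise as they build: nested `and(and(...))` and
#' `or(or(...))` are flattened, duplicate operands are collapsed
#' (idempotence), and single-operand `and`/`or` nodes dissolve into their
#' operand.
#'
#' @param ... operand rules (for `rule_and`/`rule_or`).
#' @param x a rule (for `rule_not`), or object to test/format.
#' @param gene a gene symbol (character scalar).
#' @return A `boolean_rule` object.
#' @examples
#' rule_and(rule_gene("g1"), rule_gene("g2"))
#' rule_or(rule_gene("g1"), rule_not(rule_gene("g2")))
#' @name boolean_rule
NULL

new_rule <- function(op, ...) {
  structure(list(op = op, ...), class = "boolean_rule")
}

#' @rdname boolean_rule
#' @export
rule_gene <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  new_rule("gene", gene = gene)
}

#' @rdname boolean_rule
#' @export
rule_true <- function() new_rule("true")

#' @rdname boolean_rule
#' @export
rule_not <- function(x) {
  stopifnot(inherits(x, "boolean_rule"))
  if (x$op == "not") return(x$arg)
  new_rule("not", arg = x)
}

nary <- function(op, args) {
  args <- lapply(args, function(a) {
    stopifnot(inherits(a, "boolean_rule"))
    a
  })
  # flatten same-op children
  flat <- list()
  for (a in args) {
    if (a$op == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  # collapse duplicates (idempotence), stable order
  keys <- vapply(flat, format_rule, "")
  flat <- flat[!duplicated(keys)]
  if (length(flat) == 1L) return(flat[[1L]])
  new_rule(op, args = flat)
}

#' @rdname boolean_rule
#' @export
rule_and <- function(...) nary("and", list(...))

#' @rdname boolean_rule
#' @export
rule_or <- function(...) nary("or", list(...))

#' @rdname boolean_rule
#' @export
is_boolean_rule <- function(x) inherits(x, "boolean_rule")

#' Serialise a rule to its canonical text form
#'
#' The serialisation uses `and`/`or`/`not` keywords with parentheses around
#' nested sub-expressions, and round-trips through [parse_gpr()] to an
#' isomorphic DAG.
#'
#' @param x a `boolean_rule`.
#' @return A character scalar.
#' @export
format_rule <- function(x) {
  stopifnot(is_boolean_rule(x))
  # parenthesise only where precedence demands: or under and, and any
  # compound under not ("and" binds tighter than "or")
  wrap <- function(r, parent_op) {
    s <- format_rule(r)
    if (r$op %in% c("and", "or") &&
        (parent_op == "not" || (parent_op == "and" && r$op == "or"))) {
      s <- paste0("(", s, ")")
    }
    s
  }
  switch(x$op,
    gene = x$gene,
    true = "",
    not  = paste0("not ", wrap(x$arg, "not")),
    and  = paste(vapply(x$args, wrap, "", parent_op = "and"), collapse = " and "),
    or   = paste(vapply(x$args, wrap, "", parent_op = "or"), collapse = " or ")
  )
}

#' @export
print.boolean_rule <- function(x, ...) {
  s <- format_rule(x)
  cat("<boolean rule> ", if (nzchar(s)) s else "TRUE", "\n", sep = "")
  invisible(x)
}

#' Gene symbols referenced by a rule
#'
#' @param x a `boolean_rule`.
#' @return Sorted character vector of gene symbols (empty for a `true` rule).
#' @export
rule_genes <- function(x) {
  stopifnot(is_boolean_rule(x))
  acc <- switch(x$op,
    gene = x$gene,
    true = character(),
    not  = rule_genes(x$arg),
    unlist(lapply(x$args, rule_genes))
  )
  sort(unique(acc))
}

#' Evaluate a rule against gene truth values
#'
#' @param x a `boolean_rule`.
#' @param values named logical vector; every gene of the rule must be named.
#' @return Logical scalar.
#' @export
eval_rule <- function(x, values) {
  stopifnot(is_boolean_rule(x))
  switch(x$op,
    true = TRUE,
    gene = {
      if (is.na(match(x$gene, names(values))))
        stop("no value for gene '", x$gene, "'", call. = FALSE)
      as.logical(values[[x$gene]])
    },
    not = !eval_rule(x$arg, values),
    and = all(vapply(x$args, eval_rule, NA, values = values)),
    or  = any(vapply(x$args, eval_rule, NA, values = values))
  )
}

# Push negation through a rule by De Morgan's laws, yielding a rule in which
# `not` appears only directly above gene literals.
negate_rule <- function(x) {
  stopifnot(is_boolean_rule(x))
  switch(x$op,
    true = stop("cannot negate the TRUE rule", call. = FALSE),
    gene = new_rule("not", arg = x),
    not  = push_negations(x$arg),
    and  = nary("or",  lapply(x$args, negate_rule)),
    or   = nary("and", lapply(x$args, negate_rule))
  )
}

push_negations <- function(x) {
  switch(x$op,
    true = x,
    gene = x,
    not  = negate_rule(x$arg),
    and  = nary("and", lapply(x$args, push_negations)),
    or   = nary("or",  lapply(x$args, push_negations))
  )
}

#' Parse a gene-protein-reaction rule string
#'
#' Accepts the usual SBML-style textual GPR dialect: gene symbols combined
#' with `and` / `or` (case-insensitive; `&`/`&&` and `|`/`||` are accepted as
#' synonyms) plus parentheses, with `and` binding tighter than `or`. `not`
#' (or `!`) is accepted so that regulatory rules can use the same grammar.
#' An empty or all-whitespace string denotes a spontaneous reaction and
#' parses to the `true` rule.
#'
#' @param text GPR rule string.
#' @return A `boolean_rule`.
#' @examples
#' parse_gpr("g1 and g2")
#' parse_gpr("(g1 or g2) and g3")
#' parse_gpr("")
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(rule_true())

  # tokenise, tracking character positions for error messages
  pat <- "\\(|\\)|&&|\\|\\||&|\\||!|[^\\s()&|!]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  toks <- regmatches(text, list(m))[[1L]]
  pos <- as.integer(m)
  bad <- grepl("^[^A-Za-z0-9_.:()&|!-]", toks)
  if (any(bad)) {
    stop("unknown token '", toks[which(bad)[1L]], "' at position ",
         pos[which(bad)[1L]], call. = FALSE)
  }
  kind <- tolower(toks)
  kind[kind %in% c("&", "&&")] <- "and"
  kind[kind %in% c("|", "||")] <- "or"
  kind[kind == "!"] <- "not"

  i <- 0L
  n <- length(toks)
  peek <- function() if (i < n) kind[i + 1L] else ""
  advance <- function() {
    i <<- i + 1L
    toks[i]
  }
  err <- function(msg, at = if (i < n) pos[i + 1L] else nchar(text) + 1L) {
    stop(msg, " at position ", at, call. = FALSE)
  }

  parse_or <- function() {
    lhs <- parse_and()
    args <- list(lhs)
    while (peek() == "or") {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) lhs else nary("or", args)
  }
  parse_and <- function() {
    lhs <- parse_unary()
    args <- list(lhs)
    while (peek() == "and") {
      advance()
      args <- c(args, list(parse_unary()))
    }
    if (length(args) == 1L) lhs else nary("and", args)
  }
  parse_unary <- function() {
    k <- peek()
    if (k == "not") {
      advance()
      return(rule_not(parse_unary()))
    }
    if (k == "(") {
      at <- pos[i + 1L]
      advance()
      inner <- parse_or()
      if (peek() != ")") err("unbalanced parentheses: '(' opened", at)
      advance()
      return(inner)
    }
    if (k %in% c("", ")", "and", "or")) err("expected a gene symbol")
    rule_gene(trimws(advance()))
  }

  out <- parse_or()
  if (i < n) err("unexpected token")
  out
}
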