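#' Construct a signed regulatory layer
#'
#' A regulatory layer is a signed directed edge list (source gene, target
#' gene, sign) with +1 for activation and -1 for inhibition. Duplicate edges
#' are collapsed; a pair of edges between the same genes with conflicting
#' signs is kept (the target is then both activated and repressed by the
#' source) with a warning. Self-loops are rejected: layers must stay acyclic
#' when merged into Boolean rules.
#'
#' @param edges data frame with columns `source`, `target`, `sign`.
#'   Signs accept `+1`/`-1`, `"+"`/`"-"`, `"1"`/`"-1"`, `"activation"`/
#'   `"inhibition"` (case-insensitive).
#' @param layer_index positive integer identifying the layer.
#' @return A `regulatory_layer`: data frame of deduplicated edges with
#'   numeric `sign`, plus a `layer_index` attribute.
#' @export
regulatory_layer <- function(edges, layer_index = 1L) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "sign") %in% names(edges)))
  src <- trimws(as.character(edges$source))
  tgt <- trimws(as.character(edges$target))
  sgn <- parse_sign(edges$sign)
  if (any(src == tgt)) {
    stop("self-loop edge(s) not allowed: ",
         paste(unique(src[src == tgt]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(source = src, target = tgt, sign = sgn,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  key <- paste(df$source, df$target)
  if (anyDuplicated(key)) {
    conf <- unique(key[duplicated(key)])
    warning("conflicting duplicate signed edge(s) kept: ",
            paste(conf, collapse = "; "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, layer_index = as.integer(layer_index),
            class = c("regulatory_layer", "data.frame"))
}

parse_sign <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(s))
  out[s %in% c("+1", "+", "1", "activation", "activates")] <- 1
  out[s %in% c("-1", "-", "inhibition", "inhibits", "repression")] <- -1
  if (anyNA(out)) {
    stop("sign value(s) outside {+1, -1}: ",
         paste(unique(s[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a regulatory layer from a TSV edge list
#'
#' Expects a headered TSV with columns `source`, `target`, `sign`.
#'
#' @param path path to the TSV file.
#' @param layer_index positive integer identifying the layer.
#' @return A `regulatory_layer`.
#' @export
read_regulatory_layer <- function(path, layer_index = 1L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("regulatory layer TSV needs columns source/target/sign", call. = FALSE)
  names(df)[1:3] <- c("source", "target", "sign")
  regulatory_layer(df[1:3], layer_index = layer_index)
}

#' Write a regulatory layer to TSV
#'
#' @param layer a `regulatory_layer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regulatory_layer <- function(layer, path) {
  utils::write.table(as.data.frame(layer), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
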