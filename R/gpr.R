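#' Gene-protein-reaction (GPR) boolean expressions
#'
#' A GPR rule states which gene products enable a reaction: `and` joins
#' subunits of a complex (all required), `or` joins isozymes (any
#' suffices). Rules are stored as abstract syntax trees: a leaf is a gene
#' id (character scalar), an internal node is `list(op = "and"|"or",
#' args = list(...))`. The empty rule (`""` or `NULL`) means the reaction
#' has no gene association (an orphan reaction).
#'
#' @param text GPR rule as a string, e.g. `"(gA and gB) or gC"`.
#'   Keywords `and`/`or` are case-insensitive; gene ids are any other
#'   non-whitespace, non-parenthesis tokens.
#' @return `parse_gpr()` returns a GPR tree, or `NULL` for an empty rule.
#' @examples
#' tree <- parse_gpr("(gA and gB) or gC")
#' eval_gpr(tree, active = c("gC"))
#' gpr_genes(tree)
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(NULL)
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error: unexpected token '", st$toks[st$pos],
         "' in rule: ", text, call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: unexpected end of rule", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop("GPR parse error: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tk, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tk
}

#' @rdname parse_gpr
#' @param tree a GPR tree from [parse_gpr()].
#' @param active character vector of active gene ids, or a named logical
#'   vector mapping gene id to activity. Genes not listed are inactive
#'   in the character form and active by default in the logical form
#'   only if `default` says so.
#' @param default activity assumed for genes absent from a named-logical
#'   `active` map (default `TRUE`, matching knockout usage where only the
#'   deleted genes are listed `FALSE`).
#' @return `eval_gpr()` returns `TRUE`/`FALSE`; an empty (`NULL`) rule
#'   evaluates `TRUE` (orphan reactions are always enabled).
#' @export
eval_gpr <- function(tree, active, default = TRUE) {
  if (is.null(tree)) return(TRUE)
  if (is.logical(active)) {
    lookup <- function(g) {
      if (g %in% names(active)) unname(active[[g]]) else default
    }
  } else {
    lookup <- function(g) g %in% active
  }
  rec <- function(node) {
    if (is.character(node)) return(lookup(node))
    vals <- vapply(node$args, rec, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  rec(tree)
}

#' @rdname parse_gpr
#' @return `gpr_genes()` returns the sorted unique gene ids in the rule.
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  rec <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, rec), use.names = FALSE)
  }
  sort(unique(rec(tree)))
}

#' @rdname parse_gpr
#' @return `deparse_gpr()` returns the canonical string form of a tree
#'   (lower-case keywords, fully parenthesized sub-expressions), `""`
#'   for the empty rule.
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(node, parent_op = NULL) {
    if (is.character(node)) return(node)
    parts <- vapply(node$args, rec, character(1), parent_op = node$op)
    body <- paste(parts, collapse = paste0(" ", node$op, " "))
    if (!is.null(parent_op) && !identical(parent_op, node$op)) {
      body <- paste0("(", body, ")")
    }
    body
  }
  rec(tree)
}
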