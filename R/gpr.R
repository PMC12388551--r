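#' Gene-protein-reaction (GPR) rule logic
#'
#' A GPR rule is a boolean expression over gene identifiers, with `and`
#' encoding enzyme complexes (every subunit required) and `or` encoding
#' isozymes (any one suffices). Rules are parsed into an expression tree and
#' evaluated either over tri-state expression levels (-1 low, 0 moderate,
#' 1 high; `and` = min, `or` = max) or as plain booleans for in-silico gene
#' knockouts.
#'
#' @name gpr
NULL

#' Parse a GPR rule string
#'
#' Grammar: identifiers combined with case-insensitive `and` / `or` (also
#' `&` / `|`) and parentheses; `and` binds tighter than `or`. Empty or
#' whitespace-only text yields the empty rule.
#'
#' @param text GPR rule string as stored in SBML FBC gene-association text.
#' @return a `gpr_expr`: list with `kind` in `"gene"`, `"and"`, `"or"`,
#'   `"empty"`; gene nodes carry `gene`, composite nodes `children` (>= 2).
#' @export
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text)))
    return(structure(list(kind = "empty"), class = "gpr_expr"))
  toks <- gpr_tokenize(text)
  st <- list(toks = toks, pos = 1L)
  res <- gpr_parse_or(st)
  if (res$st$pos <= length(toks))
    stop(sprintf("GPR parse error near '%s' in rule: %s",
                 toks[res$st$pos], text))
  structure(res$node, class = "gpr_expr")
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  text <- gsub("&&|&", " and ", text)
  text <- gsub("\\|\\||\\|", " or ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  first <- gpr_parse_and(st)
  st <- first$st
  children <- list(first$node)
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_and(st)
    st <- nxt$st
    children <- c(children, list(nxt$node))
  }
  node <- if (length(children) == 1) children[[1]] else
    gpr_flatten(list(kind = "or", children = children))
  list(node = node, st = st)
}

gpr_parse_and <- function(st) {
  first <- gpr_parse_atom(st)
  st <- first$st
  children <- list(first$node)
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_atom(st)
    st <- nxt$st
    children <- c(children, list(nxt$node))
  }
  node <- if (length(children) == 1) children[[1]] else
    gpr_flatten(list(kind = "and", children = children))
  list(node = node, st = st)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: dangling operator at end of rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    st <- inner$st
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("GPR parse error: unbalanced parentheses")
    st$pos <- st$pos + 1L
    return(list(node = inner$node, st = st))
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop(sprintf("GPR parse error: unexpected token '%s'", tk))
  st$pos <- st$pos + 1L
  list(node = list(kind = "gene", gene = tk), st = st)
}

# merge nested same-operator children so and/or nodes have a flat child list
gpr_flatten <- function(node) {
  kids <- list()
  for (ch in node$children) {
    if (identical(ch$kind, node$kind)) kids <- c(kids, ch$children)
    else kids <- c(kids, list(ch))
  }
  list(kind = node$kind, children = kids)
}

#' Render a GPR expression back to rule text
#' @param expr a `gpr_expr`.
#' @return canonical rule string (`""` for the empty rule).
#' @export
deparse_gpr <- function(expr) {
  switch(expr$kind,
    empty = "",
    gene = expr$gene,
    and = paste(vapply(expr$children, function(ch) {
      s <- deparse_gpr(ch)
      if (ch$kind == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    or = paste(vapply(expr$children, deparse_gpr, character(1)),
               collapse = " or "))
}

#' Genes referenced by a GPR expression
#' @param expr a `gpr_expr`.
#' @return character vector of unique gene ids.
#' @export
gpr_genes <- function(expr) {
  switch(expr$kind,
    empty = character(0),
    gene = expr$gene,
    unique(unlist(lapply(expr$children, gpr_genes))))
}

#' Evaluate a GPR under tri-state expression levels
#'
#' `and` nodes take the minimum of their children (a complex is only as
#' expressed as its scarcest subunit), `or` nodes the maximum (any isozyme
#' carries the reaction). Genes absent from `levels` and the empty rule
#' evaluate to 0 (moderate): absence of evidence must not force a reaction
#' off.
#'
#' @param expr a `gpr_expr`.
#' @param levels named integer vector, gene -> level in `{-1, 0, 1}`.
#' @return integer level in `{-1, 0, 1}`.
#' @export
evaluate_tristate <- function(expr, levels) {
  switch(expr$kind,
    empty = 0L,
    gene = {
      v <- unname(levels[expr$gene])
      if (length(v) == 0 || is.na(v)) 0L else as.integer(v)
    },
    and = min(vapply(expr$children, evaluate_tristate, integer(1), levels = levels)),
    or = max(vapply(expr$children, evaluate_tristate, integer(1), levels = levels)))
}

#' Evaluate a GPR as a boolean over a set of present genes
#'
#' Used for in-silico knockouts: a reaction remains catalysable iff its rule
#' is satisfiable by the surviving genes. The empty rule is `TRUE`
#' (spontaneous / unannotated reactions are never knocked out).
#'
#' @param expr a `gpr_expr`.
#' @param present character vector of gene ids considered present.
#' @return logical scalar.
#' @export
evaluate_boolean <- function(expr, present) {
  switch(expr$kind,
    empty = TRUE,
    gene = expr$gene %in% present,
    and = all(vapply(expr$children, evaluate_boolean, logical(1), present = present)),
    or = any(vapply(expr$children, evaluate_boolean, logical(1), present = present)))
}

#' Apply a gene knockout to a model
#'
#' Reactions whose GPR can no longer be satisfied by the surviving genes get
#' both bounds set to zero; all other reactions are untouched. Unknown gene
#' ids are ignored with a warning.
#'
#' @param model a `metabolic_model`.
#' @param deleted character vector of gene ids to remove.
#' @return the modified `metabolic_model`.
#' @export
apply_knockout <- function(model, deleted) {
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown) > 0)
    warning("ignoring unknown gene id(s): ", paste(unknown, collapse = ", "))
  surviving <- setdiff(model$genes, deleted)
  for (i in seq_len(nrow(model$reactions))) {
    expr <- parse_gpr(model$reactions$gpr[i])
    if (expr$kind == "empty") next
    if (!evaluate_boolean(expr, surviving)) {
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- 0
    }
  }
  model
}
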