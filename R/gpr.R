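#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers that states which
#' gene products a reaction needs in order to carry flux. Internally a rule is
#' a tree of nodes: a leaf `list(kind = "gene", gene = <id>)` or an operator
#' `list(kind = "and"|"or", children = <list of nodes>)`. `NULL` represents
#' the empty rule: a reaction with no gene association, which can never be
#' inactivated by a gene knockout.
#'
#' @name gpr
NULL

.gpr_token_rx <- "[A-Za-z0-9_.:-]+|\\(|\\)|&&|\\|\\|"

.gpr_tokenize <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(ws) == 1L) {
      pos <- pos + nchar(ws)
      next
    }
    m <- regmatches(rest, regexpr(paste0("^(", .gpr_token_rx, ")"), rest))
    if (length(m) == 0L) {
      stop(sprintf("GPR parse error at position %d: unexpected character '%s'",
                   pos, substr(text, pos, pos)), call. = FALSE)
    }
    low <- tolower(m)
    type <- if (m == "(") "lparen"
      else if (m == ")") "rparen"
      else if (low == "and" || m == "&&") "and"
      else if (low == "or" || m == "||") "or"
      else "ident"
    if (type == "ident" && grepl("^[0-9.]+$", m)) {
      stop(sprintf(
        "GPR parse error at position %d: numeric token '%s' (stoichiometric gene coefficients are not supported)",
        pos, m), call. = FALSE)
    }
    tokens[[length(tokens) + 1L]] <- list(type = type, text = m, pos = pos)
    pos <- pos + nchar(m)
  }
  tokens
}

# recursive-descent grammar:
#   expr   := term ( OR term )*
#   term   := factor ( AND factor )*
#   factor := IDENT | '(' expr ')'
.gpr_parse_state <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}

.gpr_peek <- function(st) {
  if (st$i > length(st$tokens)) NULL else st$tokens[[st$i]]
}

.gpr_take <- function(st) {
  tok <- .gpr_peek(st)
  st$i <- st$i + 1L
  tok
}

.gpr_fail <- function(tok, what) {
  pos <- if (is.null(tok)) "end of rule" else sprintf("position %d", tok$pos)
  got <- if (is.null(tok)) "end of input" else sprintf("'%s'", tok$text)
  stop(sprintf("GPR parse error at %s: expected %s, got %s", pos, what, got),
       call. = FALSE)
}

.gpr_parse_expr <- function(st) {
  children <- list(.gpr_parse_term(st))
  while (!is.null(tok <- .gpr_peek(st)) && tok$type == "or") {
    .gpr_take(st)
    children[[length(children) + 1L]] <- .gpr_parse_term(st)
  }
  .gpr_node("or", children)
}

.gpr_parse_term <- function(st) {
  children <- list(.gpr_parse_factor(st))
  while (!is.null(tok <- .gpr_peek(st)) && tok$type == "and") {
    .gpr_take(st)
    children[[length(children) + 1L]] <- .gpr_parse_factor(st)
  }
  .gpr_node("and", children)
}

.gpr_parse_factor <- function(st) {
  tok <- .gpr_take(st)
  if (is.null(tok)) .gpr_fail(tok, "a gene identifier or '('")
  if (tok$type == "ident") {
    return(list(kind = "gene", gene = tok$text))
  }
  if (tok$type == "lparen") {
    inner <- .gpr_parse_expr(st)
    close <- .gpr_take(st)
    if (is.null(close) || close$type != "rparen") .gpr_fail(close, "')'")
    return(inner)
  }
  .gpr_fail(tok, "a gene identifier or '('")
}

# build an operator node, flattening same-kind children and collapsing
# single-child nodes so internal nodes always have >= 2 children
.gpr_node <- function(kind, children) {
  if (length(children) == 1L) return(children[[1L]])
  flat <- list()
  for (ch in children) {
    if (!is.null(ch$kind) && ch$kind == kind) {
      flat <- c(flat, ch$children)
    } else {
      flat <- c(flat, list(ch))
    }
  }
  list(kind = kind, children = flat)
}

#' Parse a GPR rule string
#'
#' Accepts gene identifiers, parentheses and the operators `and`/`or` (any
#' case) with `&&`/`||` synonyms. Associative chains are flattened and
#' single-child nodes collapsed, so operator nodes always have at least two
#' children. Empty or all-whitespace input yields the empty rule (`NULL`).
#'
#' @param text GPR rule string, e.g. `"(g1 and g2) or g3"`.
#' @return A GPR tree (see [gpr]) or `NULL` for the empty rule.
#' @examples
#' parse_gpr("g1 or g2")
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(NULL)
  st <- .gpr_parse_state(.gpr_tokenize(text))
  tree <- .gpr_parse_expr(st)
  left <- .gpr_peek(st)
  if (!is.null(left)) .gpr_fail(left, "end of rule")
  tree
}

#' Render a GPR tree back to rule text
#'
#' Inverse of [parse_gpr()] on normalized trees: `parse_gpr(render_gpr(x))`
#' reproduces `x`.
#'
#' @param expr GPR tree or `NULL`.
#' @return A single string; `""` for the empty rule.
#' @export
render_gpr <- function(expr) {
  if (is.null(expr)) return("")
  if (expr$kind == "gene") return(expr$gene)
  parts <- vapply(expr$children, function(ch) {
    s <- render_gpr(ch)
    if (!is.null(ch$kind) && ch$kind %in% c("and", "or")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$kind, " "))
}

#' Evaluate a GPR rule under a set of inactivated genes
#'
#' A gene leaf is `FALSE` iff its gene is in `inactive_genes`; `and`/`or`
#' follow boolean semantics; the empty rule is always `TRUE` (a reaction with
#' no gene association survives any knockout).
#'
#' @param expr GPR tree or `NULL`.
#' @param inactive_genes Character vector of knocked-out gene ids.
#' @return Logical scalar.
#' @examples
#' evaluate_gpr(parse_gpr("g1 or g2"), "g1")   # TRUE, g2 is a live isozyme
#' evaluate_gpr(parse_gpr("g1 and g2"), "g1")  # FALSE
#' @export
evaluate_gpr <- function(expr, inactive_genes = character()) {
  if (is.null(expr)) return(TRUE)
  if (expr$kind == "gene") return(!(expr$gene %in% inactive_genes))
  vals <- vapply(expr$children, evaluate_gpr, logical(1),
                 inactive_genes = inactive_genes)
  if (expr$kind == "and") all(vals) else any(vals)
}

#' List the genes appearing in a GPR rule
#'
#' @param expr GPR tree or `NULL`.
#' @return Character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character())
  if (expr$kind == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gpr_genes)))
}
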