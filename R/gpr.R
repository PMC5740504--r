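# Gene-protein-reaction (GPR) rules.
#
# A GPR is a Boolean expression over gene identifiers, e.g.
# "(g1 and g2) or g3": AND across subunits of a complex, OR across
# isozymes. The package parses rules into nested list trees once at model
# load and evaluates them in two algebras:
#   * Boolean  (knockout semantics: a knocked-out gene is FALSE),
#   * min/max  (expression propagation: min over AND, max over OR).

#' Parse a GPR rule string into an AND/OR tree
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := gene | '(' expr ')'`. Keywords are case-insensitive.
#'
#' @param rule character scalar; `""` or `NA` yield `NULL` (no rule).
#' @return `NULL`, a gene id (character scalar), or
#'   `list(op = "and"|"or", args = list(...))`.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) ||
      !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_expr(st, rule)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule: unexpected token '", st$toks[st$pos],
         "' in \"", rule, "\"", call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA

gpr_parse_expr <- function(st, rule) {
  args <- list(gpr_parse_term(st, rule))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_term(st, rule)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_term <- function(st, rule) {
  args <- list(gpr_parse_factor(st, rule))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_factor(st, rule)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_factor <- function(st, rule) {
  tok <- gpr_peek(st)
  if (is.na(tok)) {
    stop("malformed GPR rule: unexpected end of expression in \"",
         rule, "\"", call. = FALSE)
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_expr(st, rule)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("malformed GPR rule: missing ')' in \"", rule, "\"",
           call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok %in% c(")", "and", "or", "AND", "OR", "And", "Or")) {
    stop("malformed GPR rule: unexpected '", tok, "' in \"", rule, "\"",
         call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tok
}

#' Genes mentioned by a parsed GPR tree
#' @noRd
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Boolean evaluation under a knockout set (absent gene = FALSE)
#' @noRd
gpr_eval_bool <- function(tree, knocked_out) {
  if (is.null(tree)) return(TRUE)  # no rule: reaction unaffected
  if (is.character(tree)) return(!(tree %in% knocked_out))
  vals <- vapply(tree$args, gpr_eval_bool, logical(1),
                 knocked_out = knocked_out)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Expression propagation: min over AND, max over OR; genes missing from
#' the profile contribute NA and are dropped (a reaction with no measured
#' gene gets NA).
#' @noRd
gpr_eval_expr <- function(tree, expr_values) {
  if (is.null(tree)) return(NA_real_)
  if (is.character(tree)) {
    v <- expr_values[tree]
    return(if (is.null(v) || is.na(v)) NA_real_ else unname(v))
  }
  vals <- vapply(tree$args, gpr_eval_expr, numeric(1),
                 expr_values = expr_values)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Render a parsed tree back to a canonical rule string
#' @noRd
gpr_deparse <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  inner <- vapply(tree$args, function(a) {
    s <- gpr_deparse(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(inner, collapse = paste0(" ", tree$op, " "))
}
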