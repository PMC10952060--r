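# atom selection language
#
# grammar:
#   expr    := and_expr ("or" and_expr)*
#   and_expr:= unary ("and" unary)*
#   unary   := "not" unary | "(" expr ")" | field values
#   field   := chain | resid | resname | name | element
#   values  := one or more bare tokens; resid accepts ranges "lo:hi"
#
# "or" is set union, "and" intersection, "not" complement over all atoms.

.sel_fields <- c("chain", "resid", "resname", "name", "element")
.sel_keywords <- c("and", "or", "not", .sel_fields)

sel_tokenize <- function(expression) {
  toks <- list()
  i <- 1L
  n <- nchar(expression)
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(text = ch, pos = i)
      i <- i + 1L
      next
    }
    rest <- substr(expression, i, n)
    m <- regmatches(rest, regexpr("^[A-Za-z0-9_:'*.-]+", rest))
    if (length(m) == 0L)
      stop_loxdyn(sprintf("selection parse error at position %d: unexpected '%s'",
                          i, ch), "loxdyn_parse_error")
    toks[[length(toks) + 1L]] <- list(text = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

# parser state: environment with tokens and cursor
sel_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
sel_next <- function(st) { tk <- sel_peek(st); st$i <- st$i + 1L; tk }
sel_err <- function(st, what) {
  tk <- sel_peek(st)
  pos <- if (is.null(tk)) st$len + 1L else tk$pos
  stop_loxdyn(sprintf("selection parse error at position %d: expected %s",
                      pos, what), "loxdyn_parse_error")
}

sel_parse_expr <- function(st) {
  node <- sel_parse_and(st)
  while (!is.null(tk <- sel_peek(st)) && tk$text == "or") {
    sel_next(st)
    node <- list(op = "or", a = node, b = sel_parse_and(st))
  }
  node
}

sel_parse_and <- function(st) {
  node <- sel_parse_unary(st)
  while (!is.null(tk <- sel_peek(st)) && tk$text == "and") {
    sel_next(st)
    node <- list(op = "and", a = node, b = sel_parse_unary(st))
  }
  node
}

sel_parse_unary <- function(st) {
  tk <- sel_peek(st)
  if (is.null(tk)) sel_err(st, "a term")
  if (tk$text == "not") {
    sel_next(st)
    return(list(op = "not", a = sel_parse_unary(st)))
  }
  if (tk$text == "(") {
    sel_next(st)
    node <- sel_parse_expr(st)
    cl <- sel_peek(st)
    if (is.null(cl) || cl$text != ")") sel_err(st, "')'")
    sel_next(st)
    return(node)
  }
  if (tk$text %in% .sel_fields) {
    sel_next(st)
    vals <- character(0)
    while (!is.null(v <- sel_peek(st)) &&
           !(v$text %in% c(.sel_keywords, ")", "("))) {
      vals <- c(vals, v$text)
      sel_next(st)
    }
    if (length(vals) == 0L) sel_err(st, paste0("value(s) after '", tk$text, "'"))
    return(list(op = "field", field = tk$text, values = vals, pos = tk$pos))
  }
  sel_err(st, "'not', '(' or a field name")
}

sel_eval <- function(node, model) {
  n <- n_atoms(model)
  switch(node$op,
    or  = union(sel_eval(node$a, model), sel_eval(node$b, model)),
    and = intersect(sel_eval(node$a, model), sel_eval(node$b, model)),
    not = setdiff(seq_len(n), sel_eval(node$a, model)),
    field = {
      a <- model$atoms
      if (node$field == "resid") {
        ids <- integer(0)
        for (v in node$values) {
          if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
            lim <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
            ids <- c(ids, seq(lim[1], lim[2]))
          } else if (grepl("^-?[0-9]+$", v)) {
            ids <- c(ids, as.integer(v))
          } else {
            stop_loxdyn(sprintf(
              "selection parse error at position %d: resid value '%s' is not an integer or range",
              node$pos, v), "loxdyn_parse_error")
          }
        }
        which(a$resid %in% ids)
      } else {
        col <- switch(node$field, chain = a$chain, resname = a$resname,
                      name = a$name, element = a$element)
        which(col %in% node$values)
      }
    },
    stop_loxdyn("internal: unknown selection node", "loxdyn_parse_error"))
}

#' Select atoms by expression
#'
#' Resolves a selection expression into a sorted set of 1-based atom
#' indices. Fields: `chain`, `resid`, `resname`, `name`, `element`; `resid`
#' accepts inclusive ranges (`resid 37:43`); boolean `and` / `or` / `not`
#' and parentheses compose terms. An empty result is valid.
#'
#' @param model a [structure_model()].
#' @param expression selection text, e.g. `"chain P and resid 112"`.
#' @return an [atom_set()] labelled with the expression.
#' @export
#' @examples
#' m <- structure_model(
#'   data.frame(name = c("CA", "FE"), resname = c("GLY", "FE"),
#'              resid = 1:2, chain = "A"),
#'   matrix(0, 2, 3))
#' select_atoms(m, "name FE")
select_atoms <- function(model, expression) {
  stopifnot(inherits(model, "structure_model"), is.character(expression))
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$len <- nchar(expression)
  if (length(toks) == 0L)
    stop_loxdyn("selection parse error at position 1: empty expression",
                "loxdyn_parse_error")
  node <- sel_parse_expr(st)
  if (!is.null(tk <- sel_peek(st)))
    stop_loxdyn(sprintf("selection parse error at position %d: trailing input '%s'",
                        tk$pos, tk$text), "loxdyn_parse_error")
  atom_set(sel_eval(node, model), label = expression, model = model)
}
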