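#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean formulas over gene identifiers: \code{and} encodes
#' enzyme complexes (all subunits required), \code{or} encodes isoenzymes
#' (any alternative suffices). Accepts \code{and}/\code{or} (case
#' insensitive), \code{&&}/\code{||}, \code{&}/\code{|} and parentheses.
#'
#' @param x GPR string; \code{""}/\code{NA} yield an empty association.
#' @return object of class \code{gpr}: a list with \code{expression} (the
#'   parse tree, \code{NULL} when empty) and \code{genes} (character vector
#'   of gene ids appearing in the rule).
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' g$genes
#' gpr_eval(g, knocked = c("g1", "g3"))
#' @export
parse_gpr <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(x))) {
    return(structure(list(expression = NULL, genes = character(0)), class = "gpr"))
  }
  s <- gsub("&&|&", " and ", x)
  s <- gsub("\\|\\||\\|", " or ", s)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error in '", x, "': unexpected end of rule")
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) {
        stop("GPR parse error in '", x, "': missing closing parenthesis")
      }
      advance()
      return(e)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop("GPR parse error in '", x, "': unexpected token '", t, "'")
    }
    advance()
    list(op = "gene", gene = t)
  }

  tree <- parse_expr()
  if (pos <= length(toks)) {
    stop("GPR parse error in '", x, "': trailing token '", toks[pos], "'")
  }
  structure(list(expression = tree, genes = sort(unique(gpr_collect_genes(tree)))),
            class = "gpr")
}

gpr_collect_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$gene)
  unlist(lapply(tree$args, gpr_collect_genes))
}

#' Evaluate a GPR rule under a gene knockout assignment
#'
#' @param gpr object from [parse_gpr()].
#' @param knocked character vector of knocked-out gene ids.
#' @return \code{TRUE} if the reaction retains catalysis, \code{FALSE} if the
#'   knockouts abolish it; \code{NA} for an empty rule (no genetic
#'   information).
#' @export
gpr_eval <- function(gpr, knocked = character(0)) {
  stopifnot(inherits(gpr, "gpr"))
  if (is.null(gpr$expression)) return(NA)
  eval_node <- function(node) {
    switch(node$op,
      gene = !(node$gene %in% knocked),
      and  = all(vapply(node$args, eval_node, logical(1))),
      or   = any(vapply(node$args, eval_node, logical(1)))
    )
  }
  eval_node(gpr$expression)
}

#' Gene units of a GPR rule
#'
#' A gene unit is a maximal AND-subtree of the rule: an enzyme complex
#' (\code{g1 and g2}) counts as one unit, while OR-alternatives (isoenzymes)
#' count separately. Units are identified by their sorted gene sets, so
#' \code{"g2 and g1"} and \code{"g1 and g2"} are the same unit.
#'
#' @param gpr object from [parse_gpr()].
#' @return character vector of unit keys (genes joined by \code{"+"}),
#'   one per alternative; empty for an empty rule.
#' @export
gpr_units <- function(gpr) {
  stopifnot(inherits(gpr, "gpr"))
  if (is.null(gpr$expression)) return(character(0))
  alts <- if (gpr$expression$op == "or") gpr$expression$args else list(gpr$expression)
  vapply(alts, function(a) paste(sort(unique(gpr_collect_genes(a))), collapse = "+"),
         character(1))
}

#' @export
format.gpr <- function(x, ...) {
  if (is.null(x$expression)) return("")
  dep <- function(node, parent_op = NA_character_) {
    if (node$op == "gene") return(node$gene)
    inner <- vapply(node$args, dep, character(1), parent_op = node$op)
    s <- paste(inner, collapse = paste0(" ", node$op, " "))
    if (!is.na(parent_op) && parent_op != node$op) paste0("(", s, ")") else s
  }
  dep(x$expression)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr>", if (is.null(x$expression)) "(empty)" else format(x), "\n")
  invisible(x)
}

# TRUE when the rule is a flat OR over single genes (isoenzyme family).
gpr_is_or_only <- function(gpr) {
  if (is.null(gpr$expression)) return(FALSE)
  e <- gpr$expression
  if (e$op == "gene") return(TRUE)
  if (e$op != "or") return(FALSE)
  all(vapply(e$args, function(a) a$op == "gene", logical(1)))
}
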