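# Rule patterns and filled rules.
#
# A rule pattern is a template "LHS -> RHS" where the LHS is a conjunction of
# clauses, each clause a parenthesized disjunction of slots (or a bare slot),
# and the RHS is a single slot. A slot is either a blank or an elementary
# equality column=values (values: one or more single characters, e.g. age=AB
# meaning age is A or B). Parsing normalizes to AND-of-OR-clauses form:
# nested ANDs are flattened into the top-level conjunction, nested ORs into
# their enclosing disjunction; an OR joining ANDs is rejected, as is an OR
# outside parentheses.

slot_blank <- function() list(kind = "blank")

slot_eq <- function(column, values) {
  list(kind = "eq", column = column,
       values = sort(unique(values), method = "radix"))
}

is_blank <- function(slot) identical(slot$kind, "blank")

gar_tokenize <- function(text) {
  text <- gsub("→", "->", text, fixed = TRUE)
  text <- gsub("□", "_", text, fixed = TRUE)
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  text <- gsub("->", " -> ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

parse_slot_token <- function(tok) {
  if (tok == "_") return(slot_blank())
  if (grepl("=", tok, fixed = TRUE)) {
    at <- regexpr("=", tok, fixed = TRUE)
    name <- substr(tok, 1L, at - 1L)
    vals <- substr(tok, at + 1L, nchar(tok))
    if (!nzchar(name) || !nzchar(vals)) {
      rlang::abort(paste0("malformed equality: ", tok), class = "gar_pattern_error")
    }
    return(slot_eq(name, strsplit(vals, "")[[1]]))
  }
  rlang::abort(paste0("unknown token in pattern: '", tok, "'"),
               class = "gar_pattern_error")
}

# Recursive-descent parse of a (sub)sequence of tokens into a tree of
# list(op = "AND"|"OR"|"ONE", items = ...) nodes with slots at the leaves.
parse_seq <- function(toks) {
  items <- list()
  ops <- character()
  i <- 1L
  n <- length(toks)
  if (n == 0L) {
    rlang::abort("empty expression in pattern", class = "gar_pattern_error")
  }
  repeat {
    if (i > n) rlang::abort("pattern ends unexpectedly", class = "gar_pattern_error")
    tok <- toks[i]
    if (tok == "(") {
      depth <- 1L
      j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) {
          rlang::abort("unbalanced parentheses in pattern",
                       class = "gar_pattern_error")
        }
        if (toks[j] == "(") depth <- depth + 1L
        if (toks[j] == ")") depth <- depth - 1L
      }
      items[[length(items) + 1L]] <- parse_seq(toks[seq.int(i + 1L, length.out = j - i - 1L)])
      i <- j + 1L
    } else if (tok == ")") {
      rlang::abort("unbalanced parentheses in pattern", class = "gar_pattern_error")
    } else if (tok %in% c("AND", "OR")) {
      rlang::abort(paste0("misplaced operator ", tok, " in pattern"),
                   class = "gar_pattern_error")
    } else {
      items[[length(items) + 1L]] <- parse_slot_token(tok)
      i <- i + 1L
    }
    if (i > n) break
    if (!toks[i] %in% c("AND", "OR")) {
      rlang::abort(paste0("expected AND or OR, got '", toks[i], "'"),
                   class = "gar_pattern_error")
    }
    ops <- c(ops, toks[i])
    i <- i + 1L
  }
  if (length(unique(ops)) > 1L) {
    rlang::abort("AND and OR mixed at the same level; parenthesize the disjunction",
                 class = "gar_pattern_error")
  }
  if (length(ops) == 0L) {
    if (length(items) == 1L && !is.null(items[[1]]$op)) return(items[[1]])
    return(list(op = "ONE", items = items))
  }
  list(op = ops[1], items = items)
}

# Flatten a node that must be a pure disjunction into its slots.
flatten_or <- function(node) {
  if (!is.null(node$kind)) return(list(node))
  if (node$op == "AND") {
    rlang::abort("a disjunction may not contain AND; only top-level AND of OR-clauses is supported",
                 class = "gar_pattern_error")
  }
  out <- list()
  for (it in node$items) out <- c(out, flatten_or(it))
  out
}

# Normalize a parse tree to a list of clauses (each a list of slots).
norm_to_clauses <- function(node) {
  if (!is.null(node$kind)) return(list(list(node)))
  if (node$op == "ONE") return(norm_to_clauses(node$items[[1]]))
  if (node$op == "AND") {
    out <- list()
    for (it in node$items) out <- c(out, norm_to_clauses(it))
    return(out)
  }
  list(flatten_or(node))
}

#' Parse a rule-pattern expression
#'
#' Accepts the pattern grammar: blanks (`_` or the box character),
#' parentheses, `AND`, `OR`, and the implies sign (`->` or the arrow
#' character). The right-hand side must be a single slot. Slots may also be
#' elementary equalities (`column=values`), so the same parser reads filled
#' rules; see [gar_parse_rule()]. `OR` is only legal inside parentheses and
#' may not contain `AND`; nested conjunctions and disjunctions are
#' flattened, so the result is always in AND-of-OR-clauses form.
#'
#' @param text The pattern, e.g. `"_ AND (_ OR _) -> _"`.
#' @return A `gar_pattern` object with fields `lhs` (list of clauses, each
#'   a list of slots) and `rhs` (one slot).
#' @examples
#' p <- gar_pattern("_ AND (_ OR _) -> _")
#' p
#' gar_pattern("x=a AND (bread=y OR onions=n) -> butter=y")
#' @export
gar_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  toks <- gar_tokenize(text)
  arrow <- which(toks == "->")
  if (length(arrow) != 1L) {
    rlang::abort("a rule pattern must contain exactly one implies sign (->)",
                 class = "gar_pattern_error")
  }
  rhs_toks <- toks[seq.int(arrow + 1L, length.out = length(toks) - arrow)]
  if (length(rhs_toks) != 1L || rhs_toks[1] %in% c("(", ")", "AND", "OR")) {
    rlang::abort("the right-hand side of a rule must consist of a single blank (or a single equality)",
                 class = "gar_pattern_error")
  }
  if (arrow == 1L) {
    rlang::abort("the left-hand side of a rule pattern is empty",
                 class = "gar_pattern_error")
  }
  lhs_toks <- toks[seq_len(arrow - 1L)]
  depth <- cumsum((lhs_toks == "(") - (lhs_toks == ")"))
  if (any(lhs_toks == "OR" & depth == 0L)) {
    rlang::abort("OR outside parentheses is ambiguous; write (_ OR _)",
                 class = "gar_pattern_error")
  }
  lhs_node <- parse_seq(lhs_toks)
  structure(list(
    lhs = norm_to_clauses(lhs_node),
    rhs = parse_slot_token(rhs_toks[1])
  ), class = "gar_pattern")
}

#' Parse a fully filled rule
#'
#' Like [gar_pattern()] but every slot must be an elementary equality; the
#' result is a `gar_rule` suitable for [gar_evaluate()] and
#' [gar_rule_metrics()].
#'
#' @param text The rule, e.g. `"age=AB AND (bread=y OR onions=n) -> butter=y"`.
#' @return A `gar_rule` object (fields `lhs`, `rhs`).
#' @export
gar_parse_rule <- function(text) {
  p <- gar_pattern(text)
  if (pattern_n_blanks(p) > 0L) {
    rlang::abort("rule contains unfilled blanks", class = "gar_contract_error")
  }
  structure(list(lhs = p$lhs, rhs = p$rhs), class = "gar_rule")
}

pattern_n_blanks <- function(p) {
  sum(vapply(p$lhs, function(cl) sum(vapply(cl, is_blank, logical(1))), integer(1))) +
    as.integer(is_blank(p$rhs))
}

render_slot <- function(slot) {
  if (is_blank(slot)) return("_")
  paste0(slot$column, "=", paste(slot$values, collapse = ""))
}

render_clause <- function(clause) {
  if (length(clause) == 1L) return(render_slot(clause[[1]]))
  paste0("(", paste(vapply(clause, render_slot, character(1)), collapse = " OR "), ")")
}

render_expr <- function(lhs, rhs) {
  paste0(paste(vapply(lhs, render_clause, character(1)), collapse = " AND "),
         " -> ", render_slot(rhs))
}

#' Render a rule (or pattern) as canonical text
#'
#' Clauses are joined by `" AND "`, multi-slot clauses are parenthesized and
#' joined by `" OR "` inside, equalities render as `name=values` with values
#' sorted ascending by character code, and the RHS follows `" -> "`.
#' Re-parsing the rendered text reproduces the structure.
#'
#' @param rule A `gar_rule` or `gar_pattern`.
#' @return A single string.
#' @examples
#' gar_render_rule(gar_parse_rule("x=a AND (bread=y OR onions=n) -> butter=y"))
#' @export
gar_render_rule <- function(rule) {
  if (inherits(rule, "gar_rule") &&
      pattern_n_blanks(rule) > 0L) {
    rlang::abort("rule contains unfilled blanks", class = "gar_contract_error")
  }
  render_expr(rule$lhs, rule$rhs)
}

#' @export
format.gar_pattern <- function(x, ...) render_expr(x$lhs, x$rhs)

#' @export
print.gar_pattern <- function(x, ...) {
  cat("<gar_pattern> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.gar_rule <- function(x, ...) render_expr(x$lhs, x$rhs)

#' @export
print.gar_rule <- function(x, ...) {
  cat("<gar_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Number of conjunctive rules a generalized LHS compresses
#'
#' Expanding an AND-of-OR-clauses left-hand side to disjunctive normal form
#' produces one pure conjunction per choice of a single slot from each
#' clause, so the count is the product of the clause sizes. For instance a
#' LHS of three two-way disjunctions expands to eight ternary conjunctions.
#'
#' @param rule A `gar_rule` (or a `gar_pattern` whose LHS slots are all
#'   filled).
#' @return An integer count.
#' @examples
#' gar_dnf_count(gar_parse_rule("(a=1 OR b=1) AND (c=1 OR d=1) -> e=1"))
#' @export
gar_dnf_count <- function(rule) {
  lhs_blanks <- sum(vapply(rule$lhs, function(cl) {
    sum(vapply(cl, is_blank, logical(1)))
  }, integer(1)))
  if (lhs_blanks > 0L) {
    rlang::abort("LHS contains unfilled blanks", class = "gar_contract_error")
  }
  prod(lengths(rule$lhs))
}
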