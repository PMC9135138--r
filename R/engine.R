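# Rule evaluation over packed row sets and the four rule quality measures.
#
# Probabilities are empirical frequencies over all N table rows, including
# rows with missing values in the referenced columns: a missing cell simply
# satisfies no elementary equality. With N the row count,
#   confidence = support / lhs_support
#   lift       = support * N / (lhs_support * rhs_support)
#   leverage   = support/N - (lhs_support/N) * (rhs_support/N)
# (Piatetsky-Shapiro leverage). Lift is 1 and leverage 0 exactly when LHS
# and RHS occur independently.

# Internal: packed row set of one elementary equality slot.
eq_rowset <- function(table, slot) {
  j <- resolve_column(table, slot$column)
  idx <- table$index[[j]]
  dom <- table$columns$domain[[j]]
  if (length(dom) == 0L) {
    # an all-missing column satisfies no equality
    return(rowset_empty(table$n_rows))
  }
  miss <- setdiff(slot$values, dom)
  if (length(miss) > 0L) {
    rlang::abort(sprintf("value '%s' not in the domain of column '%s'",
                         miss[1], table$columns$name[j]),
                 class = "gar_contract_error")
  }
  out <- idx[[slot$values[1]]]
  for (v in slot$values[-1]) out <- rowset_or(out, idx[[v]])
  out
}

#' Rows satisfying one elementary equality
#'
#' An elementary equality states that a column equals one of a given set of
#' single-character values. Missing cells never match.
#'
#' @param table A `gar_table`.
#' @param column Column name or 1-based index.
#' @param values Character vector of single-character values; must be a
#'   subset of the column's observed domain.
#' @return An integer vector of matching row numbers.
#' @examples
#' tab <- gar_read_table(text = "x,y\na,b\na,\nc,b\n")
#' gar_equality_rows(tab, "x", "a")
#' @export
gar_equality_rows <- function(table, column, values) {
  rowset_members(eq_rowset(table, slot_eq(column, values)))
}

# Internal: packed row set of an AND-of-OR-clauses expression. A zero-clause
# conjunction is the universal set (the identity of AND), which the
# simplifier relies on.
eval_clauses <- function(table, clauses) {
  acc <- rowset_full(table$n_rows)
  for (cl in clauses) {
    crow <- eq_rowset(table, cl[[1]])
    for (slot in cl[-1]) crow <- rowset_or(crow, eq_rowset(table, slot))
    acc <- rowset_and(acc, crow)
  }
  acc
}

#' Evaluate a rule side against a table
#'
#' Evaluates an AND-of-OR-clauses expression with word-parallel bit
#' operations: each elementary equality is a packed bitset over the rows,
#' disjunction within a clause and conjunction across clauses are single
#' vectorised machine-word operations, so whole blocks of rows are processed
#' per instruction rather than one row at a time.
#'
#' @param table A `gar_table`.
#' @param x A `gar_rule` (its LHS is evaluated), or a list of clauses, each
#'   clause a list of slots as produced by [gar_parse_rule()].
#' @return Integer vector of row numbers where the expression holds.
#' @examples
#' tab <- gar_read_table(text = "x,y\na,b\na,\nc,b\n")
#' gar_evaluate(tab, gar_parse_rule("x=a -> y=b"))
#' @export
gar_evaluate <- function(table, x) {
  clauses <- if (inherits(x, "gar_rule") || inherits(x, "gar_pattern")) x$lhs else x
  rowset_members(eval_clauses(table, clauses))
}

# Internal: metrics from packed row sets. Returns a plain list; confidence,
# lift and leverage are NA (undefined) when a side has zero support.
compute_metrics <- function(lhs_rows, rhs_rows, n_rows) {
  if (!identical(attr(lhs_rows, "n"), attr(rhs_rows, "n"))) {
    rlang::abort("row-set width mismatch", class = "gar_contract_error")
  }
  stopifnot(n_rows > 0L)
  lhs_support <- rowset_count(lhs_rows)
  rhs_support <- rowset_count(rhs_rows)
  support <- rowset_count(rowset_and(lhs_rows, rhs_rows))
  if (lhs_support == 0L || rhs_support == 0L) {
    return(list(support = support, lhs_support = lhs_support,
                rhs_support = rhs_support, confidence = NA_real_,
                lift = NA_real_, leverage = NA_real_))
  }
  list(
    support = support,
    lhs_support = lhs_support,
    rhs_support = rhs_support,
    confidence = support / lhs_support,
    lift = (support * n_rows) / (lhs_support * rhs_support),
    leverage = support / n_rows - (lhs_support / n_rows) * (rhs_support / n_rows)
  )
}

#' Quality measures of a rule on a table
#'
#' Computes support (rows where LHS and RHS both hold), LHS support, RHS
#' support, confidence, lift and leverage. Confidence, lift and leverage are
#' `NA` when either side holds on no row.
#'
#' @param table A `gar_table`.
#' @param rule A `gar_rule` or rule text parseable by [gar_parse_rule()].
#' @return A one-row tibble with columns `rule`, `support`, `lhs_support`,
#'   `rhs_support`, `confidence`, `lift`, `leverage`.
#' @examples
#' tab <- gar_read_table(text = "x,y\na,b\na,\nc,b\n")
#' gar_rule_metrics(tab, "x=a -> y=b")
#' @export
gar_rule_metrics <- function(table, rule) {
  if (is.character(rule)) rule <- gar_parse_rule(rule)
  lhs <- eval_clauses(table, rule$lhs)
  rhs <- eq_rowset(table, rule$rhs)
  m <- compute_metrics(lhs, rhs, table$n_rows)
  tibble::tibble(rule = gar_render_rule(rule), !!!m)
}
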