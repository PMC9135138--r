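# Candidate enumeration, branch-and-bound pattern filling, greedy rule
# simplification and the RHS-partitioned top-level miner.

#' Search configuration for the miner
#'
#' @param min_support Minimum support (row count), inclusive. At least 1.
#' @param min_confidence Minimum confidence in `[0, 1]`, inclusive.
#' @param min_lift Minimum lift, inclusive.
#' @param min_leverage Minimum leverage, inclusive. The default (-0.25, the
#'   lower end of leverage's range) passes every rule.
#' @param max_value_set_size Largest value set an elementary equality may
#'   hold. The default 2 keeps the otherwise exponential set enumeration
#'   small; the full domain of a column is never used (it would be a
#'   tautology).
#' @param lhs_columns Columns (names or indices) allowed on the left-hand
#'   side; `NULL` means all columns.
#' @param rhs_columns Columns allowed on the right-hand side; `NULL` means
#'   all columns.
#' @param rhs_singleton_only If `TRUE` (default) the RHS blank is only
#'   filled with single-value equalities.
#' @param simplify_tolerance Largest relative lift decrease, as a fraction
#'   of the original rule's lift, that a simplification step may cause
#'   (default 0.02, i.e. 2 percent).
#' @param max_rules Keep at most this many rules after sorting.
#' @param jobs Number of workers the RHS-partitioned job list is meant for.
#'   The result is identical for any value; jobs are processed in a fixed
#'   deterministic order.
#' @return A `gar_config` list.
#' @export
gar_config <- function(min_support = 1L,
                       min_confidence = 0,
                       min_lift = 0,
                       min_leverage = -0.25,
                       max_value_set_size = 2L,
                       lhs_columns = NULL,
                       rhs_columns = NULL,
                       rhs_singleton_only = TRUE,
                       simplify_tolerance = 0.02,
                       max_rules = Inf,
                       jobs = 1L) {
  if (!(is.numeric(min_support) && min_support >= 1)) {
    rlang::abort("min_support must be at least 1", class = "gar_config_error")
  }
  if (!(min_confidence >= 0 && min_confidence <= 1)) {
    rlang::abort("min_confidence must lie in [0, 1]", class = "gar_config_error")
  }
  if (!(simplify_tolerance >= 0 && simplify_tolerance < 1)) {
    rlang::abort("simplify_tolerance must lie in [0, 1)", class = "gar_config_error")
  }
  if (!(max_value_set_size >= 1)) {
    rlang::abort("max_value_set_size must be at least 1", class = "gar_config_error")
  }
  if (!(jobs >= 1)) {
    rlang::abort("jobs must be at least 1", class = "gar_config_error")
  }
  structure(list(
    min_support = as.integer(ceiling(min_support)),
    min_confidence = min_confidence,
    min_lift = min_lift,
    min_leverage = min_leverage,
    max_value_set_size = as.integer(max_value_set_size),
    lhs_columns = lhs_columns,
    rhs_columns = rhs_columns,
    rhs_singleton_only = isTRUE(rhs_singleton_only),
    simplify_tolerance = simplify_tolerance,
    max_rules = max_rules,
    jobs = as.integer(jobs)
  ), class = "gar_config")
}

#' Enumerate the elementary equalities of one column
#'
#' All non-empty value subsets of the column's observed domain with at most
#' `max_value_set_size` values, excluding the full domain whenever the
#' domain has two or more values (equality with the full domain is true on
#' every non-missing row and carries no information). Ordered canonically:
#' by set size, then by character codes.
#'
#' @param table A `gar_table`.
#' @param column Column name or index.
#' @param max_value_set_size Largest subset size.
#' @return A list of character vectors (value sets), possibly empty for an
#'   all-missing column.
#' @examples
#' tab <- gar_read_table(text = "x\nA\nB\nC\n")
#' gar_enumerate_equalities(tab, "x", 2)
#' @export
gar_enumerate_equalities <- function(table, column, max_value_set_size = 2L) {
  j <- resolve_column(table, column)
  dom <- table$columns$domain[[j]]
  k <- length(dom)
  if (k == 0L) return(list())
  out <- list()
  for (size in seq_len(min(max_value_set_size, k))) {
    if (size == k && k >= 2L) next  # full domain is tautological
    sets <- utils::combn(dom, size, simplify = FALSE)
    out <- c(out, sets)
  }
  out
}

# Flat LHS candidate pool over the permitted columns, in canonical order
# (column index, then the column's canonical equality order). Each entry
# carries its precomputed packed row set.
build_candidates <- function(table, cols, max_value_set_size) {
  out <- list()
  for (j in cols) {
    nm <- table$columns$name[j]
    for (vals in gar_enumerate_equalities(table, j, max_value_set_size)) {
      slot <- slot_eq(nm, vals)
      out[[length(out) + 1L]] <- list(
        column = j, slot = slot,
        rows = eq_rowset(table, slot)
      )
    }
  }
  out
}

#' Sound support bound for a partially filled pattern
#'
#' With some clauses fully assigned and the rest still holding blanks, no
#' completion can ever have support above the size of the intersection of
#' the assigned clauses' row sets with the RHS row set: conjunction only
#' shrinks row sets, so unfilled clauses are replaced by the universal set.
#' The miner backtracks as soon as this bound falls below `min_support`,
#' pruning every completion of the branch at once. The bound is tight at a
#' leaf, where it equals the rule's exact support.
#'
#' @param table A `gar_table`.
#' @param assigned_clauses List of fully assigned clauses (possibly empty),
#'   each a list of equality slots; e.g. the `lhs` of a [gar_parse_rule()]
#'   result.
#' @param rhs An RHS equality: a rule's `rhs` slot, or a list
#'   `list(column=, values=)`.
#' @return Integer upper bound on the support of any completion.
#' @export
gar_support_upper_bound <- function(table, assigned_clauses, rhs) {
  rhs_rows <- eq_rowset(table, slot_eq(rhs$column, rhs$values))
  acc <- eval_clauses(table, assigned_clauses)
  rowset_count(rowset_and(acc, rhs_rows))
}

# Depth-first fill of one RHS job. Blanks are filled clause by clause,
# left to right; within a clause blank fillings are strictly increasing in
# the canonical candidate order with pairwise distinct columns, and a
# clause structurally identical to its predecessor (same size, all blanks)
# must fill to a tuple lexicographically >= its predecessor's, so each
# unordered rule is generated exactly once. After each completed clause the
# support bound (intersection with the RHS row set) is checked against
# min_support and the branch is pruned when it fails.
fill_pattern_job <- function(table, pattern, rhs_slot, cfg, cands) {
  n <- table$n_rows
  rhs_col <- resolve_column(table, rhs_slot$column)
  rhs_rows <- eq_rowset(table, rhs_slot)
  rhs_support <- rowset_count(rhs_rows)
  res <- vector("list", 64L)
  nres <- 0L
  pruned <- 0L
  if (rhs_support < cfg$min_support) {
    return(list(rules = list(), pruned = 1L))
  }
  clauses <- pattern$lhs
  n_clauses <- length(clauses)
  cand_cols <- vapply(cands, `[[`, integer(1), "column")
  nc <- length(cands)
  min_support <- cfg$min_support

  # per-clause static info
  sizes <- lengths(clauses)
  all_blank <- vapply(clauses, function(cl) all(vapply(cl, is_blank, logical(1))),
                      logical(1))

  filled <- vector("list", n_clauses)   # per clause: integer cand indices (NA for fixed)
  clause_slots <- vector("list", n_clauses)

  emit <- function(acc_rows) {
    m <- compute_metrics(acc_rows, rhs_rows, n)
    if (is.na(m$confidence)) return(invisible())
    if (m$support < cfg$min_support) return(invisible())
    if (m$confidence < cfg$min_confidence) return(invisible())
    if (m$lift < cfg$min_lift) return(invisible())
    if (m$leverage < cfg$min_leverage) return(invisible())
    rule <- structure(list(lhs = clause_slots[seq_len(n_clauses)],
                           rhs = rhs_slot), class = "gar_rule")
    nres <<- nres + 1L
    if (nres > length(res)) length(res) <<- 2L * nres
    res[[nres]] <<- list(rule = rule, metrics = m)
    invisible()
  }

  rec_clause <- function(ci, acc_rows) {
    if (ci > n_clauses) {
      emit(acc_rows)
      return(invisible())
    }
    cl <- clauses[[ci]]
    sz <- sizes[ci]
    # sibling ordering applies between adjacent all-blank clauses of equal size
    prev_tuple <- if (ci > 1L && all_blank[ci] && all_blank[ci - 1L] &&
                      sizes[ci] == sizes[ci - 1L]) filled[[ci - 1L]] else NULL

    fill_slot <- function(si, last_idx, used_cols, or_rows, tuple, tied, slots_acc) {
      if (si > sz) {
        new_acc <- rowset_and(acc_rows, or_rows)
        if (rowset_count(rowset_and(new_acc, rhs_rows)) < min_support) {
          pruned <<- pruned + 1L
          return(invisible())
        }
        filled[[ci]] <<- tuple
        clause_slots[[ci]] <<- slots_acc
        rec_clause(ci + 1L, new_acc)
        return(invisible())
      }
      slot <- cl[[si]]
      if (!is_blank(slot)) {
        j <- resolve_column(table, slot$column)
        if (j %in% used_cols) return(invisible())
        srows <- eq_rowset(table, slot)
        new_or <- if (is.null(or_rows)) srows else rowset_or(or_rows, srows)
        fill_slot(si + 1L, last_idx, c(used_cols, j), new_or,
                  c(tuple, NA_integer_), FALSE, c(slots_acc, list(slot)))
        return(invisible())
      }
      lo <- last_idx + 1L
      if (tied) lo <- max(lo, prev_tuple[si])
      if (lo > nc) return(invisible())
      for (k in lo:nc) {
        jcol <- cand_cols[k]
        if (jcol %in% used_cols) next
        cand <- cands[[k]]
        new_or <- if (is.null(or_rows)) cand$rows else rowset_or(or_rows, cand$rows)
        fill_slot(si + 1L, k, c(used_cols, jcol), new_or,
                  c(tuple, k), tied && !is.na(prev_tuple[si]) && k == prev_tuple[si],
                  c(slots_acc, list(cand$slot)))
      }
      invisible()
    }

    fill_slot(1L, 0L, integer(), NULL, integer(), !is.null(prev_tuple), list())
    invisible()
  }

  rec_clause(1L, rowset_full(n))
  list(rules = if (nres > 0L) res[seq_len(nres)] else list(), pruned = pruned)
}

#' Greedily simplify a rule under a lift tolerance
#'
#' Repeatedly deletes elementary parts of the left-hand side — a whole
#' conjunct clause, or one disjunct from a multi-slot clause — as long as
#' the rule's lift does not fall more than `tolerance` (relative) below the
#' lift of the *original* rule and the result still passes all thresholds
#' in `config`. At each step every admissible deletion is evaluated and the
#' one with the highest resulting lift is applied (ties go to the textually
#' smaller rule). The last remaining clause is never deleted.
#'
#' @param table A `gar_table`.
#' @param rule A `gar_rule` (or rule text).
#' @param config A [gar_config()]; supplies the thresholds and, unless
#'   `tolerance` is given, the tolerance.
#' @param tolerance Relative lift decrease allowed, overriding
#'   `config$simplify_tolerance`.
#' @return A list with `rule` (the simplified `gar_rule`), `metrics`,
#'   `changed` (logical), and `original` (the input rule's text).
#' @export
gar_simplify <- function(table, rule, config = gar_config(),
                         tolerance = NULL) {
  if (is.character(rule)) rule <- gar_parse_rule(rule)
  tol <- if (is.null(tolerance)) config$simplify_tolerance else tolerance
  stopifnot(tol >= 0, tol < 1)
  rhs_rows <- eq_rowset(table, rule$rhs)
  rhs_support <- rowset_count(rhs_rows)
  n <- table$n_rows
  full <- rowset_full(n)
  # slot row sets are fixed by the table; compute each exactly once
  slot_rows <- lapply(rule$lhs, function(cl) lapply(cl, eq_rowset, table = table))
  metrics_of <- function(srows) {
    acc <- full
    for (cl in srows) {
      crow <- cl[[1]]
      for (s in cl[-1]) crow <- crow | s
      acc <- acc & crow
    }
    lhs_support <- rowset_count(acc)
    support <- rowset_count(acc & rhs_rows)
    if (lhs_support == 0L || rhs_support == 0L) {
      return(list(support = support, lhs_support = lhs_support,
                  rhs_support = rhs_support, confidence = NA_real_,
                  lift = NA_real_, leverage = NA_real_))
    }
    list(support = support, lhs_support = lhs_support,
         rhs_support = rhs_support,
         confidence = support / lhs_support,
         lift = (support * n) / (lhs_support * rhs_support),
         leverage = support / n - (lhs_support / n) * (rhs_support / n))
  }
  passes <- function(m) {
    !is.na(m$confidence) &&
      m$support >= config$min_support &&
      m$confidence >= config$min_confidence &&
      m$lift >= config$min_lift &&
      m$leverage >= config$min_leverage
  }
  original <- gar_render_rule(rule)
  m0 <- metrics_of(slot_rows)
  if (is.na(m0$lift)) {
    return(list(rule = rule, metrics = m0, changed = FALSE, original = original))
  }
  floor_lift <- (1 - tol) * m0$lift
  clauses <- rule$lhs
  m_cur <- m0
  repeat {
    candidates <- list()   # each: list(clauses=, srows=)
    # whole-clause deletions (never delete the last clause)
    if (length(clauses) > 1L) {
      for (ci in seq_along(clauses)) {
        candidates[[length(candidates) + 1L]] <-
          list(clauses = clauses[-ci], srows = slot_rows[-ci])
      }
    }
    # single-disjunct deletions from multi-slot clauses
    for (ci in seq_along(clauses)) {
      if (length(clauses[[ci]]) > 1L) {
        for (si in seq_along(clauses[[ci]])) {
          alt <- clauses
          alt[[ci]] <- alt[[ci]][-si]
          alt_r <- slot_rows
          alt_r[[ci]] <- alt_r[[ci]][-si]
          candidates[[length(candidates) + 1L]] <-
            list(clauses = alt, srows = alt_r)
        }
      }
    }
    if (length(candidates) == 0L) break
    best <- NULL
    best_m <- NULL
    best_text <- NULL
    for (alt in candidates) {
      m <- metrics_of(alt$srows)
      if (is.na(m$lift) || m$lift < floor_lift || !passes(m)) next
      if (!is.null(best) && m$lift < best_m$lift) next
      if (!is.null(best) && m$lift == best_m$lift) {
        # tie: prefer the textually smaller rule (render lazily)
        if (is.null(best_text)) best_text <- render_expr(best$clauses, rule$rhs)
        text <- render_expr(alt$clauses, rule$rhs)
        if (text >= best_text) next
        best_text <- text
      } else {
        best_text <- NULL
      }
      best <- alt
      best_m <- m
    }
    if (is.null(best)) break
    clauses <- best$clauses
    slot_rows <- best$srows
    m_cur <- best_m
  }
  if (!identical(clauses, rule$lhs)) {
    # deletions may leave equivalent rules differing only in clause order
    # (AND commutes); render deterministically by size, then clause text
    txt <- vapply(clauses, render_clause, character(1))
    clauses <- clauses[order(lengths(clauses), txt, method = "radix")]
  }
  out_rule <- structure(list(lhs = clauses, rhs = rule$rhs), class = "gar_rule")
  list(rule = out_rule, metrics = m_cur,
       changed = !identical(gar_render_rule(out_rule), original),
       original = original)
}

#' Mine generalized association rules matching a pattern
#'
#' Fills every blank of `pattern` with elementary equalities drawn from the
#' table, prunes the search with a sound support bound, keeps the rules
#' passing all four thresholds, simplifies each survivor under the lift
#' tolerance, and merges the per-RHS jobs into one deterministic ranking.
#' The search is partitioned by the right-hand side: each permitted RHS
#' equality is one independent job, and the merged result is identical for
#' any `jobs` setting, any row order of the input, and any number of
#' repetitions.
#'
#' Within a clause a column may appear once; the same column may appear in
#' different clauses, and the RHS column never appears on the LHS. Two
#' candidates that are equal up to the commutativity of AND/OR are counted
#' once. Rules are sorted by lift (descending), then support (descending),
#' then rule text; rules identical after simplification are de-duplicated.
#'
#' @param table A `gar_table`.
#' @param pattern A `gar_pattern` or pattern text such as
#'   `"_ AND (_ OR _) -> _"`.
#' @param config A [gar_config()]. Individual settings can also be passed
#'   through `...` as a shortcut, e.g. `gar_mine(tab, p, min_support = 5)`.
#' @param simplify If `FALSE`, survivors are reported unsimplified.
#' @param ... Settings forwarded to [gar_config()] when `config` is absent.
#' @return A `gar_rules` object; its `rules` tibble has one row per rule
#'   with columns `rule`, `support`, `lhs_support`, `rhs_support`,
#'   `confidence`, `lift`, `leverage`, `lift_pre_simplify`,
#'   `simplified_from` (`NA` when simplification left the rule unchanged).
#'   [generics::tidy()] returns that tibble, [generics::glance()] a one-row
#'   run summary.
#' @examples
#' tab <- gar_read_table(text = "x,y\na,b\na,b\na,\nc,b\nc,\nc,\n")
#' res <- gar_mine(tab, "_ -> _", min_support = 2, min_confidence = 0.5)
#' tidy(res)
#' @export
gar_mine <- function(table, pattern, config = NULL, simplify = TRUE, ...) {
  stopifnot(inherits(table, "gar_table"))
  if (is.character(pattern)) pattern <- gar_pattern(pattern)
  if (is.null(config)) config <- gar_config(...)
  cfg <- config

  all_cols <- table$columns$index
  usable <- all_cols[lengths(table$columns$domain) > 0L]
  lhs_cols <- if (is.null(cfg$lhs_columns)) usable else
    intersect(vapply(cfg$lhs_columns, resolve_column, integer(1), table = table), usable)
  rhs_cols <- if (is.null(cfg$rhs_columns)) usable else
    intersect(vapply(cfg$rhs_columns, resolve_column, integer(1), table = table), usable)
  if (length(rhs_cols) == 0L) {
    rlang::abort("no permitted RHS column", class = "gar_config_error")
  }
  if (length(lhs_cols) == 0L) {
    rlang::abort("no permitted LHS column", class = "gar_config_error")
  }

  # one job per permitted RHS equality
  if (is_blank(pattern$rhs)) {
    jobs <- list()
    rhs_max <- if (cfg$rhs_singleton_only) 1L else cfg$max_value_set_size
    for (j in rhs_cols) {
      nm <- table$columns$name[j]
      for (vals in gar_enumerate_equalities(table, j, rhs_max)) {
        jobs[[length(jobs) + 1L]] <- slot_eq(nm, vals)
      }
    }
  } else {
    jobs <- list(pattern$rhs)
  }

  rules <- list()
  pruned_total <- 0L
  for (job in jobs) {
    rhs_col <- resolve_column(table, job$column)
    cand_cols <- setdiff(lhs_cols, rhs_col)
    if (length(cand_cols) == 0L) next
    cands <- build_candidates(table, cand_cols, cfg$max_value_set_size)
    if (length(cands) == 0L) next
    out <- fill_pattern_job(table, pattern, job, cfg, cands)
    pruned_total <- pruned_total + out$pruned
    rules <- c(rules, out$rules)
  }

  rows <- lapply(rules, function(r) {
    m0 <- r$metrics
    if (simplify) {
      s <- gar_simplify(table, r$rule, cfg)
      m <- s$metrics
      list(rule = gar_render_rule(s$rule),
           support = m$support, lhs_support = m$lhs_support,
           rhs_support = m$rhs_support, confidence = m$confidence,
           lift = m$lift, leverage = m$leverage,
           lift_pre_simplify = m0$lift,
           simplified_from = if (s$changed) s$original else NA_character_)
    } else {
      list(rule = gar_render_rule(r$rule),
           support = m0$support, lhs_support = m0$lhs_support,
           rhs_support = m0$rhs_support, confidence = m0$confidence,
           lift = m0$lift, leverage = m0$leverage,
           lift_pre_simplify = m0$lift,
           simplified_from = NA_character_)
    }
  })

  tb <- tibble::tibble(
    rule = vapply(rows, `[[`, character(1), "rule"),
    support = vapply(rows, `[[`, integer(1), "support"),
    lhs_support = vapply(rows, `[[`, integer(1), "lhs_support"),
    rhs_support = vapply(rows, `[[`, integer(1), "rhs_support"),
    confidence = vapply(rows, `[[`, double(1), "confidence"),
    lift = vapply(rows, `[[`, double(1), "lift"),
    leverage = vapply(rows, `[[`, double(1), "leverage"),
    lift_pre_simplify = vapply(rows, `[[`, double(1), "lift_pre_simplify"),
    simplified_from = vapply(rows, `[[`, character(1), "simplified_from")
  )
  # de-duplicate rules identical after simplification (deterministic: keep
  # the first in canonical generation order), then rank
  tb <- tb[!duplicated(tb$rule), , drop = FALSE]
  ord <- order(-tb$lift, -tb$support, tb$rule, method = "radix")
  tb <- tb[ord, , drop = FALSE]
  if (is.finite(cfg$max_rules) && nrow(tb) > cfg$max_rules) {
    tb <- tb[seq_len(cfg$max_rules), , drop = FALSE]
  }

  structure(list(
    rules = tb,
    pattern = format(pattern),
    config = cfg,
    n_jobs = length(jobs),
    n_pruned = pruned_total,
    table_name = table$name,
    n_rows = table$n_rows,
    n_columns = nrow(table$columns)
  ), class = "gar_rules")
}

#' @export
print.gar_rules <- function(x, ...) {
  cat(sprintf("<gar_rules> pattern %s on %s (%d x %d): %d rule(s), %d job(s)\n",
              x$pattern, x$table_name, x$n_rows, x$n_columns,
              nrow(x$rules), x$n_jobs))
  print(x$rules)
  invisible(x)
}
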