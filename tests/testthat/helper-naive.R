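# Independent per-row oracle: its own CSV reading, logical-vector rule
# evaluation and metric arithmetic, plus an unpruned exhaustive miner. None
# of it touches the package's packed row sets or its search code, so it can
# stand against them in equivalence tests.

naive_cells <- function(csv) {
  lines <- strsplit(csv, "\n", fixed = TRUE)[[1]]
  lines <- lines[seq_len(max(which(nzchar(trimws(lines)))))]
  delim <- if (lengths(regmatches(lines[1], gregexpr(";", lines[1]))) >
               lengths(regmatches(lines[1], gregexpr(",", lines[1])))) ";" else ","
  split1 <- function(x) {
    nf <- lengths(regmatches(x, gregexpr(delim, x, fixed = TRUE))) + 1L
    out <- strsplit(x, delim, fixed = TRUE)[[1]]
    length(out) <- nf
    out[is.na(out)] <- ""
    out
  }
  header <- trimws(split1(lines[1]))
  body <- lines[-1]
  m <- matrix(NA_character_, nrow = length(body), ncol = length(header),
              dimnames = list(NULL, header))
  for (i in seq_along(body)) {
    f <- trimws(split1(body[i]))
    m[i, ] <- ifelse(nzchar(f), substr(f, 1, 1), NA_character_)
  }
  m
}

naive_eq <- function(cells, column, values) {
  v <- cells[, column]
  !is.na(v) & v %in% values
}

# clauses: list of clauses, each a list of list(column=, values=) slots
naive_eval <- function(cells, clauses) {
  acc <- rep(TRUE, nrow(cells))
  for (cl in clauses) {
    cv <- rep(FALSE, nrow(cells))
    for (slot in cl) cv <- cv | naive_eq(cells, slot$column, slot$values)
    acc <- acc & cv
  }
  acc
}

naive_metrics <- function(lhs, rhs) {
  n <- length(lhs)
  s <- sum(lhs & rhs); ls <- sum(lhs); rs <- sum(rhs)
  list(support = s, lhs_support = ls, rhs_support = rs,
       confidence = s / ls, lift = s * n / (ls * rs),
       leverage = s / n - (ls / n) * (rs / n))
}

naive_render_slot <- function(slot) {
  paste0(slot$column, "=", paste(sort(slot$values, method = "radix"), collapse = ""))
}

naive_render <- function(clauses, rhs) {
  cl_txt <- vapply(clauses, function(cl) {
    parts <- vapply(cl, naive_render_slot, character(1))
    if (length(parts) == 1) parts else
      paste0("(", paste(parts, collapse = " OR "), ")")
  }, character(1))
  paste0(paste(cl_txt, collapse = " AND "), " -> ", naive_render_slot(rhs))
}

# all admissible value sets of one column, with their canonical sort keys
naive_candidates <- function(cells, max_set_size) {
  out <- list()
  for (j in seq_len(ncol(cells))) {
    nm <- colnames(cells)[j]
    dom <- sort(unique(cells[, j][!is.na(cells[, j])]), method = "radix")
    k <- length(dom)
    if (k == 0) next
    for (size in seq_len(min(max_set_size, k))) {
      if (size == k && k >= 2) next
      for (vals in utils::combn(dom, size, simplify = FALSE)) {
        out[[length(out) + 1]] <- list(
          column = nm, col_idx = j, values = vals,
          vec = naive_eq(cells, nm, vals),
          key = sprintf("%04d|%02d|%s", j, size, paste(vals, collapse = "")))
      }
    }
  }
  out
}

# Exhaustive-then-filter miner: every ordered filling of the clause
# structure (distinct columns within a clause), canonicalized by sorting
# and de-duplicated by rule text, with no pruning anywhere.
naive_mine <- function(csv, clause_sizes, cfg) {
  cells <- naive_cells(csv)
  cands <- naive_candidates(cells, cfg$max_value_set_size)
  rhs_cands <- Filter(function(c) length(c$values) == 1, cands)
  if (!is.null(cfg$rhs_columns)) {
    rhs_cands <- Filter(function(c) c$column %in% cfg$rhs_columns, rhs_cands)
  }
  rows <- list()
  for (rhs in rhs_cands) {
    lhs_pool <- Filter(function(c) c$column != rhs$column, cands)
    if (!is.null(cfg$lhs_columns)) {
      lhs_pool <- Filter(function(c) c$column %in% cfg$lhs_columns, lhs_pool)
    }
    if (length(lhs_pool) == 0) next
    lhs_pool <- lhs_pool[order(vapply(lhs_pool, `[[`, character(1), "key"),
                               method = "radix")]
    # within a clause, slots are an (unordered) set of candidates with
    # pairwise distinct columns; enumerate each clause as a combination in
    # key order (a pure counting device — no search-space pruning happens)
    # each filling carries its slots (already in key order because the pool
    # is key-sorted and enumeration is by increasing index), the OR of its
    # slot vectors, its key tuple, and its rendered text
    clause_fillings <- lapply(clause_sizes, function(sz) {
      acc <- list()
      pick <- function(start, chosen) {
        if (length(chosen) == sz) {
          vec <- chosen[[1]]$vec
          for (s in chosen[-1]) vec <- vec | s$vec
          parts <- vapply(chosen, naive_render_slot, character(1))
          txt <- if (length(parts) == 1) parts else
            paste0("(", paste(parts, collapse = " OR "), ")")
          acc[[length(acc) + 1]] <<- list(
            vec = vec,
            tup = paste(vapply(chosen, `[[`, character(1), "key"),
                        collapse = "~"),
            txt = txt)
          return(invisible())
        }
        if (start > length(lhs_pool)) return(invisible())
        for (k in start:length(lhs_pool)) {
          c_ <- lhs_pool[[k]]
          if (c_$col_idx %in% vapply(chosen, `[[`, numeric(1), "col_idx")) next
          pick(k + 1, c(chosen, list(c_)))
        }
        invisible()
      }
      pick(1, list())
      acc
    })
    rhs_txt <- naive_render_slot(rhs)
    n_cl <- length(clause_sizes)
    leaf <- function(chosen) {
      # canonical order inside runs of equal-size adjacent clauses
      if (n_cl > 1) {
        i <- 1
        while (i <= n_cl) {
          j <- i
          while (j < n_cl && clause_sizes[j + 1] == clause_sizes[i]) j <- j + 1
          if (j > i) {
            run <- chosen[i:j]
            chosen[i:j] <- run[order(vapply(run, `[[`, character(1), "tup"),
                                     method = "radix")]
          }
          i <- j + 1
        }
      }
      lhs_vec <- chosen[[1]]$vec
      for (f in chosen[-1]) lhs_vec <- lhs_vec & f$vec
      m <- naive_metrics(lhs_vec, rhs$vec)
      if (m$lhs_support == 0 || m$rhs_support == 0) return(invisible())
      if (m$support < cfg$min_support || m$confidence < cfg$min_confidence ||
          m$lift < cfg$min_lift || m$leverage < cfg$min_leverage) return(invisible())
      txt <- paste0(paste(vapply(chosen, `[[`, character(1), "txt"),
                          collapse = " AND "), " -> ", rhs_txt)
      if (is.null(rows[[txt]])) {
        rows[[txt]] <<- c(list(rule = txt), m)
      }
      invisible()
    }
    # cartesian product over the clauses' fillings
    product <- function(ci, chosen) {
      if (ci > n_cl) {
        leaf(chosen)
        return(invisible())
      }
      for (f in clause_fillings[[ci]]) product(ci + 1, c(chosen, list(f)))
      invisible()
    }
    if (all(lengths(clause_fillings) > 0)) product(1, list())
  }
  rows <- unname(rows)
  out <- data.frame(
    rule = vapply(rows, `[[`, character(1), "rule"),
    support = as.integer(vapply(rows, `[[`, numeric(1), "support")),
    lhs_support = as.integer(vapply(rows, `[[`, numeric(1), "lhs_support")),
    rhs_support = as.integer(vapply(rows, `[[`, numeric(1), "rhs_support")),
    confidence = vapply(rows, `[[`, numeric(1), "confidence"),
    lift = vapply(rows, `[[`, numeric(1), "lift"),
    leverage = vapply(rows, `[[`, numeric(1), "leverage"),
    stringsAsFactors = FALSE)
  out[order(out$rule, method = "radix"), , drop = FALSE]
}

naive_cfg <- function(min_support = 1, min_confidence = 0, min_lift = 0,
                      min_leverage = -0.25, max_value_set_size = 2,
                      lhs_columns = NULL, rhs_columns = NULL) {
  list(min_support = min_support, min_confidence = min_confidence,
       min_lift = min_lift, min_leverage = min_leverage,
       max_value_set_size = max_value_set_size,
       lhs_columns = lhs_columns, rhs_columns = rhs_columns)
}
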