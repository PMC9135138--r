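test_that("elementary equalities enumerate canonically and drop the full domain", {
  tab <- gar_read_table(text = "p,q,r\nA,y,A\nB,y,B\nA,y,C\n")
  expect_identical(gar_enumerate_equalities(tab, "p", 2), list("A", "B"))
  expect_identical(gar_enumerate_equalities(tab, "q", 2), list("y"))
  expect_identical(gar_enumerate_equalities(tab, "r", 2),
                   list("A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C")))
  # brute subset check on a wider domain
  tab2 <- gar_read_table(text = "s\na\nb\nc\nd\n")
  got <- gar_enumerate_equalities(tab2, "s", 3)
  all_subsets <- unlist(lapply(1:3, function(k)
    utils::combn(letters[1:4], k, simplify = FALSE)), recursive = FALSE)
  expect_setequal(vapply(got, paste, character(1), collapse = ""),
                  vapply(all_subsets, paste, character(1), collapse = ""))
})

test_that("the support bound is the assigned-clause intersection with the RHS", {
  fix <- make_planted(5)
  tab <- fix$table
  rhs <- fix$rule$rhs
  # no clause assigned: the bound is the RHS support
  expect_identical(gar_support_upper_bound(tab, list(), rhs),
                   gar_rule_metrics(tab, fix$rule)$rhs_support)
  # all clauses assigned: the bound is the exact support
  expect_identical(gar_support_upper_bound(tab, fix$rule$lhs, rhs),
                   gar_rule_metrics(tab, fix$rule)$support)
})

test_that("the bound never underestimates the support of any completion", {
  n_checked <- 0
  for (seed in 1:25) {
    csv <- random_table_csv(seed, n_cols = sample(3:6, 1), n_vals = 3,
                            n_rows = 32)
    tab <- gar_read_table(text = csv)
    cells <- naive_cells(csv)
    withr::with_seed(seed + 77, {
      for (rep in 1:4) {
        full <- random_filled_rule(csv, sample.int(10000, 1),
                                   clause_sizes = c(1, 2))
        # partial assignment: first clause assigned, second still blank
        partial <- full$clauses[1]
        bound <- gar_support_upper_bound(tab, partial, full$rhs)
        exact <- sum(naive_eval(cells, full$clauses) &
                       naive_eq(cells, full$rhs$column, full$rhs$values))
        expect_gte(bound, exact)
        n_checked <- n_checked + 1
      }
    })
  }
  expect_gte(n_checked, 100)
})

test_that("pattern filling matches exhaustive enumeration on small tables", {
  for (seed in c(1, 8, 21)) {
    csv <- random_table_csv(seed, n_cols = 4, n_vals = 3, n_rows = 40)
    res <- gar_mine(gar_read_table(text = csv), "_ AND (_ OR _) -> _",
                    min_support = 4, min_confidence = 0.5, simplify = FALSE)
    oracle <- naive_mine(csv, c(1, 2),
                         naive_cfg(min_support = 4, min_confidence = 0.5))
    got <- mine_to_sorted_df(res)
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("unsatisfiable thresholds yield no rules", {
  fix <- make_planted(3)
  res <- gar_mine(fix$table, "_ -> _", min_support = fix$table$n_rows + 1)
  expect_identical(nrow(tidy(res)), 0L)
})

test_that("mined rules never repeat and never mention the RHS column on the LHS", {
  fix <- make_planted(9)
  res <- gar_mine(fix$table, "_ AND (_ OR _) -> _", min_support = 10,
                  min_confidence = 0.3)
  tb <- tidy(res)
  expect_false(any(duplicated(tb$rule)))
  for (txt in tb$rule) {
    r <- gar_parse_rule(txt)
    lhs_cols <- vapply(unlist(r$lhs, recursive = FALSE), `[[`,
                       character(1), "column")
    expect_false(r$rhs$column %in% lhs_cols)
    for (cl in r$lhs) {
      expect_false(anyDuplicated(vapply(cl, `[[`, character(1), "column")) > 0)
    }
  }
})

test_that("a redundant conjunct is deleted and tolerance zero is the identity", {
  # y=b holds everywhere, so the clause is uninformative: removal keeps lift
  csv <- paste0("x,y,z\n",
                paste(rep(c("a,b,c", "d,b,e"), c(6, 6)), collapse = "\n"),
                "\n")
  tab <- gar_read_table(text = csv)
  s <- gar_simplify(tab, "x=a AND y=b -> z=c", gar_config(min_support = 1))
  expect_identical(gar_render_rule(s$rule), "x=a -> z=c")
  expect_true(s$changed)
  expect_identical(s$original, "x=a AND y=b -> z=c")
  # strictly informative clauses at tolerance zero stay put
  fix <- make_planted(13)
  e <- fix$expected
  s2 <- gar_simplify(fix$table, fix$rule,
                     gar_config(min_support = ceiling(0.9 * e$support),
                                min_confidence = 0.9 * e$confidence),
                     tolerance = 0)
  expect_false(s2$changed)
  expect_identical(gar_render_rule(s2$rule), fix$rule_text)
})

test_that("a noise clause is dropped and lift stays within tolerance", {
  for (seed in c(4, 14, 24)) {
    fix <- make_planted(seed)
    # make the noise column cover every LHS row, so the appended clause is
    # uninformative by construction and its known lift change is zero
    cells <- fix$cells
    lhs_rows <- naive_eval(cells, fix$rule$lhs)
    cells[lhs_rows, "n1"] <- "p"
    csv <- paste0(paste(c(paste(colnames(cells), collapse = ","),
                          apply(cells, 1, paste, collapse = ",")),
                        collapse = "\n"), "\n")
    tab <- gar_read_table(text = csv)
    padded <- fix$rule
    padded$lhs <- c(padded$lhs, list(list(list(column = "n1", values = "p"))))
    mp <- gar_rule_metrics(tab, padded)
    e <- fix$expected
    s <- gar_simplify(tab, padded,
                      gar_config(min_support = ceiling(0.9 * e$support),
                                 min_confidence = 0.9 * e$confidence))
    expect_identical(gar_render_rule(s$rule), fix$rule_text)
    expect_gte(s$metrics$lift, 0.98 * mp$lift)
  }
})

test_that("every simplified rule keeps at least 98 percent of its original lift", {
  fix <- make_planted(31)
  res <- gar_mine(fix$table, "_ AND (_ OR _) -> _", min_support = 10,
                  min_confidence = 0.3, rhs_columns = "w")
  tb <- tidy(res)
  expect_true(nrow(tb) > 0)
  changed <- !is.na(tb$simplified_from)
  expect_true(any(changed))
  expect_true(all(tb$lift >= (1 - 0.02) * tb$lift_pre_simplify - 1e-12))
})

test_that("the planted generalized rule is recovered and ranked first", {
  fix <- make_planted(1)
  e <- fix$expected
  res <- gar_mine(fix$table, "_ AND (_ OR _) -> _",
                  min_support = ceiling(0.9 * e$support),
                  min_confidence = 0.9 * e$confidence,
                  min_lift = 0.9 * e$lift,
                  min_leverage = 0.9 * e$leverage)
  tb <- tidy(res)
  expect_identical(tb$rule[1], fix$rule_text)
  expect_identical(tb$support[1], e$support)
  expect_identical(tb$lift[1], e$lift)
})

test_that("the job partition has one job per permitted RHS equality", {
  fix <- make_planted(6)
  res <- gar_mine(fix$table, "_ -> _", min_support = 5, rhs_columns = "w")
  # w has two observed values -> two singleton RHS assignments
  expect_identical(res$n_jobs, 2L)
  res_all <- gar_mine(fix$table, "_ -> _", min_support = 5)
  n_expected <- sum(vapply(fix$table$columns$index, function(j)
    length(gar_enumerate_equalities(fix$table, j, 1)), integer(1)))
  expect_identical(res_all$n_jobs, as.integer(n_expected))
})

test_that("output is invariant to jobs, row order and repetition", {
  fix <- make_planted(8)
  base <- gar_mine(fix$table, "_ AND (_ OR _) -> _", min_support = 40,
                   min_confidence = 0.5, jobs = 1)
  again <- gar_mine(fix$table, "_ AND (_ OR _) -> _", min_support = 40,
                    min_confidence = 0.5, jobs = 8)
  expect_identical(gar_write_txt(base), gar_write_txt(again))
  # permute rows: identical rules and metrics
  cells <- fix$cells[rev(seq_len(nrow(fix$cells))), ]
  csv <- paste0(paste(c(paste(colnames(cells), collapse = ","),
                        apply(cells, 1, paste, collapse = ",")),
                      collapse = "\n"), "\n")
  perm <- gar_mine(gar_read_table(text = csv, name = fix$table$name),
                   "_ AND (_ OR _) -> _", min_support = 40,
                   min_confidence = 0.5)
  expect_identical(gar_write_txt(perm), gar_write_txt(base))
})

test_that("rules identical after simplification are reported once", {
  # two different candidates both simplify to x=a -> z=c on this table
  csv <- paste0("x,y,z\n",
                paste(rep(c("a,b,c", "a,u,c", "d,b,e", "d,u,e"),
                          c(4, 4, 4, 4)), collapse = "\n"), "\n")
  tab <- gar_read_table(text = csv)
  res <- gar_mine(tab, "_ AND _ -> _", min_support = 2, min_confidence = 0.5,
                  rhs_columns = "z")
  tb <- tidy(res)
  expect_false(any(duplicated(tb$rule)))
})

test_that("configuration contracts are enforced", {
  expect_error(gar_config(min_support = 0), class = "gar_config_error")
  expect_error(gar_config(min_confidence = 1.5), class = "gar_config_error")
  expect_error(gar_config(simplify_tolerance = 1), class = "gar_config_error")
  fix <- make_planted(2)
  expect_error(gar_mine(fix$table, "_ -> _", rhs_columns = character()),
               class = "gar_config_error")
})
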