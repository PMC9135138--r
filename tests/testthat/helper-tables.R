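# Seeded random tables and rules for property tests.

random_table_csv <- function(seed, n_cols = NULL, n_vals = NULL,
                             n_rows = NULL, na_rate = 0.1) {
  withr::with_seed(seed, {
    if (is.null(n_cols)) n_cols <- sample(2:6, 1)
    if (is.null(n_vals)) n_vals <- sample(2:4, 1)
    if (is.null(n_rows)) n_rows <- sample(8:64, 1)
    vals <- letters[seq_len(n_vals)]
    header <- paste0("c", seq_len(n_cols))
    cells <- matrix(sample(vals, n_rows * n_cols, replace = TRUE), n_rows)
    cells[matrix(stats::runif(n_rows * n_cols) < na_rate, n_rows)] <- ""
    paste0(paste(c(paste(header, collapse = ","),
                   apply(cells, 1, paste, collapse = ",")), collapse = "\n"),
           "\n")
  })
}

# a random fully filled rule drawn from a table's observed domains;
# clauses have pairwise distinct columns, the RHS column is fresh
random_filled_rule <- function(csv, seed, clause_sizes = c(1, 2)) {
  cells <- naive_cells(csv)
  withr::with_seed(seed, {
    doms <- lapply(seq_len(ncol(cells)), function(j)
      sort(unique(cells[, j][!is.na(cells[, j])])))
    usable <- which(lengths(doms) > 0)
    stopifnot(length(usable) >= 2)
    rhs_col <- usable[sample.int(length(usable), 1)]
    lhs_cols <- setdiff(usable, rhs_col)
    clauses <- lapply(clause_sizes, function(sz) {
      sz <- min(sz, length(lhs_cols))
      cols <- lhs_cols[sample.int(length(lhs_cols), sz)]
      lapply(cols, function(j) {
        dom <- doms[[j]]
        k <- max(1, min(length(dom), sample(1:2, 1)))
        if (k == length(dom) && k >= 2) k <- k - 1
        list(column = colnames(cells)[j], values = sort(sample(dom, k)))
      })
    })
    rhs <- list(column = colnames(cells)[rhs_col],
                values = sample(doms[[rhs_col]], 1))
    list(clauses = clauses, rhs = rhs)
  })
}

# standard planted fixture used across miner/acceptance tests:
# x=a AND (y=b OR z=c) -> w=y with exactly realized counts
make_planted <- function(seed, n_rows = 200) {
  spec <- gar_planted_spec(
    lhs = list(
      list(list(column = "x", values = "a")),
      list(list(column = "y", values = "b"), list(column = "z", values = "c"))
    ),
    rhs = list(column = "w", value = "y"),
    coverage = 0.4, confidence = 0.9, background = 0.1,
    n_rows = n_rows, seed = seed)
  gar_generate_table(spec)
}

mine_to_sorted_df <- function(res) {
  tb <- as.data.frame(tidy(res)[, c("rule", "support", "lhs_support",
                                    "rhs_support", "confidence", "lift",
                                    "leverage")])
  tb[order(tb$rule, method = "radix"), , drop = FALSE]
}
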