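# Seeded synthetic tables with planted generalized rules.
#
# The generator realizes the planted rule's counts exactly by construction
# (no sampling noise on the metrics): ceiling(coverage * n) rows satisfy the
# LHS, of which ceiling(confidence * coverage * n) satisfy the RHS, and the
# remaining rows satisfy the RHS at exactly the background rate. Every other
# degree of freedom (which disjunct carries a row, which rows are RHS
# positive, noise cells, row order) comes from one pseudo-random stream
# keyed by the seed, so a fixture is byte-identical across runs.
#
# The construction keeps every planted clause informative: each non-LHS row
# falsifies exactly one clause (round-robin), so deleting any conjunct
# admits its own block of background rows; and each disjunct of a multi-slot
# clause is the unique satisfier for its round-robin share of LHS rows, so
# deleting a disjunct loses that share of the support.

#' Specify a planted generalized rule fixture
#'
#' @param lhs List of clauses; each clause a list of
#'   `list(column = <name>, values = <chr vector>)` equalities. Columns must
#'   be distinct across the whole LHS.
#' @param rhs `list(column = <name>, value = <single char>)`.
#' @param coverage Fraction of rows satisfying the LHS, in (0, 1).
#' @param confidence Fraction of LHS rows also satisfying the RHS.
#' @param background RHS rate among non-LHS rows, in `[0, 1]`.
#' @param n_rows Number of rows.
#' @param seed Integer seed of the fixture's random stream.
#' @param n_noise_cols Number of unrelated noise columns.
#' @param noise_values Value alphabet of the noise columns.
#' @return A `gar_planted_spec` list. `coverage * n_rows`,
#'   `confidence * coverage * n_rows` and
#'   `background * (1 - coverage) * n_rows` must all be whole numbers, so
#'   the expected metrics are exact, or the spec is rejected.
#' @export
gar_planted_spec <- function(lhs, rhs, coverage, confidence, background,
                             n_rows, seed, n_noise_cols = 2L,
                             noise_values = c("p", "q", "r", "s")) {
  stopifnot(coverage > 0, coverage < 1, confidence >= 0, confidence <= 1,
            background >= 0, background <= 1, n_rows >= 4)
  is_whole <- function(x) abs(x - round(x)) < 1e-9
  n_lhs <- coverage * n_rows
  if (!is_whole(n_lhs)) {
    rlang::abort("coverage * n_rows is not a whole number", class = "gar_spec_error")
  }
  n_both <- confidence * n_lhs
  if (!is_whole(n_both)) {
    rlang::abort("confidence * coverage * n_rows is not a whole number",
                 class = "gar_spec_error")
  }
  n_bg <- background * (n_rows - round(n_lhs))
  if (!is_whole(n_bg)) {
    rlang::abort("background * (1 - coverage) * n_rows is not a whole number",
                 class = "gar_spec_error")
  }
  lhs_cols <- unlist(lapply(lhs, function(cl) vapply(cl, `[[`, character(1), "column")))
  if (anyDuplicated(c(lhs_cols, rhs$column))) {
    rlang::abort("planted columns must be distinct", class = "gar_spec_error")
  }
  structure(list(
    lhs = lhs, rhs = rhs, coverage = coverage, confidence = confidence,
    background = background, n_rows = as.integer(n_rows),
    seed = as.integer(seed), n_noise_cols = as.integer(n_noise_cols),
    noise_values = noise_values,
    n_lhs = as.integer(round(n_lhs)), n_both = as.integer(round(n_both)),
    n_bg = as.integer(round(n_bg))
  ), class = "gar_planted_spec")
}

# pick a decoy character not among `taken`
pick_decoy <- function(taken) {
  pool <- c(letters, LETTERS, as.character(0:9))
  pool[!pool %in% taken][1]
}

#' Generate a table realizing a planted rule exactly
#'
#' @param spec A [gar_planted_spec()].
#' @return A list with `csv` (the table in the package's CSV dialect),
#'   `table` (the parsed `gar_table`), `cells` (character matrix),
#'   `rule` (the planted `gar_rule`), `rule_text`, and `expected` — the
#'   planted rule's exact metrics (support, lhs_support, rhs_support,
#'   confidence, lift, leverage), which the engine reproduces exactly.
#' @examples
#' spec <- gar_planted_spec(
#'   lhs = list(list(list(column = "x", values = "a"))),
#'   rhs = list(column = "y", value = "b"),
#'   coverage = 0.4, confidence = 0.75, background = 0.25,
#'   n_rows = 100, seed = 1)
#' fix <- gar_generate_table(spec)
#' fix$expected$lift
#' @export
gar_generate_table <- function(spec) {
  stopifnot(inherits(spec, "gar_planted_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  n <- spec$n_rows
  n_lhs <- spec$n_lhs
  n_rest <- n - n_lhs
  clauses <- spec$lhs
  n_clauses <- length(clauses)

  cols <- character()
  for (cl in clauses) cols <- c(cols, vapply(cl, `[[`, character(1), "column"))
  cols <- c(cols, spec$rhs$column)
  noise_names <- paste0("n", seq_len(spec$n_noise_cols))
  if (any(noise_names %in% cols)) {
    noise_names <- paste0("noise", seq_len(spec$n_noise_cols))
  }
  header <- c(cols, noise_names)
  cells <- matrix(NA_character_, nrow = n, ncol = length(header),
                  dimnames = list(NULL, header))

  decoys <- list()
  for (cl in clauses) {
    for (eq in cl) decoys[[eq$column]] <- pick_decoy(eq$values)
  }
  rhs_decoy <- pick_decoy(spec$rhs$value)

  lhs_rows <- seq_len(n_lhs)
  rest_rows <- seq.int(n_lhs + 1L, length.out = n_rest)

  # planted clause columns
  fill_clause_satisfied <- function(row, cl, pick) {
    k <- length(cl)
    d <- ((pick - 1L) %% k) + 1L
    for (s in seq_len(k)) {
      eq <- cl[[s]]
      cells[row, eq$column] <<- if (s == d) {
        if (length(eq$values) == 1L) eq$values else sample(eq$values, 1L)
      } else decoys[[eq$column]]
    }
  }
  for (i in lhs_rows) {
    for (cl in clauses) fill_clause_satisfied(i, cl, i)
  }
  for (j in seq_along(rest_rows)) {
    row <- rest_rows[j]
    fals <- ((j - 1L) %% n_clauses) + 1L
    for (ci in seq_len(n_clauses)) {
      cl <- clauses[[ci]]
      if (ci == fals) {
        for (eq in cl) cells[row, eq$column] <- decoys[[eq$column]]
      } else {
        fill_clause_satisfied(row, cl, j)
      }
    }
  }

  # RHS column: exact positive counts on both sides
  rhs_col <- spec$rhs$column
  cells[, rhs_col] <- rhs_decoy
  pos_lhs <- if (spec$n_both > 0L)
    lhs_rows[sample.int(length(lhs_rows), spec$n_both)] else integer()
  pos_bg <- if (spec$n_bg > 0L)
    rest_rows[sample.int(length(rest_rows), spec$n_bg)] else integer()
  cells[c(pos_lhs, pos_bg), rhs_col] <- spec$rhs$value

  # noise columns
  for (nm in noise_names) {
    cells[, nm] <- sample(spec$noise_values, n, replace = TRUE)
  }

  cells <- cells[sample.int(n), , drop = FALSE]

  csv <- paste0(paste(c(
    paste(header, collapse = ","),
    apply(cells, 1L, paste, collapse = ",")
  ), collapse = "\n"), "\n")

  rhs_support <- spec$n_both + spec$n_bg
  expected <- list(
    support = spec$n_both,
    lhs_support = n_lhs,
    rhs_support = rhs_support,
    confidence = spec$n_both / n_lhs,
    lift = (spec$n_both * n) / (n_lhs * rhs_support),
    leverage = spec$n_both / n - (n_lhs / n) * (rhs_support / n)
  )
  rule <- structure(list(
    lhs = lapply(clauses, function(cl) lapply(cl, function(eq) {
      slot_eq(eq$column, eq$values)
    })),
    rhs = slot_eq(spec$rhs$column, spec$rhs$value)
  ), class = "gar_rule")

  list(csv = csv,
       table = gar_read_table(text = csv, name = sprintf("planted-%d", spec$seed)),
       cells = cells,
       rule = rule,
       rule_text = gar_render_rule(rule),
       expected = expected,
       spec = spec)
}

#' Blank noise cells of a fixture to exercise missing-value handling
#'
#' Each noise-column cell is independently replaced by an empty field with
#' probability `na_rate`; planted-rule cells are never touched, so the
#' fixture's expected metrics continue to hold exactly.
#'
#' @param fixture A [gar_generate_table()] result.
#' @param na_rate Blanking probability in `[0, 1)`.
#' @param seed Seed of the blanking stream.
#' @return A list like the input fixture with updated `csv`, `table` and
#'   `cells`.
#' @export
gar_generate_na_noise <- function(fixture, na_rate, seed) {
  stopifnot(na_rate >= 0, na_rate < 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  cells <- fixture$cells
  spec <- fixture$spec
  planted <- c(unlist(lapply(spec$lhs, function(cl)
    vapply(cl, `[[`, character(1), "column"))), spec$rhs$column)
  noise_cols <- setdiff(colnames(cells), planted)
  for (nm in noise_cols) {
    blank <- stats::runif(nrow(cells)) < na_rate
    cells[blank, nm] <- NA_character_
  }
  out_cells <- cells
  out_cells[is.na(out_cells)] <- ""
  csv <- paste0(paste(c(
    paste(colnames(cells), collapse = ","),
    apply(out_cells, 1L, paste, collapse = ",")
  ), collapse = "\n"), "\n")
  fixture$csv <- csv
  fixture$cells <- cells
  fixture$table <- gar_read_table(text = csv,
                                  name = sprintf("planted-%d-na", spec$seed))
  fixture
}
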