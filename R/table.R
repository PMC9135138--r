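#' Read a categorical rule-mining table from a CSV file
#'
#' Reads the single-character categorical CSV dialect used throughout the
#' package: the first line is a header with column names, every following
#' line is one record, fields are separated by commas or semicolons
#' (whichever occurs more often in the header), each cell is reduced to a
#' single printable ASCII character, and an empty (or whitespace-only) cell
#' is a missing value (N/A). Different characters are different values and
#' comparison is case-sensitive.
#'
#' Cells are whitespace-stripped first and then truncated to their first
#' character, so `"yes"` becomes `"y"` and `"  A "` becomes `"A"`. A missing
#' value satisfies no elementary equality. There is no quoting: a cell that
#' legitimately holds one character can never contain a delimiter.
#'
#' @param file Path to a CSV file.
#' @param text A character string (or vector of lines) holding CSV content,
#'   as an alternative to `file`.
#' @param name Display name for the input recorded in reports; defaults to
#'   the file name or `"<text>"`.
#' @return A `gar_table` object: a list with `columns` (a tibble with one
#'   row per column: `name`, `index` (1-based), `domain` (list-column of
#'   observed value characters, missing excluded), `na_count`), `n_rows`,
#'   and an internal per-(column, value) row-set index used by the
#'   evaluation engine.
#' @examples
#' tab <- gar_read_table(text = "x,y\na,b\na,\nc,b\n")
#' tab$n_rows
#' tab$columns
#' @export
gar_read_table <- function(file = NULL, text = NULL, name = NULL) {
  if (is.null(file) == is.null(text)) {
    rlang::abort("supply exactly one of `file` or `text`")
  }
  if (!is.null(file)) {
    if (!file.exists(file)) {
      rlang::abort(paste0("input file not found: ", file))
    }
    lines <- readLines(file, warn = FALSE)
    if (is.null(name)) name <- basename(file)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(name)) name <- "<text>"
  }
  gar_parse_table(lines, name = name)
}

#' Choose the field delimiter from a header line
#'
#' The dialect allows comma- or semicolon-separated files; the delimiter is
#' the one occurring more often in the header line (ties go to the comma).
#'
#' @param first_line The header line as a single string.
#' @return `","` or `";"`.
#' @examples
#' gar_detect_delimiter("age;bread;butter")
#' gar_detect_delimiter("a,b;c;d")
#' @export
gar_detect_delimiter <- function(first_line) {
  stopifnot(is.character(first_line), length(first_line) == 1L, nzchar(first_line))
  n_semi <- lengths(gregexpr(";", first_line, fixed = TRUE))
  n_comma <- lengths(gregexpr(",", first_line, fixed = TRUE))
  if (length(grep(";", first_line, fixed = TRUE)) == 0L) n_semi <- 0L
  if (length(grep(",", first_line, fixed = TRUE)) == 0L) n_comma <- 0L
  if (n_semi > n_comma) ";" else ","
}

# Split one record on the raw delimiter, keeping trailing empty fields
# (strsplit drops them, which would miscount "a,b," as two fields).
split_fields <- function(line, delim) {
  n_fields <- lengths(gregexpr(delim, line, fixed = TRUE))
  if (length(grep(delim, line, fixed = TRUE)) == 0L) n_fields <- 0L
  n_fields <- n_fields + 1L
  out <- strsplit(line, delim, fixed = TRUE)[[1]]
  length(out) <- n_fields
  out[is.na(out)] <- ""
  out
}

#' Normalize one raw cell to a value character or missing
#'
#' Strips surrounding whitespace; an empty result is missing (`NA`);
#' otherwise the first character is the value. The character must be
#' printable ASCII.
#'
#' @param raw Character vector of raw cell contents.
#' @return Character vector of single characters, `NA` for missing cells.
#' @examples
#' gar_normalize_cell(c("", "yes", "  A "))
#' @export
gar_normalize_cell <- function(raw) {
  x <- trimws(raw)
  out <- ifelse(nzchar(x), substr(x, 1L, 1L), NA_character_)
  bad <- !is.na(out) & !grepl("^[\x21-\x7e]$", out)
  if (any(bad)) {
    rlang::abort(paste0(
      "cell value is not printable ASCII: ",
      paste0("'", out[bad][1], "'")
    ), class = "gar_format_error")
  }
  out
}

#' Parse table lines into an indexed `gar_table`
#'
#' @param lines Character vector: header line followed by record lines.
#' @param name Display name recorded on the table.
#' @return A `gar_table`; see [gar_read_table()].
#' @export
gar_parse_table <- function(lines, name = "<text>") {
  # drop trailing blank lines (a final newline is not an empty record)
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2L) {
    rlang::abort("table must have a header line and at least one data row",
                 class = "gar_format_error")
  }
  delim <- gar_detect_delimiter(lines[1])
  header <- trimws(split_fields(lines[1], delim))
  if (any(!nzchar(header))) {
    rlang::abort("empty column name in header", class = "gar_format_error")
  }
  if (anyDuplicated(header)) {
    rlang::abort(paste0("duplicate column name in header: ",
                        header[duplicated(header)][1]),
                 class = "gar_format_error")
  }
  n_cols <- length(header)
  body <- lines[-1]
  n_rows <- length(body)
  cells <- matrix(NA_character_, nrow = n_rows, ncol = n_cols,
                  dimnames = list(NULL, header))
  for (i in seq_len(n_rows)) {
    f <- split_fields(body[i], delim)
    if (length(f) != n_cols) {
      rlang::abort(sprintf(
        "line %d has %d fields but the header has %d",
        i + 1L, length(f), n_cols), class = "gar_format_error")
    }
    x <- trimws(f)
    v <- ifelse(nzchar(x), substr(x, 1L, 1L), NA_character_)
    bad <- !is.na(v) & !grepl("^[\x21-\x7e]$", v)
    if (any(bad)) {
      k <- which(bad)[1]
      rlang::abort(sprintf(
        "cell value is not printable ASCII at line %d, column '%s'",
        i + 1L, header[k]), class = "gar_format_error")
    }
    cells[i, ] <- v
  }
  gar_table_from_cells(cells, name = name, delim = delim)
}

# Build the indexed table from a normalized character matrix (NA = missing).
gar_table_from_cells <- function(cells, name = "<cells>", delim = ",") {
  header <- colnames(cells)
  n_rows <- nrow(cells)
  n_cols <- ncol(cells)
  index <- vector("list", n_cols)
  domain <- vector("list", n_cols)
  na_count <- integer(n_cols)
  for (j in seq_len(n_cols)) {
    v <- cells[, j]
    na_count[j] <- sum(is.na(v))
    vals <- sort(unique(v[!is.na(v)]), method = "radix")
    domain[[j]] <- vals
    idx <- vector("list", length(vals))
    names(idx) <- vals
    for (val in vals) {
      idx[[val]] <- rowset_from_logical(!is.na(v) & v == val)
    }
    index[[j]] <- idx
  }
  structure(list(
    columns = tibble::tibble(
      name = header,
      index = seq_len(n_cols),
      domain = domain,
      na_count = na_count
    ),
    n_rows = n_rows,
    index = index,
    name = name,
    delim = delim
  ), class = "gar_table")
}

#' @export
print.gar_table <- function(x, ...) {
  cat(sprintf("<gar_table> %s: %d rows x %d columns\n",
              x$name, x$n_rows, nrow(x$columns)))
  print(x$columns)
  invisible(x)
}

#' Serialize a parsed table back to its CSV dialect
#'
#' Reconstructs cell values from the row-set index (missing cells become
#' empty fields) and writes the table in the same dialect it was read from.
#' Parsing the output again yields an identical index.
#'
#' @param table A `gar_table`.
#' @param file Optional path to write to; if `NULL` the CSV text is returned.
#' @return The CSV text as a single string, invisibly when written to a file.
#' @export
gar_write_table <- function(table, file = NULL) {
  stopifnot(inherits(table, "gar_table"))
  cells <- gar_table_cells(table)
  delim <- table$delim
  lines <- c(
    paste(colnames(cells), collapse = delim),
    apply(cells, 1L, function(r) {
      r[is.na(r)] <- ""
      paste(r, collapse = delim)
    })
  )
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Recover the cell matrix of a parsed table
#'
#' @param table A `gar_table`.
#' @return A character matrix (rows x columns) with `NA` for missing cells.
#' @export
gar_table_cells <- function(table) {
  n <- table$n_rows
  cols <- table$columns
  cells <- matrix(NA_character_, nrow = n, ncol = nrow(cols),
                  dimnames = list(NULL, cols$name))
  for (j in seq_len(nrow(cols))) {
    for (val in cols$domain[[j]]) {
      cells[rowset_members(table$index[[j]][[val]]), j] <- val
    }
  }
  cells
}

# Resolve a column given by name or index to its 1-based index.
resolve_column <- function(table, column) {
  if (is.character(column)) {
    j <- match(column, table$columns$name)
    if (is.na(j)) {
      rlang::abort(paste0("unknown column: ", column), class = "gar_contract_error")
    }
    j
  } else {
    j <- as.integer(column)
    if (is.na(j) || j < 1L || j > nrow(table$columns)) {
      rlang::abort(paste0("column index out of range: ", column),
                   class = "gar_contract_error")
    }
    j
  }
}
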