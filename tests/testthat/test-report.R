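# helper: the 100-row independence table (40/50 with overlap 20)
independence_table <- function() {
  x <- c(rep("a", 40), rep("c", 60))
  y <- c(rep("b", 20), rep("d", 20), rep("b", 30), rep("d", 30))
  gar_read_table(text = paste0("x,y\n",
                               paste(x, y, sep = ",", collapse = "\n"), "\n"),
                 name = "independence.csv")
}

test_that("the TXT report prints counts and four-decimal metrics per rule", {
  res <- gar_mine(independence_table(), "_ -> _", min_support = 20)
  lines <- gar_write_txt(res)
  header <- grep("^#", lines, value = TRUE)
  expect_true(any(grepl("^# pattern: _ -> _$", header)))
  expect_true(any(grepl("^# n_rows: 100$", header)))
  target <- grep("^x=a -> y=b\t", lines, value = TRUE)
  expect_length(target, 1)
  expect_identical(target, "x=a -> y=b\t20\t40\t50\t0.5000\t1.0000\t0.0000")
  # rule text column is exactly the canonical rendering
  body <- lines[!grepl("^#", lines)]
  expect_identical(vapply(strsplit(body, "\t", fixed = TRUE), `[[`, character(1), 1),
                   tidy(res)$rule)
})

test_that("an empty result still writes a complete header and valid XML", {
  res <- gar_mine(independence_table(), "_ -> _", min_support = 101)
  lines <- gar_write_txt(res)
  expect_true(all(grepl("^#", lines)))
  expect_true(any(grepl("^# rules: 0$", lines)))
  xml_path <- withr::local_tempfile(fileext = ".xml")
  gar_write_xml(res, xml_path)
  expect_identical(nrow(gar_read_xml(xml_path)), 0L)
})

test_that("the XML report round-trips rules and metrics to four decimals", {
  res <- gar_mine(independence_table(), "_ -> _", min_support = 20,
                  min_confidence = 0.5, min_lift = 1,
                  lhs_columns = "x", rhs_columns = "y")
  xml_path <- withr::local_tempfile(fileext = ".xml")
  gar_write_xml(res, xml_path)
  doc <- xml2::read_xml(xml_path)
  expect_identical(xml2::xml_name(doc), "rule_mining_results")
  expect_identical(
    length(xml2::xml_find_all(doc, "//rule")), nrow(tidy(res)))
  back <- gar_read_xml(xml_path)
  tb <- tidy(res)
  expect_identical(back$rule, tb$rule)
  expect_identical(back$support, tb$support)
  expect_equal(back$confidence, round(tb$confidence, 4))
  expect_equal(back$lift, round(tb$lift, 4))
  expect_equal(back$leverage, round(tb$leverage, 4))
})

test_that("TXT and XML agree on rule count, order and metrics", {
  fix <- make_planted(17)
  res <- gar_mine(fix$table, "_ AND (_ OR _) -> _", min_support = 40,
                  min_confidence = 0.5, rhs_columns = "w")
  xml_path <- withr::local_tempfile(fileext = ".xml")
  gar_write_xml(res, xml_path)
  back <- gar_read_xml(xml_path)
  lines <- gar_write_txt(res)
  body <- lines[!grepl("^#", lines)]
  expect_identical(length(body), nrow(back))
  fields <- strsplit(body, "\t", fixed = TRUE)
  expect_identical(vapply(fields, `[[`, character(1), 1), back$rule)
  expect_identical(vapply(fields, function(f) as.integer(f[2]), integer(1)),
                   back$support)
  expect_identical(vapply(fields, `[[`, character(1), 6),
                   sprintf("%.4f", back$lift))
})

test_that("the CLI mines a table and writes both reports", {
  csv_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(make_planted(25)$csv, csv_path, sep = "")
  txt_path <- withr::local_tempfile(fileext = ".txt")
  xml_path <- withr::local_tempfile(fileext = ".xml")
  status <- suppressMessages(gar_run_cli(c(
    "--in", csv_path, "--pattern", "_ AND (_ OR _) -> _",
    "--min-support", "40", "--min-confidence", "0.5",
    "--rhs-columns", "w",
    "--txt", txt_path, "--xml", xml_path, "--log-level", "quiet")))
  expect_identical(status, 0L)
  expect_true(file.exists(txt_path) && file.exists(xml_path))
  lines1 <- readLines(txt_path)
  # a second identical run is byte-identical
  status2 <- suppressMessages(gar_run_cli(c(
    "--in", csv_path, "--pattern", "_ AND (_ OR _) -> _",
    "--min-support", "40", "--min-confidence", "0.5",
    "--rhs-columns", "w",
    "--txt", txt_path, "--xml", xml_path, "--log-level", "quiet")))
  expect_identical(status2, 0L)
  expect_identical(readLines(txt_path), lines1)
})

test_that("the CLI fails cleanly on bad input and writes nothing", {
  csv_path <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y\na,b\nc,d\n", csv_path, sep = "")
  txt_path <- withr::local_tempfile(fileext = ".txt")
  # compound RHS violates the single-blank rule
  expect_message(
    status <- gar_run_cli(c("--in", csv_path, "--pattern", "_ -> _ AND _",
                            "--txt", txt_path)),
    "single blank")
  expect_false(status == 0L)
  expect_false(file.exists(txt_path))
  # missing input file
  expect_message(
    status2 <- gar_run_cli(c("--in", file.path(tempdir(), "nope.csv"),
                             "--pattern", "_ -> _", "--txt", txt_path)))
  expect_false(status2 == 0L)
  expect_false(file.exists(txt_path))
  # bad thresholds
  expect_message(
    status3 <- gar_run_cli(c("--in", csv_path, "--pattern", "_ -> _",
                             "--min-confidence", "2")))
  expect_false(status3 == 0L)
})
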