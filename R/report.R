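# TXT and XML report writers. Both are pure functions of the mining result:
# repeated runs produce byte-identical files (no timestamps). Fractions are
# printed with four decimals.

fmt4 <- function(x) sprintf("%.4f", x)

report_header_lines <- function(res) {
  cfg <- res$config
  c("# generalized association rule mining report",
    paste0("# input: ", res$table_name),
    paste0("# pattern: ", res$pattern),
    paste0("# n_rows: ", res$n_rows),
    paste0("# n_columns: ", res$n_columns),
    paste0("# min_support: ", cfg$min_support),
    paste0("# min_confidence: ", fmt4(cfg$min_confidence)),
    paste0("# min_lift: ", fmt4(cfg$min_lift)),
    paste0("# min_leverage: ", fmt4(cfg$min_leverage)),
    paste0("# max_value_set_size: ", cfg$max_value_set_size),
    paste0("# simplify_tolerance: ", fmt4(cfg$simplify_tolerance)),
    paste0("# rules: ", nrow(res$rules)))
}

#' Write a mining result as a plain-text report
#'
#' A `#`-prefixed header block with the run metadata, then one rule per
#' line: the rendered rule followed by TAB-separated support, LHS support,
#' RHS support, confidence, lift and leverage (fractions with four
#' decimals).
#'
#' @param res A `gar_rules` object from [gar_mine()].
#' @param file Path to write to, or `NULL` to return the text.
#' @return The report text (a character vector of lines), invisibly when
#'   written to a file.
#' @export
gar_write_txt <- function(res, file = NULL) {
  stopifnot(inherits(res, "gar_rules"))
  tb <- res$rules
  lines <- report_header_lines(res)
  if (nrow(tb) > 0L) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%s",
                              tb$rule, tb$support, tb$lhs_support,
                              tb$rhs_support, fmt4(tb$confidence),
                              fmt4(tb$lift), fmt4(tb$leverage)))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Write a mining result as XML
#'
#' The document root is `<rule_mining_results>` with a `<meta>` element
#' (pattern, thresholds, table dimensions) and a `<rules>` element holding
#' one `<rule>` per mined rule: `<lhs>` with `<clause>` and
#' `<eq column values>` children, `<rhs>`, and a `<metrics>` element whose
#' attributes carry the six quality measures. [gar_read_xml()] re-parses
#' the document and reproduces the report table.
#'
#' @param res A `gar_rules` object from [gar_mine()].
#' @param file Path to write to.
#' @return The `xml2` document, invisibly.
#' @export
gar_write_xml <- function(res, file) {
  stopifnot(inherits(res, "gar_rules"))
  cfg <- res$config
  doc <- xml2::xml_new_root("rule_mining_results")
  xml2::xml_add_child(doc, "meta",
    input = res$table_name,
    pattern = res$pattern,
    n_rows = as.character(res$n_rows),
    n_columns = as.character(res$n_columns),
    min_support = as.character(cfg$min_support),
    min_confidence = fmt4(cfg$min_confidence),
    min_lift = fmt4(cfg$min_lift),
    min_leverage = fmt4(cfg$min_leverage),
    max_value_set_size = as.character(cfg$max_value_set_size),
    simplify_tolerance = fmt4(cfg$simplify_tolerance))
  rules_node <- xml2::xml_add_child(doc, "rules")
  tb <- res$rules
  for (i in seq_len(nrow(tb))) {
    rule <- gar_parse_rule(tb$rule[i])
    rn <- xml2::xml_add_child(rules_node, "rule", text = tb$rule[i])
    lhs_node <- xml2::xml_add_child(rn, "lhs")
    for (cl in rule$lhs) {
      cn <- xml2::xml_add_child(lhs_node, "clause")
      for (slot in cl) {
        xml2::xml_add_child(cn, "eq", column = slot$column,
                            values = paste(slot$values, collapse = ""))
      }
    }
    rhs_node <- xml2::xml_add_child(rn, "rhs")
    xml2::xml_add_child(rhs_node, "eq", column = rule$rhs$column,
                        values = paste(rule$rhs$values, collapse = ""))
    xml2::xml_add_child(rn, "metrics",
      support = as.character(tb$support[i]),
      lhs_support = as.character(tb$lhs_support[i]),
      rhs_support = as.character(tb$rhs_support[i]),
      confidence = fmt4(tb$confidence[i]),
      lift = fmt4(tb$lift[i]),
      leverage = fmt4(tb$leverage[i]))
  }
  xml2::write_xml(doc, file)
  invisible(doc)
}

#' Read a rule report back from XML
#'
#' @param file Path to an XML report written by [gar_write_xml()].
#' @return A tibble with one row per rule: `rule`, `support`,
#'   `lhs_support`, `rhs_support`, `confidence`, `lift`, `leverage`.
#' @export
gar_read_xml <- function(file) {
  doc <- xml2::read_xml(file)
  rules <- xml2::xml_find_all(doc, "/rule_mining_results/rules/rule")
  tibble::tibble(
    rule = xml2::xml_attr(rules, "text"),
    support = as.integer(xml2::xml_attr(
      xml2::xml_find_first(rules, "metrics"), "support")),
    lhs_support = as.integer(xml2::xml_attr(
      xml2::xml_find_first(rules, "metrics"), "lhs_support")),
    rhs_support = as.integer(xml2::xml_attr(
      xml2::xml_find_first(rules, "metrics"), "rhs_support")),
    confidence = as.numeric(xml2::xml_attr(
      xml2::xml_find_first(rules, "metrics"), "confidence")),
    lift = as.numeric(xml2::xml_attr(
      xml2::xml_find_first(rules, "metrics"), "lift")),
    leverage = as.numeric(xml2::xml_attr(
      xml2::xml_find_first(rules, "metrics"), "leverage"))
  )
}
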