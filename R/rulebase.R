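#' Build the weighted Sugeno rule base from questionnaire-2 ticks
#'
#' Every antecedent line whose cell for severity level k received at least
#' one tick contributes one rule "IF line THEN severity = k" weighted by
#' ticks / panel size. A line whose panel split over several levels thus
#' yields several rules whose weights sum to 1; zero-tick cells yield no
#' rule. Lines keep their input order and levels ascend within a line, so
#' rebuilding from the serialized CSV is lossless.
#'
#' @param responses Data frame of tick counts: columns `pf_cat`,
#'   `compliance_cat`, `peep_cat`, `film`, `n0`..`n3`.
#' @param panel_size Number of physicians; every row's ticks must sum to it.
#' @return Object of class `rule_base`: data frame with columns `pf_cat`,
#'   `compliance_cat`, `peep_cat`, `film`, `consequent`, `weight`, plus
#'   attributes `panel_size` and `line_count`.
#' @examples
#' r <- data.frame(pf_cat = 1, compliance_cat = 1, peep_cat = 1, film = 1,
#'                 n0 = 0, n1 = 6, n2 = 6, n3 = 0)
#' build_rules(r, panel_size = 12)   # two rules, weights 0.5 / 0.5
#' @export
build_rules <- function(responses, panel_size) {
  need <- c("pf_cat", "compliance_cat", "peep_cat", "film",
            paste0("n", 0:3))
  if (!all(need %in% names(responses)))
    stop("responses need columns: ", paste(need, collapse = ", "))
  ticks <- as.matrix(responses[paste0("n", 0:3)])
  bad <- which(rowSums(ticks) != panel_size)
  if (length(bad))
    stop(sprintf("tick counts of line %d sum to %d, not the panel size %d",
                 bad[1], sum(ticks[bad[1], ]), panel_size))
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    lev <- which(ticks[i, ] > 0) - 1L
    data.frame(pf_cat = responses$pf_cat[i],
               compliance_cat = responses$compliance_cat[i],
               peep_cat = responses$peep_cat[i],
               film = responses$film[i],
               consequent = lev,
               weight = ticks[i, lev + 1L] / panel_size)
  })
  rb <- do.call(rbind, rows)
  rownames(rb) <- NULL
  structure(rb, panel_size = as.integer(panel_size),
            line_count = nrow(responses),
            class = c("rule_base", "data.frame"))
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("<rule_base> %d rules from %d antecedent lines (panel of %d)\n",
              nrow(x), attr(x, "line_count"), attr(x, "panel_size")))
  print.data.frame(utils::head(x, 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Read and write rule bases as CSV
#'
#' The CSV carries the antecedent indices, the crisp consequent and the
#' weight; `panel_size` is restored from the weights' common denominator on
#' read unless given.
#'
#' @param rules A `rule_base`.
#' @param path CSV path.
#' @return `write_rules()`: the path, invisibly; `read_rules()`: a
#'   `rule_base`.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_base"))
  df <- as.data.frame(rules)
  df$panel_size <- attr(rules, "panel_size")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  df <- utils::read.csv(path)
  ps <- unique(df$panel_size)
  if (length(ps) != 1L) stop("inconsistent panel_size column")
  key <- interaction(df$pf_cat, df$compliance_cat, df$peep_cat, df$film,
                     drop = TRUE)
  structure(df[setdiff(names(df), "panel_size")],
            panel_size = as.integer(ps),
            line_count = nlevels(key),
            class = c("rule_base", "data.frame"))
}
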