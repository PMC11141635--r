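# Rule-based MYCN amplification-status classifier. Evidence per cell line
# is the MYCN relative copy number on the log2(CN/2 + 1) scale, MYCN
# expression as log2(TPM + 1), and any status reported in the literature.
# Four rules are evaluated in order; the first that fires decides:
#
#   1. cn >= 3                        -> amplified, unless the line is
#      reported not_amplified, in which case the evidence conflicts and
#      the call is inconsistent.
#   2. 1.10 <= cn < 3 and (expr >= 5 or reported amplified) -> amplified.
#   3. 1.10 <= cn < 3 and (expr < 3 or reported not_amplified)
#      -> not_amplified.
#   4. cn < 1.10 and expr >= 5 and reported not_amplified -> inconsistent.
#
# If no rule fires (e.g. medium copy number with 3 <= expr < 5 and no
# report) the call is undetermined rather than a guess. The medium
# copy-number interval is taken as [1.10, 3) so rules 1 and 2 are
# disjoint. A line with expr >= 5 but reported not_amplified at medium
# copy number satisfies both rule 2 and rule 3; rule order resolves it in
# favor of amplified and the conflict is flagged with a warning.

#' Classify MYCN amplification status from copy number, expression and
#' reported status
#'
#' @param cn MYCN log2(CN/2 + 1), non-negative.
#' @param expr MYCN log2(TPM + 1), non-negative.
#' @param reported Reported status, one of `"amplified"`,
#'   `"not_amplified"`, `"none"`.
#' @param line Optional line identifiers (default `L1`, `L2`, ...).
#' @return A data frame with columns `line`, `status` (one of
#'   `"amplified"`, `"not_amplified"`, `"inconsistent"`,
#'   `"undetermined"`) and `rule_fired` (`1:4` or `NA` when no rule
#'   fires).
#' @examples
#' classify_mycn(cn = c(3.5, 2.0, 0.5), expr = c(7, 2, 6),
#'               reported = c("none", "none", "not_amplified"))
#' @export
classify_mycn <- function(cn, expr, reported = "none", line = NULL) {
  n <- max(length(cn), length(expr), length(reported))
  cn <- rep_len(as.numeric(cn), n)
  expr <- rep_len(as.numeric(expr), n)
  reported <- rep_len(as.character(reported), n)
  if (is.null(line)) line <- paste0("L", seq_len(n))
  line <- rep_len(as.character(line), n)
  if (any(is.na(cn)) || any(is.na(expr)))
    stop("missing copy-number or expression evidence")
  if (any(cn < 0) || any(expr < 0))
    stop("negative copy-number or expression evidence")
  ok <- reported %in% c("amplified", "not_amplified", "none")
  if (!all(ok))
    stop("unknown reported status: ",
         paste(unique(reported[!ok]), collapse = ", "))

  status <- rep("undetermined", n)
  rule <- rep(NA_integer_, n)

  r1 <- cn >= 3
  status[r1] <- ifelse(reported[r1] == "not_amplified",
                       "inconsistent", "amplified")
  rule[r1] <- 1L

  medium <- !r1 & cn >= 1.10 & cn < 3
  r2 <- medium & (expr >= 5 | reported == "amplified")
  status[r2] <- "amplified"
  rule[r2] <- 2L

  conflict <- r2 & reported == "not_amplified"
  if (any(conflict))
    warning("conflicting evidence (expression >= 5 but reported ",
            "not_amplified) for: ", paste(line[conflict], collapse = ", "),
            "; rule order resolves to amplified")

  r3 <- medium & !r2 & (expr < 3 | reported == "not_amplified")
  status[r3] <- "not_amplified"
  rule[r3] <- 3L

  r4 <- !r1 & !medium & cn < 1.10 & expr >= 5 & reported == "not_amplified"
  status[r4] <- "inconsistent"
  rule[r4] <- 4L

  data.frame(line = line, status = status, rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' Classify MYCN status for every line of a screen bundle
#'
#' Convenience wrapper applying [classify_mycn()] to the bundle's
#' per-line annotations.
#'
#' @param bundle A [generate_screen()] bundle (or any list with an
#'   `annotations` data frame carrying `line`, `mycn_cn`, `mycn_expr`,
#'   `mycn_reported`).
#' @return The [classify_mycn()] call table.
#' @export
classify_mycn_bundle <- function(bundle) {
  ann <- bundle$annotations
  classify_mycn(cn = ann$mycn_cn, expr = ann$mycn_expr,
                reported = ann$mycn_reported, line = ann$line)
}
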