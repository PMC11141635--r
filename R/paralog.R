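# Paralog-redundancy screen: restrict to cell lines dependent on an
# anchor gene, then correlate a query gene's dependency with genome-wide
# expression. A redundant paralog shows up as the strongest (negative)
# correlation: dependency on the query deepens where the paralog's
# expression is low.

#' Select lines dependent on an anchor gene
#'
#' Lines whose (non-missing) dependency score for the anchor gene lies
#' strictly below the threshold. The conventional cutoff for calling a
#' line dependent is a score below -0.3.
#'
#' @param dep Genes x lines dependency matrix.
#' @param anchor_gene Row name of the anchor gene.
#' @param threshold Strict upper bound on the score (default `-0.3`).
#' @return Character vector of line identifiers (possibly empty, with a
#'   warning).
#' @export
select_dependent_lines <- function(dep, anchor_gene, threshold = -0.3) {
  if (!anchor_gene %in% rownames(dep))
    stop("anchor gene not in matrix: ", anchor_gene)
  s <- dep[anchor_gene, ]
  lines <- colnames(dep)[!is.na(s) & s < threshold]
  if (length(lines) == 0L)
    warning("no line qualifies as dependent on ", anchor_gene,
            " at threshold ", threshold)
  lines
}

#' Correlate a query gene's dependency with genome-wide expression
#'
#' For each expressed gene, the Pearson correlation across the selected
#' lines between the query gene's dependency scores and that gene's
#' expression, with `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and a
#' two-sided p from the t distribution on `n - 2` df, plus a
#' Benjamini-Hochberg q across all tested genes. Missing values are
#' handled pairwise per gene; genes with fewer than three complete pairs
#' or a constant vector are skipped with a reason.
#'
#' @param dep Genes x lines dependency matrix.
#' @param expr Genes x lines log2(TPM+1) expression matrix.
#' @param query_gene Dependency row to correlate (e.g. `KAT2A`).
#' @param lines Lines to use (e.g. from [select_dependent_lines()]).
#' @param expressed_only Keep only genes with maximum log2(TPM+1) >= 1
#'   across the selected lines (default `TRUE`).
#' @return Data frame sorted by p: `gene`, `n`, `r`, `t`, `p`, `q`,
#'   `note` (`""`, `"perfect_correlation"`); skipped genes in the
#'   `"skipped"` attribute.
#' @export
expression_dependency_screen <- function(dep, expr, query_gene, lines,
                                         expressed_only = TRUE) {
  if (!query_gene %in% rownames(dep))
    stop("query gene not in dependency matrix: ", query_gene)
  lines <- intersect(lines, intersect(colnames(dep), colnames(expr)))
  if (length(lines) < 3L)
    stop("need at least three lines with dependency and expression data")
  y <- dep[query_gene, lines]
  e <- expr[, lines, drop = FALSE]
  if (expressed_only) {
    mx <- apply(e, 1L, max, na.rm = TRUE)
    e <- e[is.finite(mx) & mx >= 1, , drop = FALSE]
  }
  genes <- rownames(e)
  res <- lapply(genes, function(g) {
    x <- e[g, ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L)
      return(list(skip = data.frame(gene = g, reason = "too_few_pairs")))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(list(skip = data.frame(gene = g, reason = "constant_vector")))
    r <- stats::cor(x[ok], y[ok])
    note <- ""
    if (abs(r) >= 1 - 1e-12) {
      r <- sign(r)  # perfect correlation: p underflows to machine limit
      tt <- sign(r) * Inf
      p <- .Machine$double.xmin
      note <- "perfect_correlation"
    } else {
      tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    list(row = data.frame(gene = g, n = n, r = r, t = tt, p = p,
                          note = note, stringsAsFactors = FALSE))
  })
  rows <- do.call(rbind, lapply(res, `[[`, "row"))
  skipped <- do.call(rbind, lapply(res, `[[`, "skip"))
  if (is.null(rows)) stop("no testable genes")
  rows$q <- bh_adjust(rows$p)
  rows <- rows[order(rows$p, rows$gene),
               c("gene", "n", "r", "t", "p", "q", "note")]
  rownames(rows) <- NULL
  attr(rows, "skipped") <- skipped
  rows
}

#' Linear association F-test
#'
#' Ordinary least squares of `y` on `x`; the slope's F statistic on
#' `(1, n - 2)` df. Algebraically `F = t^2` of the Pearson correlation,
#' so the p-value equals the correlation p on the same data.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped);
#'   `x` must not be constant.
#' @return List with `slope`, `intercept`, `F`, `df` (`c(1, n - 2)`) and
#'   `p`.
#' @export
linear_association_ftest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least three paired observations")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  if (stats::sd(y) == 0)
    return(list(slope = 0, intercept = mean(y), F = 0,
                df = c(1, n - 2), p = 1))
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  if (abs(r) >= 1 - 1e-12) {
    f <- Inf
    p <- .Machine$double.xmin
  } else {
    f <- r^2 * (n - 2) / (1 - r^2)
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       F = f, df = c(1, n - 2), p = p)
}
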