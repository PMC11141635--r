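# Two-class differential dependency with an empirical-Bayes moderated
# t-statistic. Per gene, the pooled two-sample residual variance s_g^2 on
# d_g = n_in + n_out - 2 df is shrunk toward a prior variance s0^2 with
# prior df d0, both estimated across genes by method of moments on
# log s_g^2 (digamma/trigamma inversion). The moderated variance is
#   s~^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)
# and t = effect / (s~ * sqrt(1/n_in + 1/n_out)) on d0 + d_g df.
# d0 = 0 recovers the classical pooled t; d0 = Inf uses the common prior
# variance for every gene.

#' Benjamini-Hochberg adjustment
#'
#' Validates the inputs and applies the standard step-up false discovery
#' rate correction.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing, convex
# in 1/y), with asymptotic starts for extreme x.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Estimate empirical-Bayes variance moderation parameters
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior to observed
#' per-gene variances: on the log scale, `E[log s^2]` and `Var[log s^2]`
#' have closed forms in digamma/trigamma of the residual and prior df,
#' which are inverted to give the prior df `d0` and prior variance
#' `s0_sq`. When the observed spread of `log s^2` is no larger than
#' expected from the residual df alone, the prior df is infinite and
#' `s0_sq` is the common variance.
#'
#' @param s2 Per-gene residual variances (positive; zeros/NAs excluded
#'   from estimation).
#' @param df Residual degrees of freedom, scalar or per-gene.
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_moderation <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2L)
    stop("need at least two positive variances to estimate moderation")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # spread of log s^2 fully explained by the residual df: infinite
    # prior df, common variance equal to the mean observed variance
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Two-class differential dependency
#'
#' Compares the dependency scores of an in-group of cell lines against an
#' out-group, gene by gene, with a moderated t-statistic. Missing values
#' are removed per gene per group; genes left with fewer than two values
#' in either group are reported with missing statistics and a reason.
#'
#' @param dep Genes x lines dependency matrix.
#' @param in_lines,out_lines Disjoint character vectors of column names.
#' @param d0 Prior degrees of freedom: `NULL` (default) estimates
#'   `(d0, s0_sq)` across genes; `0` gives the classical pooled t;
#'   `Inf` uses the common prior variance.
#' @param s0_sq Prior variance, required if `d0` is given as a finite
#'   positive number or `Inf`; ignored when `d0` is `NULL` or `0`.
#' @return A data frame with one row per gene: `gene`, `n_in`, `n_out`,
#'   `mean_in`, `mean_out`, `effect` (`mean_in - mean_out`), `t`, `df`,
#'   `p` (two-sided), `q` (Benjamini-Hochberg across tested genes) and
#'   `note` (`""`, `"too_few_values"`, or `"zero_variance_nonzero_effect"`).
#'   The moderation parameters used are attached as attribute
#'   `"moderation"`.
#' @export
two_class <- function(dep, in_lines, out_lines, d0 = NULL, s0_sq = NULL) {
  if (length(intersect(in_lines, out_lines)))
    stop("in and out groups overlap: ",
         paste(intersect(in_lines, out_lines), collapse = ", "))
  missing_cols <- setdiff(c(in_lines, out_lines), colnames(dep))
  if (length(missing_cols))
    stop("lines not in matrix: ", paste(missing_cols, collapse = ", "))
  if (length(in_lines) < 2L || length(out_lines) < 2L)
    stop("each group needs at least two lines")

  x <- dep[, in_lines, drop = FALSE]
  y <- dep[, out_lines, drop = FALSE]
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
  tested <- n1 >= 2 & n2 >= 2
  dg <- n1 + n2 - 2
  s2 <- ifelse(tested, (ss1 + ss2) / dg, NA_real_)

  if (is.null(d0)) {
    mod <- estimate_moderation(s2[tested], dg[tested])
  } else if (d0 == 0) {
    mod <- list(d0 = 0, s0_sq = 0)
  } else {
    if (is.null(s0_sq)) stop("s0_sq required when d0 is fixed and nonzero")
    mod <- list(d0 = d0, s0_sq = s0_sq)
  }

  s2_mod <- if (is.infinite(mod$d0)) rep(mod$s0_sq, length(s2))
            else (mod$d0 * mod$s0_sq + dg * s2) / (mod$d0 + dg)
  # total df capped at the pooled residual df across tested genes: the
  # prior is estimated from these genes, so it cannot add more
  # information than they carry
  df_total <- pmin(mod$d0 + dg, sum(dg[tested]))
  effect <- m1 - m2
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat <- effect / se
  note <- rep("", nrow(dep))
  # degenerate: zero moderated variance
  zero_se <- tested & se == 0
  tstat[zero_se & effect == 0] <- 0
  flagged <- zero_se & effect != 0
  tstat[flagged] <- sign(effect[flagged]) * Inf
  note[flagged] <- "zero_variance_nonzero_effect"
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[zero_se & effect == 0] <- 1
  p[flagged] <- .Machine$double.xmin
  p[!tested] <- NA_real_
  tstat[!tested] <- NA_real_
  effect[!tested] <- NA_real_
  note[!tested] <- "too_few_values"
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_adjust(p[tested])

  out <- data.frame(gene = rownames(dep), n_in = n1, n_out = n2,
                    mean_in = m1, mean_out = m2, effect = effect,
                    t = tstat, df = ifelse(tested, df_total, NA_real_),
                    p = p, q = q, note = note,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "moderation") <- mod
  out
}
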