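# Spike-in calibrated ChIP-seq region quantification: per-sample scale
# factors from exogenous (dm6) read totals, AUC-based peak curation with
# blacklist removal, merging of per-condition peak sets, and
# differential-region classification combining a delta on log2(AUC + 1)
# condition means with a count-based significance test.

#' Spike-in scale factors
#'
#' For each sample, the ratio between the cross-sample mean of the
#' uniquely mapped spike-in read counts and that sample's count.
#' Multiplying a sample's signal by its factor equalizes spike-in totals
#' to the pre-scaling mean.
#'
#' @param spike Named vector of positive per-sample spike-in read counts.
#' @return Named numeric vector of scale factors.
#' @export
spikein_scale_factors <- function(spike) {
  if (length(spike) == 0L) stop("no samples")
  bad <- which(!is.finite(spike) | spike <= 0)
  if (length(bad))
    stop("non-positive spike-in count for sample: ",
         paste(if (!is.null(names(spike))) names(spike)[bad] else bad,
               collapse = ", "))
  mean(spike) / spike
}

#' Curate peaks by AUC signal and blacklist overlap
#'
#' Removes regions whose log2(AUC + 1) in the calling sample falls below
#' the threshold (boundary kept: log2(AUC + 1) == threshold is retained)
#' and regions overlapping a blacklist interval by at least one base.
#'
#' @param signal A region signal table: list with `regions`
#'   ([region_table()]) and `auc` (region x sample matrix or per-region
#'   vector), e.g. from [generate_region_fixture()]; `counts` and other
#'   parallel fields are filtered alongside.
#' @param blacklist Optional [region_table()] of excluded regions.
#' @param auc_min_log2 Threshold on log2(AUC + 1) (default 13).
#' @param auc_sample Column of `auc` used for curation (default 1).
#' @return The filtered signal table; the number of regions removed per
#'   criterion is in the `"removed"` attribute
#'   (`c(low_auc = , blacklist = )`).
#' @export
curate_peaks <- function(signal, blacklist = NULL, auc_min_log2 = 13,
                         auc_sample = 1L) {
  regions <- signal$regions
  stopifnot(inherits(regions, "region_table"))
  auc <- signal$auc
  a <- if (is.null(dim(auc))) auc else auc[, auc_sample]
  if (length(a) != nrow(regions))
    stop("AUC vector does not match region table")
  keep_auc <- log2(a + 1) >= auc_min_log2
  n_low <- sum(!keep_auc)
  keep_bl <- rep(TRUE, nrow(regions))
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    hits <- GenomicRanges::findOverlaps(as_granges(regions),
                                        as_granges(blacklist),
                                        minoverlap = 1L)
    keep_bl[unique(S4Vectors_queryHits(hits))] <- FALSE
  }
  n_bl <- sum(keep_auc & !keep_bl)  # attribute removals to first failing rule
  keep <- keep_auc & keep_bl
  out <- filter_signal(signal, keep)
  attr(out, "removed") <- c(low_auc = n_low, blacklist = n_bl)
  out
}

# queryHits without importing S4Vectors into the NAMESPACE surface.
S4Vectors_queryHits <- function(hits) {
  getExportedValue("S4Vectors", "queryHits")(hits)
}

# Subset every region-parallel field of a signal table.
filter_signal <- function(signal, keep) {
  out <- signal
  out$regions <- signal$regions[keep, , drop = FALSE]
  class(out$regions) <- c("region_table", "data.frame")
  for (f in c("auc", "counts")) {
    if (is.null(signal[[f]])) next
    out[[f]] <- if (is.null(dim(signal[[f]]))) signal[[f]][keep]
                else signal[[f]][keep, , drop = FALSE]
  }
  out
}

#' Merge per-condition peak sets into aggregated peaks
#'
#' Union of all intervals with overlapping or directly abutting
#' intervals merged; output sorted by (chromosome, start). Names are not
#' preserved (merged regions get fresh `peak_N` names).
#'
#' @param ... Any number of [region_table()] objects (or a single list
#'   of them).
#' @return A merged, sorted [region_table()].
#' @export
merge_condition_peaks <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1L]], "region_table"))
    tabs <- tabs[[1L]]
  if (!all(vapply(tabs, inherits, TRUE, "region_table")))
    stop("all inputs must be region tables")
  all_regions <- do.call(rbind, lapply(tabs, function(t) t[, 1:3]))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = all_regions$chrom,
    ranges = IRanges::IRanges(start = all_regions$start + 1,
                              end = all_regions$end)))
  gr <- GenomicRanges::sort(gr)
  region_table(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr),
               sprintf("peak_%d", seq_along(gr)))
}

# Negative-binomial log-likelihood of counts y with means mu * lib
# (per-sample relative effective size lib) at common dispersion phi.
nb_loglik <- function(y, mu, lib, phi) {
  m <- mu * lib
  if (phi <= 1e-12) sum(stats::dpois(y, m, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = m, log = TRUE))
}

# MLE of a single NB mean with offsets: closed form when library sizes
# are equal, otherwise a 1-d optimization on log mu.
nb_fit_mean <- function(y, lib, phi) {
  if (all(y == 0)) return(list(mu = 0, ll = nb_loglik(y, 1e-12, lib, phi)))
  if (max(lib) - min(lib) < 1e-12) {
    mu <- mean(y) / lib[1]
    return(list(mu = mu, ll = nb_loglik(y, mu, lib, phi)))
  }
  start <- sum(y) / sum(lib)
  opt <- stats::optimize(function(lm) -nb_loglik(y, exp(lm), lib, phi),
                         interval = log(start) + c(-8, 8), tol = 1e-9)
  list(mu = exp(opt$minimum), ll = -opt$objective)
}

# Method-of-moments common dispersion across regions on normalized
# counts: per region pooled within-group (var - mean) / mean^2, combined
# as the median over informative regions, floored at 0.
estimate_common_dispersion <- function(norm_counts, groups) {
  phis <- apply(norm_counts, 1L, function(y) {
    per_group <- vapply(unique(groups), function(g) {
      v <- y[groups == g]
      if (length(v) < 2L) return(c(NA_real_, NA_real_))
      c(mean(v), stats::var(v))
    }, numeric(2))
    m <- per_group[1, ]; v <- per_group[2, ]
    ok <- !is.na(m) & m > 0
    if (!any(ok)) return(NA_real_)
    sum((v[ok] - m[ok])) / sum(m[ok]^2)
  })
  phis <- phis[is.finite(phis)]
  if (length(phis) == 0L) return(0)
  max(0, stats::median(phis))
}

#' Classify differential regions between two conditions
#'
#' The effect size is the difference of the per-condition means of
#' log2(AUC + 1) (treated minus control); significance comes from a
#' per-region likelihood-ratio test on the read counts under a
#' negative-binomial model with a common dispersion estimated across
#' regions by method of moments (or from an exact group-relabeling
#' permutation of the LRT statistic for small designs). A region is
#' called `increase` when `delta >= delta_cutoff` and `p <= p_cutoff`,
#' `decrease` when `delta <= -delta_cutoff` and `p <= p_cutoff`, and
#' `not_significant` otherwise.
#'
#' @param counts Region x sample integer count matrix.
#' @param groups Named vector/factor assigning each sample (column) to
#'   one of exactly two conditions.
#' @param aucs Region x sample AUC matrix on the same samples.
#' @param treated Level of `groups` taken as the treated condition
#'   (default the second level).
#' @param delta_cutoff Absolute cutoff on the delta of log2(AUC + 1)
#'   condition means (default 1.5).
#' @param p_cutoff Significance cutoff (default 0.10).
#' @param scale_factors Optional per-sample factors (e.g. from
#'   [spikein_scale_factors()]); counts are modeled with matching
#'   effective sizes and AUCs are multiplied by them before the delta.
#' @param method `"nb_lrt"` (default) or `"permutation"` (exact
#'   enumeration of group relabelings of the LRT statistic).
#' @return Data frame: `region`, `delta`, `p`, `class`.
#' @export
differential_regions <- function(counts, groups, aucs,
                                 treated = NULL,
                                 delta_cutoff = 1.5, p_cutoff = 0.10,
                                 scale_factors = NULL,
                                 method = c("nb_lrt", "permutation")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two conditions required")
  if (is.null(treated)) treated <- lv[2L]
  if (!treated %in% lv) stop("unknown treated level: ", treated)
  control <- setdiff(lv, treated)
  if (min(table(groups)) < 1L) stop("a condition has zero replicates")
  if (ncol(counts) != length(groups) || ncol(aucs) != length(groups))
    stop("counts/aucs columns must match groups")

  if (is.null(scale_factors)) scale_factors <- rep(1, length(groups))
  lib <- 1 / scale_factors          # effective relative depth per sample
  auc_scaled <- sweep(aucs, 2L, scale_factors, `*`)
  delta <- rowMeans(log2(auc_scaled[, groups == treated, drop = FALSE] + 1)) -
           rowMeans(log2(auc_scaled[, groups == control, drop = FALSE] + 1))

  norm_counts <- sweep(counts, 2L, scale_factors, `*`)
  phi <- estimate_common_dispersion(norm_counts, groups)

  lrt_stat <- function(y, g) {
    full <- nb_fit_mean(y[g == treated], lib[g == treated], phi)$ll +
            nb_fit_mean(y[g == control], lib[g == control], phi)$ll
    null <- nb_fit_mean(y, lib, phi)$ll
    max(0, 2 * (full - null))
  }

  n_regions <- nrow(counts)
  p <- numeric(n_regions)
  if (method == "nb_lrt") {
    for (i in seq_len(n_regions)) {
      y <- counts[i, ]
      if (all(y == 0)) { p[i] <- 1; next }
      p[i] <- stats::pchisq(lrt_stat(y, groups), df = 1, lower.tail = FALSE)
    }
  } else {
    idx_treated <- utils::combn(length(groups), sum(groups == treated))
    if (ncol(idx_treated) > 10000L)
      stop("too many relabelings for exact permutation; use nb_lrt")
    for (i in seq_len(n_regions)) {
      y <- counts[i, ]
      if (all(y == 0)) { p[i] <- 1; next }
      obs <- lrt_stat(y, groups)
      stats_perm <- apply(idx_treated, 2L, function(ix) {
        g <- rep(control, length(groups)); g[ix] <- treated
        lrt_stat(y, g)
      })
      p[i] <- mean(stats_perm >= obs - 1e-12)
    }
  }

  cls <- rep("not_significant", n_regions)
  cls[delta >= delta_cutoff & p <= p_cutoff] <- "increase"
  cls[delta <= -delta_cutoff & p <= p_cutoff] <- "decrease"
  region <- if (!is.null(rownames(counts))) rownames(counts)
            else sprintf("region_%d", seq_len(n_regions))
  data.frame(region = region, delta = delta, p = p, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
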