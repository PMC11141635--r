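# Preranked gene set enrichment with the weighted Kolmogorov-Smirnov
# running-sum statistic and a gene-label permutation null, single-sample
# GSEA (ssGSEA) metagene scores, cross-sample z-standardization, and
# set-overlap significance tests.
#
# Enrichment score: walking down the ranked list, in-set genes add
# |s_j|^p / sum_set |s|^p to the running sum and out-of-set genes
# subtract 1 / (N - |S|); ES is the signed extremum of the running sum.
# The null distribution comes from random gene-label sets of identical
# size; NES divides ES by the mean same-sign permutation ES.

#' Rank genes by a signed score
#'
#' Produces the descending ranked list consumed by [gsea_preranked()].
#' Ties are broken lexicographically by gene identifier so the order is
#' deterministic; non-finite scores are excluded and counted.
#'
#' @param scores Named numeric vector (names = gene identifiers), or a
#'   data frame with a `gene` column and the score column named by
#'   `score_col` (e.g. the output of [two_class()]).
#' @param score_col Column to rank on when `scores` is a data frame
#'   (default `"t"`).
#' @return A list of class `ranked_list` with `genes`, `scores`
#'   (descending) and `n_excluded`.
#' @export
rank_genes <- function(scores, score_col = "t") {
  if (is.data.frame(scores)) {
    s <- scores[[score_col]]
    names(s) <- scores$gene
    scores <- s
  }
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by gene identifier")
  if (anyDuplicated(names(scores)))
    stop("duplicate gene identifiers in ranking")
  keep <- is.finite(scores)
  n_excluded <- sum(!keep)
  scores <- scores[keep]
  ord <- order(-scores, names(scores), method = "radix")
  structure(list(genes = names(scores)[ord],
                 scores = unname(scores[ord]),
                 n_excluded = n_excluded),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("ranked_list of", length(x$genes), "genes (",
      x$n_excluded, "excluded )\n")
  invisible(x)
}

# Core running-sum statistic. scores: full descending score vector;
# hit: logical vector marking in-set positions; p: weight exponent.
# Returns ES and the extremum position.
gsea_running_sum <- function(scores, hit, p = 1) {
  n <- length(scores)
  n_hit <- sum(hit)
  if (n_hit == 0L || n_hit == n)
    stop("gene set empty or equal to the ranked universe")
  w <- abs(scores)^p
  nr <- sum(w[hit])
  if (nr == 0) return(list(es = NA_real_, at = NA_integer_))
  inc <- ifelse(hit, w / nr, -1 / (n - n_hit))
  running <- cumsum(inc)
  at <- which.max(abs(running))
  list(es = running[at], at = at, running = running)
}

# ES for a set given as positions within the ranked list.
gsea_es_at <- function(scores, positions, p = 1) {
  hit <- logical(length(scores))
  hit[positions] <- TRUE
  gsea_running_sum(scores, hit, p)$es
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment of each gene set in a ranked
#' list, with significance from a seeded gene-label permutation null.
#' Per set: `ES` is the signed extremum of the running sum; `NES` is
#' `ES` divided by the mean absolute permutation ES of the same sign;
#' the nominal p is the one-sided frequency of same-sign permutation ESs
#' at least as extreme; the FDR follows the GSEA-software global
#' ratio-of-tails scheme on NES (`fdr_method = "gsea"`), or
#' Benjamini-Hochberg on the nominal p (`"bh"`, preferable at small
#' `n_perm`).
#'
#' @param ranked A [rank_genes()] ranked list.
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of gene-label permutations per set size.
#' @param weight_p Weight exponent on |score| (1 = weighted scheme,
#'   0 = classic unweighted KS).
#' @param seed Integer seed for the permutation null.
#' @param min_size,max_size Sets with fewer/more members present in the
#'   ranked list are skipped (reason recorded in the `skipped`
#'   attribute).
#' @param fdr_method `"gsea"` or `"bh"`.
#' @return Data frame with one row per scored set: `set`, `size`, `ES`,
#'   `NES`, `p`, `q`, `leading_edge` (comma-separated genes). Skipped
#'   sets are recorded in the `"skipped"` attribute.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight_p = 1,
                           seed = 1L, min_size = 2, max_size = Inf,
                           fdr_method = c("gsea", "bh")) {
  stopifnot(inherits(ranked, "ranked_list"),
            inherits(sets, "gene_set_collection"))
  fdr_method <- match.arg(fdr_method)
  genes <- ranked$genes
  scores <- ranked$scores
  n <- length(genes)

  members <- lapply(sets$sets, function(s) which(genes %in% s))
  sizes <- lengths(members)
  skip <- sizes < min_size | sizes > max_size
  skipped <- data.frame(set = names(sets$sets)[skip],
                        size = sizes[skip],
                        reason = ifelse(sizes[skip] < min_size,
                                        "below_min_size", "above_max_size"),
                        stringsAsFactors = FALSE)
  use <- names(sets$sets)[!skip]
  if (any(sizes[!skip] == n))
    stop("gene set equal to the ranked universe: ",
         paste(use[sizes[!skip] == n], collapse = ", "))

  obs <- lapply(members[use], function(pos) {
    hit <- logical(n); hit[pos] <- TRUE
    gsea_running_sum(scores, hit, weight_p)
  })
  es <- vapply(obs, `[[`, 0, "es")

  # one shared permutation null per distinct set size
  perm_by_size <- with_local_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes[use]))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i)
        gsea_es_at(scores, sample.int(n, k), weight_p), 0)
    }
    out
  })

  nes <- p_nom <- rep(NA_real_, length(use))
  perm_nes_all <- vector("list", length(use))
  for (i in seq_along(use)) {
    perm <- perm_by_size[[as.character(sizes[use][i])]]
    pos_mean <- mean(perm[perm > 0])
    neg_mean <- mean(abs(perm[perm < 0]))
    e <- es[i]
    if (is.na(e)) next
    if (e >= 0) {
      if (is.finite(pos_mean) && pos_mean > 0) nes[i] <- e / pos_mean
      n_same <- sum(perm > 0)
      p_nom[i] <- if (n_same > 0) sum(perm >= e) / n_same else NA_real_
      if (e == 0) p_nom[i] <- 1
    } else {
      if (is.finite(neg_mean) && neg_mean > 0) nes[i] <- e / neg_mean
      n_same <- sum(perm < 0)
      p_nom[i] <- if (n_same > 0) sum(perm <= e) / n_same else NA_real_
    }
    pn <- perm
    pn[perm > 0] <- perm[perm > 0] / pos_mean
    pn[perm < 0] <- perm[perm < 0] / neg_mean
    perm_nes_all[[i]] <- pn[is.finite(pn)]
  }

  q <- if (fdr_method == "bh") {
    bh_adjust(p_nom)
  } else {
    pool <- unlist(perm_nes_all)
    vapply(seq_along(use), function(i) {
      v <- nes[i]
      if (is.na(v)) return(NA_real_)
      if (v >= 0) {
        num_den <- sum(pool >= 0)
        num <- if (num_den > 0) sum(pool >= v) / num_den else NA_real_
        obs_den <- sum(nes >= 0, na.rm = TRUE)
        den <- if (obs_den > 0) sum(nes >= v, na.rm = TRUE) / obs_den else NA_real_
      } else {
        num_den <- sum(pool < 0)
        num <- if (num_den > 0) sum(pool <= v) / num_den else NA_real_
        obs_den <- sum(nes < 0, na.rm = TRUE)
        den <- if (obs_den > 0) sum(nes <= v, na.rm = TRUE) / obs_den else NA_real_
      }
      min(1, num / den)
    }, 0)
  }

  leading <- vapply(seq_along(use), function(i) {
    o <- obs[[i]]
    if (is.na(o$es)) return("")
    pos <- members[[use[i]]]
    le <- if (o$es >= 0) pos[pos <= o$at] else pos[pos >= o$at]
    paste(genes[le], collapse = ",")
  }, "")

  out <- data.frame(set = use, size = sizes[use], ES = es, NES = nes,
                    p = p_nom, q = q, leading_edge = leading,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Single-sample GSEA scores
#'
#' For each sample, genes are ranked descending by their value; the score
#' of a set is the sum over all list positions of the difference between
#' the weighted in-set empirical CDF (weights = rank^alpha, average ranks
#' for ties) and the uniform out-of-set CDF -- an integral rather than an
#' extremum. With `normalize = TRUE` all scores are divided by the range
#' (max - min) of the whole score matrix.
#'
#' @param mat Genes x samples matrix (dependency or expression); missing
#'   genes are dropped per sample.
#' @param sets A [gene_set_collection()].
#' @param alpha Rank weight exponent (default 0.25).
#' @param normalize Range-normalize the score matrix (default `TRUE`).
#' @return Sets x samples numeric matrix; set/sample pairs with no set
#'   member present are `NA` and listed in the `"skipped"` attribute.
#' @export
ssgsea_score <- function(mat, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(inherits(sets, "gene_set_collection"), alpha >= 0)
  set_names <- names(sets$sets)
  out <- matrix(NA_real_, length(set_names), ncol(mat),
                dimnames = list(set_names, colnames(mat)))
  skipped <- list()
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    v <- v[!is.na(v)]
    if (length(v) < 2L) next
    ord <- order(-v, names(v), method = "radix")
    g <- names(v)[ord]
    r <- rank(v, ties.method = "average")[ord]  # top gene has rank ~N
    w <- r^alpha
    n <- length(v)
    for (s in set_names) {
      hit <- g %in% sets$sets[[s]]
      n_hit <- sum(hit)
      if (n_hit == 0L) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(set = s, sample = colnames(mat)[j],
                     reason = "no_members_in_matrix")
        next
      }
      if (n_hit == n) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(set = s, sample = colnames(mat)[j],
                     reason = "set_equals_universe")
        next
      }
      p_in <- cumsum(w * hit) / sum(w[hit])
      p_out <- cumsum(!hit) / (n - n_hit)
      out[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) > 0) out <- out / diff(rng)
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else NULL
  out
}

#' z-standardize scores across samples
#'
#' Per set (row), subtracts the cross-sample mean and divides by the
#' cross-sample standard deviation (sample sd, n - 1 denominator).
#' Constant rows get all-zero z-scores with a warning.
#'
#' @param scores Sets x samples matrix (e.g. from [ssgsea_score()]).
#' @return Matrix of the same shape with per-row mean 0, sd 1 (where
#'   defined).
#' @export
zscore_across_samples <- function(scores) {
  if (is.null(dim(scores))) stop("scores must be a matrix")
  n_ok <- rowSums(!is.na(scores))
  if (any(n_ok < 2L))
    stop("need at least two non-missing samples per set")
  m <- rowMeans(scores, na.rm = TRUE)
  s <- apply(scores, 1L, stats::sd, na.rm = TRUE)
  z <- (scores - m) / s
  if (any(s == 0)) {
    warning("constant scores for set(s): ",
            paste(rownames(scores)[s == 0], collapse = ", "),
            "; z set to 0")
    z[s == 0, ] <- 0
  }
  z
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a hit list and a gene set drawn from a common universe.
#'
#' @param hits,set Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List with `overlap` (count), `expected` (under independence)
#'   and `p` (upper tail, `P(X >= k)`).
#' @export
overlap_test <- function(hits, set, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  hits <- unique(hits); set <- unique(set)
  if (!all(hits %in% universe) || !all(set %in% universe))
    stop("hits and set must be subsets of the universe")
  k <- length(intersect(hits, set))
  p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                     length(hits), lower.tail = FALSE)
  list(overlap = k,
       expected = length(hits) * length(set) / length(universe),
       p = p)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Two-tailed p computed by summing the probabilities of all tables
#' (with the observed margins) whose point probability does not exceed
#' the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`matrix(c(a, c, b, d), 2)`).
#' @return Two-tailed p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}
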