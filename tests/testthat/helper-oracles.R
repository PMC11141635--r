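# Independent reference implementations used as oracles. All are written
# as plain position-by-position loops so they share no code path with the
# vectorized package implementations.

# Enrichment score by explicit walk down the ranked list.
oracle_es <- function(scores, set_positions, p = 1) {
  n <- length(scores)
  n_hit <- length(set_positions)
  nr <- sum(abs(scores[set_positions])^p)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (i %in% set_positions) {
      running <- running + abs(scores[i])^p / nr
    } else {
      running <- running - 1 / (n - n_hit)
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Exact permutation null: ES for every size-k subset of 1..n.
oracle_all_subset_es <- function(scores, k, p = 1) {
  apply(utils::combn(length(scores), k), 2L,
        function(ix) oracle_es(scores, ix, p))
}

# One-sided nominal p among same-sign permutation ESs (the definition
# gsea_preranked uses), from an explicit null vector.
oracle_nominal_p <- function(es_obs, es_null) {
  if (es_obs >= 0) {
    same <- es_null[es_null > 0]
    if (length(same) == 0) return(NA_real_)
    sum(same >= es_obs) / length(same)
  } else {
    same <- es_null[es_null < 0]
    if (length(same) == 0) return(NA_real_)
    sum(same <= es_obs) / length(same)
  }
}

# ssGSEA score for one sample by direct summation of the two ECDF series.
oracle_ssgsea <- function(values, set, alpha) {
  ord <- order(-values, names(values))
  g <- names(values)[ord]
  r <- rank(values, ties.method = "average")[ord]
  n <- length(values)
  in_set <- g %in% set
  w_total <- sum(r[in_set]^alpha)
  n_out <- n - sum(in_set)
  cum_in <- 0; cum_out <- 0; score <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_in <- cum_in + r[i]^alpha / w_total
    else cum_out <- cum_out + 1 / n_out
    score <- score + (cum_in - cum_out)
  }
  unname(score)
}

# Two-tailed Fisher p on a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables (fixed margins) whose point
# probability does not exceed the observed one.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b          # first row margin
  n_ <- c + d
  k <- a + c          # first column margin
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n_, k), 0)
  obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# ES comparison tolerant of the symmetric-extremum knife edge: when the
# running sum attains +m and -m with |difference| below float noise, the
# signed winner depends on summation order, so only |ES| is compared.
expect_es_equal <- function(actual, expected, tol = 1e-9, label = NULL) {
  if (abs(abs(actual) - abs(expected)) < tol &&
      abs(actual - expected) > tol) {
    testthat::expect_equal(abs(actual), abs(expected), tolerance = tol,
                           label = label)
  } else {
    testthat::expect_equal(actual, expected, tolerance = tol, label = label)
  }
}

# Ranked list constructor for toys, bypassing rank_genes.
toy_ranked <- function(scores, genes = paste0("g", seq_along(scores))) {
  structure(list(genes = genes, scores = scores, n_excluded = 0L),
            class = "ranked_list")
}
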