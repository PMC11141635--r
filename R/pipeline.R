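#' Complex-level selective dependency screen
#'
#' The screen-arm pipeline in one call: two-class differential dependency
#' between the subgroup lines and all other lines, ranking of genes by
#' the moderated t-statistic, and preranked GSEA of the bundle's gene-set
#' collection (protein complexes plus decoys) on that ranking. Complexes
#' whose members are selectively required in the subgroup surface with
#' large negative NES.
#'
#' @param bundle A [generate_screen()] bundle, or a list with
#'   `dependency`, `annotations` (carrying a logical `subgroup` column)
#'   and `genesets`.
#' @param n_perm,weight_p,seed,min_size,max_size,fdr_method Passed to
#'   [gsea_preranked()].
#' @param d0 Moderation prior df passed to [two_class()] (default
#'   `NULL`: estimated).
#' @return List with `diffdep` (the [two_class()] table), `ranked` (the
#'   [rank_genes()] list) and `enrichment` (the [gsea_preranked()]
#'   table, sorted by increasing NES so the strongest selective
#'   dependencies come first).
#' @export
complex_dependency_screen <- function(bundle, n_perm = 1000, weight_p = 1,
                                      seed = 1L, min_size = 2,
                                      max_size = Inf,
                                      fdr_method = c("gsea", "bh"),
                                      d0 = NULL) {
  fdr_method <- match.arg(fdr_method)
  ann <- bundle$annotations
  in_lines <- ann$line[ann$subgroup]
  out_lines <- ann$line[!ann$subgroup]
  dd <- two_class(bundle$dependency, in_lines, out_lines, d0 = d0)
  ranked <- rank_genes(dd[!is.na(dd$t), ], score_col = "t")
  enr <- gsea_preranked(ranked, bundle$genesets, n_perm = n_perm,
                        weight_p = weight_p, seed = seed,
                        min_size = min_size, max_size = max_size,
                        fdr_method = fdr_method)
  enr <- enr[order(enr$NES), ]
  rownames(enr) <- NULL
  list(diffdep = dd, ranked = ranked, enrichment = enr)
}

#' Filter enrichment results at the conventional significance cutoffs
#'
#' Keeps gene sets with `|NES| >= nes_min`, nominal `p <= p_max` and
#' FDR `q <= q_max` (defaults 1.3 / 0.05 / 0.25, the usual GSEA hit
#' definition).
#'
#' @param enrichment A [gsea_preranked()] result table.
#' @param nes_min,p_max,q_max Cutoffs.
#' @return The filtered table.
#' @export
significant_enrichments <- function(enrichment, nes_min = 1.3,
                                    p_max = 0.05, q_max = 0.25) {
  keep <- !is.na(enrichment$NES) & abs(enrichment$NES) >= nes_min &
    !is.na(enrichment$p) & enrichment$p <= p_max &
    !is.na(enrichment$q) & enrichment$q <= q_max
  out <- enrichment[keep, ]
  rownames(out) <- NULL
  out
}
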