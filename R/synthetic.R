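# Seeded synthetic screens with the statistical structure the analysis
# pipeline assumes: a bimodal essential/non-essential dependency score
# distribution (essentials centered at -1, non-essentials at 0), an
# embedded subgroup-selective complex dependency of configurable effect
# size, MYCN copy-number/expression profiles spanning all classifier
# regimes, a paralog-redundancy link between one gene's dependency and
# another's expression, and region-level count fixtures with spike-in
# totals for the ChIP quantification stages.

#' Configuration for a synthetic dependency screen
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: 1000 genes of which 200 are common-essential, 100 cell
#' lines in two lineages (a 20-line subgroup standing in for
#' MYCN-amplified neuroblastoma and 80 other lines), Gaussian score noise
#' with sd 0.2 around per-class centers (-1 for essentials, 0 for
#' non-essentials), one embedded 8-gene complex whose members lose an
#' extra 0.6 score units in the subgroup, 30 decoy gene sets, and one
#' redundant paralog pair.
#'
#' @param n_genes Total genes in the universe.
#' @param n_common_essential Number of common-essential genes (the first
#'   `n_common_essential` genes of the universe).
#' @param lineages List of `list(name=, n_lines=, subgroup=)` entries;
#'   `subgroup = TRUE` marks the selective-dependency target subgroup.
#' @param essential_center,nonessential_center Score centers for the two
#'   gene classes (Chronos convention: essentials at -1, non-targets at 0).
#' @param noise_sd Gaussian sd of scores around their center.
#' @param embedded_complexes List of
#'   `list(name=, members=, target=, effect_size=)`; member scores in the
#'   target lines are shifted by `-effect_size`. `target` is `"subgroup"`
#'   or a lineage name.
#' @param n_genesets Number of decoy gene sets drawn from non-essential
#'   genes outside the embedded complexes.
#' @param geneset_size_range Length-2 integer range of decoy set sizes.
#' @param expr_mean_range Range of per-gene expression baselines,
#'   log2(TPM+1) units.
#' @param expr_sd Gaussian sd of expression around the gene baseline.
#' @param paralog_pairs List of `list(gene_a=, gene_b=, redundant=)`;
#'   for redundant pairs, `gene_a` dependency deepens linearly as
#'   `gene_b` expression decreases.
#' @param paralog_slope Score units of extra `gene_a` dependency per unit
#'   of `gene_b` expression below its mean (positive slope on centered
#'   expression, so low expression means a more negative score).
#' @param mycn_profile Optional data frame with columns `line`, `cn`
#'   (log2(CN/2+1)), `expr` (log2(TPM+1)), `reported` (one of
#'   `"amplified"`, `"not_amplified"`, `"none"`). When `NULL` a default
#'   profile is generated that covers all four classifier rules including
#'   exact boundary values at 1.10, 3 and 5.
#' @param seed Integer seed; fully determines the generated bundle.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_genes = 1000,
                          n_common_essential = 200,
                          lineages = list(
                            list(name = "NBL", n_lines = 20, subgroup = TRUE),
                            list(name = "other", n_lines = 80, subgroup = FALSE)
                          ),
                          essential_center = -1,
                          nonessential_center = 0,
                          noise_sd = 0.2,
                          embedded_complexes = list(
                            list(name = "EMBEDDED_COMPLEX",
                                 members = paste0("G", n_common_essential + 1:8),
                                 target = "subgroup",
                                 effect_size = 0.6)
                          ),
                          n_genesets = 30,
                          geneset_size_range = c(5, 15),
                          expr_mean_range = c(1, 8),
                          expr_sd = 1,
                          paralog_pairs = list(
                            list(gene_a = paste0("G", n_common_essential + 9),
                                 gene_b = paste0("G", n_common_essential + 10),
                                 redundant = TRUE)
                          ),
                          paralog_slope = 0.25,
                          mycn_profile = NULL,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_common_essential = as.integer(n_common_essential),
              lineages = lineages,
              essential_center = essential_center,
              nonessential_center = nonessential_center,
              noise_sd = noise_sd,
              embedded_complexes = embedded_complexes,
              n_genesets = as.integer(n_genesets),
              geneset_size_range = as.integer(geneset_size_range),
              expr_mean_range = expr_mean_range,
              expr_sd = expr_sd,
              paralog_pairs = paralog_pairs,
              paralog_slope = paralog_slope,
              mycn_profile = mycn_profile,
              seed = as.integer(seed))
  validate_screen_config(cfg)
  structure(cfg, class = "screen_config")
}

validate_screen_config <- function(cfg) {
  if (cfg$n_genes < 1L || cfg$n_common_essential < 0L ||
      cfg$n_common_essential > cfg$n_genes)
    stop("invalid gene counts in screen config")
  n_lines <- vapply(cfg$lineages, function(l) as.integer(l$n_lines), 1L)
  if (any(n_lines < 1L)) stop("lineage with zero lines")
  if (!any(vapply(cfg$lineages, function(l) isTRUE(l$subgroup), TRUE)) &&
      length(cfg$embedded_complexes) > 0L &&
      any(vapply(cfg$embedded_complexes,
                 function(e) identical(e$target, "subgroup"), TRUE)))
    stop("embedded complex targets 'subgroup' but no lineage is flagged as subgroup")
  genes <- paste0("G", seq_len(cfg$n_genes))
  for (e in cfg$embedded_complexes) {
    if (!all(e$members %in% genes))
      stop("embedded complex '", e$name, "' references unknown gene(s): ",
           paste(setdiff(e$members, genes), collapse = ", "))
    if (!is.finite(e$effect_size)) stop("non-finite effect size")
  }
  for (p in cfg$paralog_pairs)
    if (!all(c(p$gene_a, p$gene_b) %in% genes))
      stop("paralog pair references unknown gene(s)")
  invisible(cfg)
}

# Run expr with a locally seeded Mersenne-Twister RNG, restoring the
# caller's RNG state afterwards so generation never perturbs a session.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Default per-line MYCN evidence: subgroup lines amplified-like, others
# not-amplified-like, with the first lines pinned to the exact rule
# boundaries (cn = 3, cn = 1.10 with expr = 5, cn = 1.10 with expr < 3,
# rule-4 inconsistency, and the undetermined evidence gap).
default_mycn_profile <- function(line_ids, subgroup) {
  n <- length(line_ids)
  cn <- numeric(n); expr <- numeric(n)
  reported <- rep("none", n)
  sub_idx <- which(subgroup)
  oth_idx <- which(!subgroup)
  cn[sub_idx] <- stats::runif(length(sub_idx), 3.2, 5.5)
  expr[sub_idx] <- stats::runif(length(sub_idx), 5.5, 8)
  cn[oth_idx] <- stats::runif(length(oth_idx), 0.2, 1.0)
  expr[oth_idx] <- stats::runif(length(oth_idx), 0.5, 2.8)
  reported[oth_idx] <- sample(c("not_amplified", "none"), length(oth_idx),
                              replace = TRUE)
  # pin boundary/regime cases onto the first lines of each group
  if (length(sub_idx) >= 3) {
    cn[sub_idx[1]] <- 3;    expr[sub_idx[1]] <- 7          # rule 1 boundary
    cn[sub_idx[2]] <- 1.10; expr[sub_idx[2]] <- 5          # rule 2 boundary
    cn[sub_idx[3]] <- 2.0;  expr[sub_idx[3]] <- 6
    reported[sub_idx[3]] <- "amplified"
  }
  if (length(oth_idx) >= 3) {
    cn[oth_idx[1]] <- 1.10; expr[oth_idx[1]] <- 2.9        # rule 3
    cn[oth_idx[2]] <- 0.5;  expr[oth_idx[2]] <- 6          # rule 4
    reported[oth_idx[2]] <- "not_amplified"
    cn[oth_idx[3]] <- 2.0;  expr[oth_idx[3]] <- 4          # evidence gap
    reported[oth_idx[3]] <- "none"
  }
  data.frame(line = line_ids, cn = cn, expr = expr, reported = reported,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dependency screen bundle
#'
#' Draws a Chronos-like dependency matrix (per-gene Gaussian scores around
#' the class center), a log2(TPM+1) expression matrix, per-line MYCN
#' copy-number/expression/reported-status annotations, and a gene-set
#' collection containing the embedded complexes plus decoy sets. The
#' embedded effects are recorded in a `truth` block that analysis stages
#' never consume; it exists for recovery tests.
#'
#' @param config A [screen_config()].
#' @return A list of class `screen_bundle` with elements `dependency`
#'   (genes x lines matrix), `expression` (genes x lines matrix),
#'   `copy_number` (named per-line MYCN log2(CN/2+1)), `annotations`
#'   (data frame: line, lineage, subgroup, mycn_cn, mycn_expr,
#'   mycn_reported), `genesets` ([gene_set_collection()]) and `truth`.
#' @export
generate_screen <- function(config = screen_config()) {
  if (!inherits(config, "screen_config")) config <- do.call(screen_config, config)
  validate_screen_config(config)
  with_local_seed(config$seed, {
    genes <- paste0("G", seq_len(config$n_genes))
    essential <- genes[seq_len(config$n_common_essential)]
    lineage_names <- vapply(config$lineages, `[[`, "", "name")
    n_per <- vapply(config$lineages, function(l) as.integer(l$n_lines), 1L)
    lines <- unlist(mapply(function(nm, n) sprintf("%s_%02d", nm, seq_len(n)),
                           lineage_names, n_per, SIMPLIFY = FALSE),
                    use.names = FALSE)
    lineage <- rep(lineage_names, n_per)
    subgroup <- rep(vapply(config$lineages,
                           function(l) isTRUE(l$subgroup), TRUE), n_per)
    n_lines <- length(lines)

    center <- ifelse(genes %in% essential,
                     config$essential_center, config$nonessential_center)
    dep <- matrix(stats::rnorm(config$n_genes * n_lines, mean = center,
                               sd = config$noise_sd),
                  nrow = config$n_genes, dimnames = list(genes, lines))

    for (e in config$embedded_complexes) {
      target <- if (identical(e$target, "subgroup")) subgroup
                else lineage == e$target
      if (!any(target)) stop("embedded complex target has zero lines")
      dep[e$members, target] <- dep[e$members, target] - e$effect_size
    }

    mu <- stats::runif(config$n_genes, config$expr_mean_range[1],
                       config$expr_mean_range[2])
    expr <- matrix(stats::rnorm(config$n_genes * n_lines, mean = mu,
                                sd = config$expr_sd),
                   nrow = config$n_genes, dimnames = list(genes, lines))
    expr[expr < 0] <- 0

    for (p in config$paralog_pairs) {
      if (!isTRUE(p$redundant)) next
      eb <- expr[p$gene_b, ]
      dep[p$gene_a, ] <- config$nonessential_center +
        config$paralog_slope * (eb - mean(eb)) +
        stats::rnorm(n_lines, sd = config$noise_sd)
    }

    prof <- config$mycn_profile
    if (is.null(prof)) prof <- default_mycn_profile(lines, subgroup)
    if (!all(lines %in% prof$line)) stop("mycn_profile missing lines")
    prof <- prof[match(lines, prof$line), ]

    nonessential <- setdiff(genes, essential)
    embedded_members <- unique(unlist(lapply(config$embedded_complexes,
                                             `[[`, "members")))
    decoy_pool <- setdiff(nonessential, embedded_members)
    sets <- lapply(config$embedded_complexes, `[[`, "members")
    names(sets) <- vapply(config$embedded_complexes, `[[`, "", "name")
    if (config$n_genesets > 0L) {
      sizes <- sample(seq(config$geneset_size_range[1],
                          config$geneset_size_range[2]),
                      config$n_genesets, replace = TRUE)
      decoys <- lapply(sizes, function(k) sample(decoy_pool, k))
      names(decoys) <- sprintf("DECOY_%03d", seq_len(config$n_genesets))
      sets <- c(sets, decoys)
    }
    genesets <- gene_set_collection(sets)

    annotations <- data.frame(line = lines, lineage = lineage,
                              subgroup = subgroup,
                              mycn_cn = prof$cn, mycn_expr = prof$expr,
                              mycn_reported = prof$reported,
                              stringsAsFactors = FALSE)

    structure(list(
      dependency = dep,
      expression = expr,
      copy_number = stats::setNames(prof$cn, lines),
      annotations = annotations,
      genesets = genesets,
      truth = list(essential_genes = essential,
                   embedded_complexes = config$embedded_complexes,
                   paralog_pairs = config$paralog_pairs,
                   config = config)
    ), class = "screen_bundle")
  })
}

#' @export
print.screen_bundle <- function(x, ...) {
  cat("screen_bundle:", nrow(x$dependency), "genes x",
      ncol(x$dependency), "lines;",
      length(x$genesets), "gene sets;",
      sum(x$annotations$subgroup), "subgroup lines\n")
  invisible(x)
}

#' Write a screen bundle to a directory of delimited files
#'
#' Writes `dependency.tsv`, `expression.tsv`, `annotations.tsv`,
#' `genesets.gmt` and `truth_complexes.tsv` (the embedded-effect record).
#'
#' @param bundle A [generate_screen()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_screen_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "screen_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(bundle$dependency, file.path(dir, "dependency.tsv"))
  write_matrix(bundle$expression, file.path(dir, "expression.tsv"))
  write_result_table(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_gmt(bundle$genesets, file.path(dir, "genesets.gmt"))
  truth <- do.call(rbind, lapply(bundle$truth$embedded_complexes, function(e)
    data.frame(set = e$name, gene = e$members, target = e$target,
               effect_size = e$effect_size, stringsAsFactors = FALSE)))
  if (!is.null(truth))
    write_result_table(truth, file.path(dir, "truth_complexes.tsv"))
  invisible(dir)
}

#' Generate a region-signal fixture for the ChIP quantification stages
#'
#' Builds `n_regions` non-overlapping intervals on one chromosome with a
#' per-region baseline read count, `n_samples` control and `n_samples`
#' treated samples, multiplicative log-normal noise, a configurable
#' fold-change applied to the treated samples of the effect regions, and
#' per-sample spike-in totals.
#'
#' @param n_regions Number of regions.
#' @param n_samples Replicates per condition.
#' @param spikein_counts Per-sample spike-in read totals: a vector of
#'   length `2 * n_samples`, or a scalar mean from which per-sample totals
#'   are drawn with coefficient of variation `spikein_cv`.
#' @param effect_regions Integer indices of regions that change in the
#'   treated condition (default none).
#' @param fold_change Fold-change applied to effect regions in treated
#'   samples.
#' @param base_depth Mean baseline read count per region.
#' @param noise_sd Sd of log-normal multiplicative count noise
#'   (0 = deterministic counts).
#' @param spikein_cv Coefficient of variation for spike-in totals when
#'   `spikein_counts` is a scalar (0 = constant).
#' @param seed Integer seed.
#' @return A list with `regions` ([region_table()]), `counts` and `auc`
#'   (region x sample matrices), `spikein` (named per-sample totals),
#'   `groups` (named condition factor) and `effect_regions`.
#' @export
generate_region_fixture <- function(n_regions, n_samples, spikein_counts,
                                    effect_regions = integer(),
                                    fold_change = 4,
                                    base_depth = 1000,
                                    noise_sd = 0,
                                    spikein_cv = 0.2,
                                    seed = 1L) {
  if (n_samples < 1L) stop("need at least one sample per condition")
  if (any(spikein_counts <= 0)) stop("spike-in counts must be positive")
  if (length(effect_regions) && any(effect_regions > n_regions))
    stop("effect region index out of range")
  with_local_seed(seed, {
    samples <- c(sprintf("ctrl_%d", seq_len(n_samples)),
                 sprintf("trt_%d", seq_len(n_samples)))
    groups <- stats::setNames(rep(c("control", "treated"), each = n_samples),
                              samples)
    regions <- region_table(chrom = rep("chr1", n_regions),
                            start = (seq_len(n_regions) - 1) * 2000,
                            end = (seq_len(n_regions) - 1) * 2000 + 1000,
                            name = sprintf("region_%04d", seq_len(n_regions)))
    base <- rep(base_depth, n_regions)
    fc <- matrix(1, n_regions, 2 * n_samples, dimnames = list(regions$name, samples))
    if (length(effect_regions))
      fc[effect_regions, groups == "treated"] <- fold_change
    noise <- if (noise_sd > 0)
      matrix(exp(stats::rnorm(n_regions * 2 * n_samples, sd = noise_sd)),
             n_regions, 2 * n_samples)
    else matrix(1, n_regions, 2 * n_samples)
    counts <- round(base * fc * noise)
    dimnames(counts) <- list(regions$name, samples)
    auc <- counts  # AUC signal proportional to region read mass
    if (length(spikein_counts) == 1L) {
      spike <- if (spikein_cv > 0)
        round(spikein_counts * exp(stats::rnorm(2 * n_samples, sd = spikein_cv)))
      else rep(spikein_counts, 2 * n_samples)
    } else {
      if (length(spikein_counts) != 2 * n_samples)
        stop("spikein_counts must be scalar or length 2 * n_samples")
      spike <- spikein_counts
    }
    spike <- stats::setNames(pmax(1, round(spike)), samples)
    list(regions = regions, counts = counts, auc = auc,
         spikein = spike, groups = groups,
         effect_regions = as.integer(effect_regions))
  })
}
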