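# Readers/writers for the external formats the pipeline touches: GMT gene-set
# collections, delimited gene x cell-line matrices, and BED3/BED4 region
# tables. All downstream stages consume only the in-memory types returned
# here.

#' Construct a gene set collection
#'
#' A gene set collection maps set names to character vectors of gene
#' identifiers, with an optional one-line description per set. Duplicate
#' genes within a set are collapsed, keeping the first occurrence.
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled or named like `sets`.
#' @return An object of class `gene_set_collection` with elements `sets`
#'   (named list) and `descriptions` (named character).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list of gene identifier vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(sets) == 0L))
    stop("empty gene set: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  if (length(descriptions) == 1L) descriptions <- rep(descriptions, length(sets))
  stopifnot(length(descriptions) == length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x$sets), "sets;",
      "sizes", paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene set file
#'
#' One set per line: name, description, then one gene identifier per field,
#' tab-separated. Blank gene fields are dropped and within-set duplicates
#' collapsed (first occurrence kept), following the MSigDB dialect.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": expected >= 3 tab-separated fields, got ",
         lengths(fields)[bad[1L]])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Detect comma vs tab from the header line of a delimited matrix.
detect_delim <- function(header) {
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else if (n_com > 0L) "," else "\t"
}

#' Read a delimited numeric matrix (genes x cell lines)
#'
#' Expects a header row of column identifiers and a leading identifier
#' column. The delimiter (comma or tab) is auto-detected from the header.
#' Empty cells become `NA`; any other non-numeric cell is an error naming
#' its coordinates. With `orientation = "genes_cols"` the file is stored
#' lines-by-genes and is transposed on read, so rows are always genes.
#'
#' @param path Path to a CSV/TSV matrix.
#' @param orientation `"genes_rows"` (default) if file rows are genes,
#'   `"genes_cols"` if file rows are samples/cell lines.
#' @return A numeric matrix with gene row names and sample column names.
#' @export
read_matrix <- function(path, orientation = c("genes_rows", "genes_cols")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- detect_delim(header)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols))
    stop("duplicate column identifiers: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[!nzchar(trimws(raw))] <- NA_character_
  suppressWarnings(vals <- as.numeric(raw))
  bad <- which(is.na(vals) & !is.na(raw))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(raw)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(raw)) + 1L
    stop("non-numeric cell '", raw[bad[1L]], "' at row '", ids[i],
         "', column '", cols[j], "'")
  }
  m <- matrix(vals, nrow = nrow(raw), dimnames = list(ids, cols))
  if (orientation == "genes_cols") m <- t(m)
  m
}

#' Write a numeric matrix as TSV with an identifier column
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_name Name for the identifier column (default `"gene"`).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, id_name = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a region table
#'
#' Genomic intervals in the 0-based half-open convention used throughout
#' the package (the BED convention): a region covers bases
#' `start, ..., end - 1`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued coordinates, `0 <= start < end`.
#' @param name Optional region names (default `"."`).
#' @return A `data.frame` of class `region_table` with columns
#'   `chrom`, `start`, `end`, `name`.
#' @export
region_table <- function(chrom, start, end, name = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric region coordinates")
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end))
    stop("empty or inverted interval (start >= end) at record ",
         which(start >= end)[1L])
  if (is.null(name)) name <- rep(".", length(chrom))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = as.character(name), stringsAsFactors = FALSE)
  class(df) <- c("region_table", "data.frame")
  df
}

#' Read a BED3/BED4 file
#'
#' Tab-separated, at least three columns (chrom, start, end); a fourth
#' column is kept as the region name. Coordinates are 0-based half-open.
#'
#' @param path Path to a BED file.
#' @return A [region_table()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(region_table(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": expected >= 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", "")
  region_table(chrom, start, end, name)
}

#' Write a region table as BED
#'
#' Writes BED4 (BED3 if every name is `"."`). Round-tripping through
#' [read_bed()] is the identity on (chrom, start, end, name).
#'
#' @param regions A [region_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_table"))
  cols <- if (all(regions$name == ".")) regions[, 1:3] else regions[, 1:4]
  utils::write.table(format(cols, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal: region_table -> GRanges (0-based half-open -> 1-based closed).
as_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    name = regions$name
  )
}

# Internal: GRanges -> region_table.
from_granges <- function(gr) {
  nm <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  region_table(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr),
               nm)
}

#' Write a result table as TSV
#'
#' Column order is preserved as given; row names are dropped.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
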