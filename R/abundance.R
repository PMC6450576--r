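#' Construct an abundance table
#'
#' The central count container: a samples x features matrix of
#' non-negative integers plus per-feature metadata (`tier`, `genus`,
#' `taxon`). Features may be probes, reference taxa, or genera after
#' aggregation.
#'
#' @param counts integer matrix, rows = samples, columns = features, with
#'   dimnames.
#' @param feature_meta data.frame with columns `feature_id`, `tier`,
#'   `genus`, `taxon`; one row per feature, in column order of `counts`.
#'   If `NULL`, minimal metadata is synthesised from the column names.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(counts, feature_meta = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("counts must have feature (column) names")
  if (is.null(rownames(counts)))
    stop("counts must have sample (row) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate feature ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "integer"
  if (is.null(feature_meta))
    feature_meta <- data.frame(feature_id = colnames(counts), tier = NA_character_,
                               genus = NA_character_, taxon = colnames(counts),
                               stringsAsFactors = FALSE)
  if (ncol(counts) > 0) {
    stopifnot(identical(feature_meta$feature_id, colnames(counts)))
  } else {
    stopifnot(nrow(feature_meta) == 0)
  }
  rownames(feature_meta) <- NULL
  structure(list(counts = counts, feature_meta = feature_meta),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features, %s total counts\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname abundance_table
#' @export
feature_ids <- function(x) colnames(x$counts)

#' @rdname abundance_table
#' @export
sample_totals <- function(x) rowSums(x$counts)

#' Remove low-abundance features per sample
#'
#' Within each sample, any feature whose count is strictly below
#' `fraction` of that sample's total is zeroed (default 0.01% of the
#' summed per-sample value). Counts exactly at the threshold are kept.
#' Features left with zero counts in every sample are dropped. Applying
#' the filter twice with the same fraction changes nothing.
#'
#' @param x an `abundance_table`.
#' @param fraction per-sample relative-abundance threshold in \[0, 1).
#' @return filtered `abundance_table`.
#' @export
filter_low_abundance <- function(x, fraction = 1e-4) {
  stopifnot(fraction >= 0, fraction < 1)
  m <- x$counts
  thr <- rowSums(m) * fraction
  m[m < thr] <- 0L           # strict inequality: count == threshold survives
  keep <- colSums(m) > 0L
  abundance_table(m[, keep, drop = FALSE],
                  x$feature_meta[keep, , drop = FALSE])
}

#' Remove singleton features
#'
#' Drops features whose total count across all samples is at most one.
#'
#' @param x an `abundance_table`.
#' @return `abundance_table` without singleton (or all-zero) features.
#' @export
drop_singletons <- function(x) {
  keep <- colSums(x$counts) > 1L
  abundance_table(x$counts[, keep, drop = FALSE],
                  x$feature_meta[keep, , drop = FALSE])
}

#' Aggregate probe-level counts to genus level
#'
#' Genus-level results sum the species-tier features of each genus, then
#' add that genus's genus-tier feature counts. Per-sample totals are
#' conserved exactly.
#'
#' @param x an `abundance_table` whose features all carry a `genus`
#'   annotation.
#' @return genus-level `abundance_table` (features = genera,
#'   tier = "genus").
#' @export
aggregate_to_genus <- function(x) {
  g <- x$feature_meta$genus
  bad <- x$feature_meta$feature_id[is.na(g) | !nzchar(g)]
  if (length(bad))
    stop("features with no genus annotation: ", paste(bad, collapse = ", "))
  genera <- unique(g)
  m <- vapply(genera, function(gn)
    rowSums(x$counts[, g == gn, drop = FALSE]), numeric(nrow(x$counts)))
  m <- matrix(m, nrow = nrow(x$counts), dimnames = list(rownames(x$counts), genera))
  abundance_table(m, data.frame(feature_id = genera, tier = "genus",
                                genus = genera, taxon = genera,
                                stringsAsFactors = FALSE))
}

#' Rarefy samples to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads. Samples with fewer than `depth` total reads are dropped (their
#' ids are attached as attribute `dropped`). The same seed reproduces the
#' same table.
#'
#' @param x an `abundance_table`.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return rarefied `abundance_table` with attribute `dropped`.
#' @export
rarefy_table <- function(x, depth, seed = NULL) {
  if (depth <= 0) stop("rarefaction depth must be positive")
  tot <- sample_totals(x)
  keep <- tot >= depth
  dropped <- names(tot)[!keep]
  m <- x$counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    r <- m
    for (i in seq_len(nrow(m))) {
      if (sum(m[i, ]) == depth) next   # already at depth: unchanged
      picked <- sample.int(sum(m[i, ]), depth)
      r[i, ] <- tabulate(findInterval(picked - 1L, cumsum(m[i, ])) + 1L,
                         nbins = ncol(m))
    }
    r
  })
  res <- abundance_table(out, x$feature_meta)
  attr(res, "dropped") <- dropped
  res
}

#' Read and write abundance tables
#'
#' Two dialects: `tsv` (features as rows; columns `feature_id`, `tier`,
#' `genus`, `taxon`, then one column per sample) and `biom_v1_json`
#' (BIOM 1.0 JSON via the biomformat package, feature metadata stored as
#' observation metadata in the order tier, genus, taxon). Both round-trip
#' counts, ids and metadata losslessly.
#'
#' @param x an `abundance_table`.
#' @param path file path.
#' @param dialect `"tsv"` or `"biom_v1_json"`.
#' @return `write_abundance` returns `path` invisibly; `read_abundance`
#'   returns an `abundance_table`.
#' @export
write_abundance <- function(x, path, dialect = c("tsv", "biom_v1_json")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- cbind(x$feature_meta,
                 as.data.frame(t(x$counts), optional = TRUE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    om <- x$feature_meta[, c("tier", "genus", "taxon"), drop = FALSE]
    rownames(om) <- x$feature_meta$feature_id
    b <- biomformat::make_biom(t(x$counts), observation_metadata = om)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path, dialect = c("tsv", "biom_v1_json")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "character", quote = "")
    meta <- data.frame(feature_id = tab$feature_id, tier = tab$tier,
                       genus = tab$genus, taxon = tab$taxon,
                       stringsAsFactors = FALSE)
    scols <- setdiff(names(tab), c("feature_id", "tier", "genus", "taxon"))
    m <- t(vapply(scols, function(s) as.integer(tab[[s]]), integer(nrow(tab))))
    m <- matrix(m, nrow = length(scols),
                dimnames = list(scols, tab$feature_id))
    abundance_table(m, meta)
  } else {
    b <- biomformat::read_biom(path)
    m <- t(as(biomformat::biom_data(b), "matrix"))
    ## single-row/column matrices can come back without dimnames
    rownames(m) <- biomformat::colnames(b)
    colnames(m) <- biomformat::rownames(b)
    om <- biomformat::observation_metadata(b)
    meta <- data.frame(feature_id = colnames(m),
                       tier = as.character(om[[1]]),
                       genus = as.character(om[[2]]),
                       taxon = as.character(om[[3]]),
                       stringsAsFactors = FALSE)
    abundance_table(m, meta)
  }
}
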