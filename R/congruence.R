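#' Per-sample unassigned fractions for two classification arms
#'
#' The probe arm's unassigned reads (matching no probe) and the reference
#' arm's excluded reads (no hit at the identity threshold) expressed as
#' fractions of each sample's total, side by side.
#'
#' @param tallies list of `assignment_tally` (probe arm).
#' @param ref_excluded named per-sample excluded counts (reference arm).
#' @param ref_totals named per-sample total read counts (reference arm).
#' @return data.frame: `sample_id`, `probe_arm`, `reference_arm`.
#' @export
unassigned_profile <- function(tallies, ref_excluded, ref_totals) {
  if (inherits(tallies, "assignment_tally")) tallies <- list(tallies)
  ids <- vapply(tallies, `[[`, character(1), "sample_id")
  if (!setequal(ids, names(ref_excluded)) || !setequal(ids, names(ref_totals)))
    stop("sample sets differ between the two arms")
  probe_frac <- vapply(tallies, function(t) t$reads_unassigned / t$total_reads,
                       numeric(1))
  data.frame(sample_id = ids,
             probe_arm = probe_frac,
             reference_arm = unname(ref_excluded[ids] / ref_totals[ids]),
             stringsAsFactors = FALSE)
}

#' Paired genus-level profiles over a fixed label set
#'
#' Builds the label space as the `top_k` most abundant genera of one
#' reference sample under method A (the construction behind paired
#' composition bar charts), then expresses every sample of both methods
#' as relative abundances over those labels. Proportions are raw (not
#' renormalised to the shown labels); the per-sample coverage -- the
#' summed proportion falling on shown labels -- is reported instead.
#'
#' @param tA,tB genus-level `abundance_table`s over the same samples.
#' @param top_k number of genera to display (16 in the published maps).
#' @param reference_sample sample id whose method-A profile ranks the
#'   genera.
#' @return list with `labels`, `profiles` (long data.frame: sample_id,
#'   method, genus, proportion) and `coverage` (data.frame: sample_id,
#'   method, coverage).
#' @export
paired_genus_profiles <- function(tA, tB, top_k = 16L, reference_sample) {
  if (!setequal(rownames(tA$counts), rownames(tB$counts)))
    stop("the two tables cover different sample sets")
  if (!reference_sample %in% rownames(tA$counts))
    stop("reference sample not found: ", reference_sample)
  relA <- tA$counts / rowSums(tA$counts)
  relB <- tB$counts / rowSums(tB$counts)
  ref <- relA[reference_sample, ]
  labels <- names(sort(ref, decreasing = TRUE))[seq_len(min(top_k, ncol(relA)))]
  long <- function(rel, method) {
    got <- intersect(labels, colnames(rel))
    m <- matrix(0, nrow(rel), length(labels),
                dimnames = list(rownames(rel), labels))
    m[, got] <- rel[, got]
    data.frame(sample_id = rep(rownames(m), times = ncol(m)),
               method = method,
               genus = rep(colnames(m), each = nrow(m)),
               proportion = as.vector(m), stringsAsFactors = FALSE)
  }
  profiles <- rbind(long(relA, "A"), long(relB, "B"))
  cov <- stats::aggregate(proportion ~ sample_id + method, profiles, sum)
  names(cov)[3] <- "coverage"
  list(labels = labels, profiles = profiles, coverage = cov)
}

#' Map species labels to their covering probe
#'
#' Each species resolves to its dedicated species probe when one exists,
#' otherwise to the first genus probe listing it among its targets,
#' otherwise it is uncovered (many commensal taxa are reachable only
#' through genus-level probes).
#'
#' @param ps a `probe_set`.
#' @param species_labels character vector of species names.
#' @return data.frame: `species`, `coverage` (`"species-probe"`,
#'   `"genus-probe"`, `"uncovered"`), `probe_id` (NA when uncovered).
#' @export
coverage_map <- function(ps, species_labels) {
  p <- ps$probes
  out <- data.frame(species = species_labels,
                    coverage = "uncovered",
                    probe_id = NA_character_, stringsAsFactors = FALSE)
  sp <- p[p$level == "species", , drop = FALSE]
  ge <- p[p$level == "genus", , drop = FALSE]
  for (i in seq_along(species_labels)) {
    s <- species_labels[i]
    j <- which(vapply(sp$target_taxa, function(t) s %in% t, logical(1)))
    if (length(j)) {
      out$coverage[i] <- "species-probe"
      out$probe_id[i] <- sp$probe_id[j[1]]
      next
    }
    j <- which(vapply(ge$target_taxa, function(t) s %in% t, logical(1)))
    if (length(j)) {   # first listed genus probe wins when several cover s
      out$coverage[i] <- "genus-probe"
      out$probe_id[i] <- ge$probe_id[j[1]]
    }
  }
  out
}

## collapse a species-level table's features through the coverage map into
## probe-space labels; uncovered species are dropped
.collapse_by_coverage <- function(x, ps) {
  cm <- coverage_map(ps, x$feature_meta$taxon)
  keep <- cm$coverage != "uncovered"
  if (!any(keep)) stop("no feature is covered by any probe")
  m <- x$counts[, keep, drop = FALSE]
  lab <- cm$probe_id[keep]
  out <- vapply(unique(lab), function(l)
    rowSums(m[, lab == l, drop = FALSE]), numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), unique(lab)))
  abundance_table(out)
}

#' Per-sample agreement between two classification arms
#'
#' For each sample, relative abundances (over assigned reads only) of the
#' two methods are compared on their shared label space: Bray-Curtis
#' dissimilarity, the number of shared labels, and the summed absolute
#' proportion difference (twice the total variation distance).
#'
#' @param tA,tB `abundance_table`s over the same samples.
#' @param after_coverage_collapse collapse method A's species-level
#'   features through [coverage_map()] first so the label spaces match
#'   (requires `ps`).
#' @param ps the `probe_set`, when collapsing.
#' @return data.frame: `sample_id`, `bray_curtis`, `shared_labels`,
#'   `total_variation`.
#' @export
agreement_metrics <- function(tA, tB, after_coverage_collapse = FALSE, ps = NULL) {
  if (!setequal(rownames(tA$counts), rownames(tB$counts)))
    stop("the two tables cover different sample sets")
  if (after_coverage_collapse) {
    if (is.null(ps)) stop("coverage collapse requires the probe set")
    tA <- .collapse_by_coverage(tA, ps)
  }
  shared <- intersect(colnames(tA$counts), colnames(tB$counts))
  if (!length(shared)) stop("the two tables share no feature labels")
  ids <- rownames(tA$counts)
  out <- data.frame(sample_id = ids, bray_curtis = NA_real_,
                    shared_labels = length(shared),
                    total_variation = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    a <- tA$counts[ids[i], shared] / sum(tA$counts[ids[i], ])
    b <- tB$counts[ids[i], shared] / sum(tB$counts[ids[i], ])
    out$bray_curtis[i] <- as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
    out$total_variation[i] <- sum(abs(a - b))
  }
  out
}
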