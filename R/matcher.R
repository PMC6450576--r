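#' Build a two-tier probe matcher
#'
#' Compiles a probe set into per-tier pattern dictionaries for exact
#' substring search. Species probes form the first tier; only reads that
#' match no species probe are tested against the genus tier. With
#' `scan_reverse_complement = TRUE` (default) every probe is also searched
#' as its reverse complement, since the orientation of joined reads is not
#' guaranteed.
#'
#' @param ps a `probe_set`.
#' @param scan_reverse_complement also match probe reverse complements.
#' @return object of class `probe_matcher`.
#' @export
build_matcher <- function(ps, scan_reverse_complement = TRUE) {
  if (nrow(ps$probes) == 0L) stop("cannot build a matcher from an empty probe set")
  tier <- function(level) {
    p <- ps$probes[ps$probes$level == level, , drop = FALSE]
    list(probe_id = p$probe_id,
         fwd = Biostrings::DNAStringSet(p$sequence),
         rev = Biostrings::reverseComplement(Biostrings::DNAStringSet(p$sequence)))
  }
  structure(list(species = tier("species"), genus = tier("genus"),
                 scan_rc = isTRUE(scan_reverse_complement), probe_set = ps),
            class = "probe_matcher")
}

#' @export
print.probe_matcher <- function(x, ...) {
  cat(sprintf("probe_matcher: %d species-tier + %d genus-tier probes (reverse complement scan %s)\n",
              length(x$species$probe_id), length(x$genus$probe_id),
              if (x$scan_rc) "on" else "off"))
  invisible(x)
}

## reads x probes logical hit matrix for one tier
.tier_hits <- function(subject, tier, scan_rc) {
  np <- length(tier$probe_id)
  hits <- matrix(FALSE, length(subject), np, dimnames = list(NULL, tier$probe_id))
  for (j in seq_len(np)) {
    h <- Biostrings::vcountPattern(tier$fwd[[j]], subject, fixed = TRUE) > 0L
    if (scan_rc)
      h <- h | Biostrings::vcountPattern(tier$rev[[j]], subject, fixed = TRUE) > 0L
    hits[, j] <- h
  }
  hits
}

#' Classify reads against the two-tier probe set
#'
#' Every read is first searched for species-probe hits; a read with at
#' least one species hit is species-tier and is never tested against the
#' genus probes (tier precedence, which limits double counting between
#' tiers). Remaining reads with at least one genus hit are genus-tier;
#' the rest are unassigned. Under `policy = "all_matches"` (default) a
#' read increments every probe it matches within its tier; under
#' `policy = "unique"` it increments a probe only when it matches exactly
#' one probe in its tier, multi-hit reads being counted in the tier totals
#' but credited to no probe (reported as ambiguous).
#'
#' @param reads a `read_set` of joined, QC-passed reads.
#' @param idx a `probe_matcher`.
#' @param policy `"all_matches"` or `"unique"`.
#' @param sample_id label carried into the tally.
#' @return object of class `assignment_tally`: `probe_counts` (named
#'   integer vector over all probes), tier totals `reads_species_tier`,
#'   `reads_genus_tier`, `reads_unassigned`, `total_reads`, and
#'   `ambiguous` per tier (nonzero only under `policy = "unique"`).
#' @export
classify_sample <- function(reads, idx, policy = c("all_matches", "unique"),
                            sample_id = "sample") {
  policy <- match.arg(policy)
  subject <- Biostrings::DNAStringSet(reads$sequence)
  sp <- .tier_hits(subject, idx$species, idx$scan_rc)
  sp_any <- rowSums(sp) > 0L
  ge <- .tier_hits(subject[!sp_any], idx$genus, idx$scan_rc)
  ge_any <- rowSums(ge) > 0L

  credit <- function(hits, active) {
    if (policy == "unique") {
      uniq <- rowSums(hits) == 1L
      list(counts = colSums(hits[active & uniq, , drop = FALSE]),
           ambiguous = sum(active & !uniq & rowSums(hits) > 0L))
    } else {
      list(counts = colSums(hits[active, , drop = FALSE]), ambiguous = 0L)
    }
  }
  csp <- credit(sp, sp_any)
  cge <- credit(ge, ge_any)
  counts <- c(csp$counts, cge$counts)
  structure(list(sample_id = sample_id,
                 probe_counts = as.integer(counts) |> stats::setNames(names(counts)),
                 reads_species_tier = sum(sp_any),
                 reads_genus_tier = sum(ge_any),
                 reads_unassigned = length(subject) - sum(sp_any) - sum(ge_any),
                 total_reads = length(subject),
                 ambiguous = c(species = csp$ambiguous, genus = cge$ambiguous),
                 policy = policy),
            class = "assignment_tally")
}

#' @export
print.assignment_tally <- function(x, ...) {
  cat(sprintf("assignment_tally '%s': %d reads (%d species-tier, %d genus-tier, %d unassigned; policy %s)\n",
              x$sample_id, x$total_reads, x$reads_species_tier,
              x$reads_genus_tier, x$reads_unassigned, x$policy))
  invisible(x)
}

#' Probe-level abundance table from assignment tallies
#'
#' @param tallies list of `assignment_tally` (one per sample).
#' @param ps the `probe_set` used for classification (provides feature
#'   metadata: tier, genus, first target taxon).
#' @return an `abundance_table` with probes as features.
#' @export
tallies_to_table <- function(tallies, ps) {
  if (inherits(tallies, "assignment_tally")) tallies <- list(tallies)
  sample_ids <- vapply(tallies, `[[`, character(1), "sample_id")
  counts <- do.call(rbind, lapply(tallies, function(t)
    t$probe_counts[ps$probes$probe_id]))
  dimnames(counts) <- list(sample_ids, ps$probes$probe_id)
  counts[is.na(counts)] <- 0L
  meta <- data.frame(feature_id = ps$probes$probe_id,
                     tier = ps$probes$level,
                     genus = ps$probes$genus,
                     taxon = vapply(ps$probes$target_taxa, `[[`, character(1), 1),
                     stringsAsFactors = FALSE)
  abundance_table(counts, meta)
}

#' Per-sample read accounting
#'
#' Summarises tallies the way cumulative MiSeq library reports are laid
#' out: totals, species- and genus-tier assigned counts, unassigned
#' counts, and the corresponding percentages.
#'
#' @param tallies list of `assignment_tally`.
#' @return data.frame with one row per sample.
#' @export
read_accounting <- function(tallies) {
  if (inherits(tallies, "assignment_tally")) tallies <- list(tallies)
  out <- do.call(rbind, lapply(tallies, function(t) {
    data.frame(sample_id = t$sample_id,
               total_reads = t$total_reads,
               species_assigned = t$reads_species_tier,
               genus_assigned = t$reads_genus_tier,
               total_assigned = t$reads_species_tier + t$reads_genus_tier,
               unassigned = t$reads_unassigned,
               stringsAsFactors = FALSE)
  }))
  out$pct_species <- 100 * out$species_assigned / out$total_reads
  out$pct_genus <- 100 * out$genus_assigned / out$total_reads
  out$pct_assigned <- 100 * out$total_assigned / out$total_reads
  out$pct_unassigned <- 100 * out$unassigned / out$total_reads
  out
}
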