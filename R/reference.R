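#' Build a closed-reference index
#'
#' Loads a reference 16S FASTA plus a taxonomy TSV (`ref_id`, seven-rank
#' semicolon taxonomy) and builds a k-mer postings index used to shortlist
#' candidate references before alignment. Any reference sharing at least
#' one k-mer with a query is retrieved.
#'
#' @param fasta path to the reference FASTA, or a named character vector
#'   of sequences.
#' @param taxonomy path to a two-column TSV (`ref_id`, `taxonomy`), or a
#'   named character vector of taxonomy strings.
#' @param k k-mer size for the prefilter (default 12).
#' @return object of class `reference_db`.
#' @export
build_reference_index <- function(fasta, taxonomy, k = 12L) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else fasta
  tax <- if (is.character(taxonomy) && length(taxonomy) == 1L && file.exists(taxonomy)) {
    t <- read.delim(taxonomy, header = TRUE, colClasses = "character", quote = "")
    stats::setNames(t$taxonomy, t$ref_id)
  } else taxonomy
  if (anyDuplicated(names(seqs))) stop("duplicate ref_id in reference FASTA")
  missing <- setdiff(names(seqs), names(tax))
  if (length(missing))
    stop("reference record(s) without taxonomy: ", paste(missing, collapse = ", "))
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) character(0) else unique(substring(s, 1:(n - k + 1), k:n))
  })
  postings <- new.env(parent = emptyenv())
  for (i in seq_along(kmers)) {
    for (km in kmers[[i]]) {
      postings[[km]] <- c(postings[[km]], i)
    }
  }
  structure(list(ref_id = names(seqs), sequence = unname(seqs),
                 taxonomy = unname(tax[names(seqs)]), k = as.integer(k),
                 postings = postings),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d references, %d-mer prefilter\n",
              length(x$ref_id), x$k))
  invisible(x)
}

## candidate reference indices sharing >= 1 k-mer with the query
.candidates <- function(db, query) {
  n <- nchar(query)
  if (n < db$k) return(integer(0))
  kms <- unique(substring(query, 1:(n - db$k + 1), db$k:n))
  hits <- unlist(lapply(kms, function(km) db$postings[[km]]), use.names = FALSE)
  sort(unique(hits))
}

## percent-identity of an end-gap-free (overlap) global alignment:
## matches / alignment columns, internal gaps counted as mismatch columns
.alignment_identity <- function(refs, query) {
  ## match = 1, mismatch = 0: the alignment score is the number of matched
  ## columns, so extending the end-gap-free alignment never hurts and short
  ## perfect subregions cannot outscore a near-full-length alignment
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), query, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  ident <- Biostrings::pid(aln, type = "PID2") / 100
  ident[is.nan(ident)] <- 0   # empty overlap: nothing aligns
  ident
}

#' Closed-reference taxonomic assignment
#'
#' Assigns each read to the reference with the highest alignment identity,
#' provided that identity reaches `min_identity` (default 0.99); reads
#' below the threshold against every reference are excluded from all
#' downstream analyses, mirroring closed-reference OTU picking. Identity
#' is matches over alignment columns of an end-gap-free global alignment.
#' Ties at equal identity go to the reference earliest in file order (the
#' number of ties is reported). Candidate references are shortlisted by
#' shared k-mers; `exhaustive = TRUE` aligns every read against every
#' reference instead.
#'
#' @param reads a `read_set`, or a named list of `read_set`s (one per
#'   sample).
#' @param db a `reference_db`.
#' @param min_identity assignment threshold in (0, 1].
#' @param exhaustive bypass the k-mer prefilter.
#' @return list with `table` (an `abundance_table`, features = reference
#'   taxa), `excluded` (named per-sample counts), `ties` (count of
#'   equal-identity ties broken by file order).
#' @export
closed_reference_classify <- function(reads, db, min_identity = 0.99,
                                      exhaustive = FALSE) {
  stopifnot(min_identity > 0, min_identity <= 1)
  if (length(db$ref_id) == 0L) stop("empty reference database")
  if (inherits(reads, "read_set")) reads <- list(sample = reads)

  ties <- 0L
  classify_unique <- function(useq) {
    ## returns ref index or NA per unique sequence
    vapply(useq, function(q) {
      cand <- if (exhaustive) seq_along(db$ref_id) else .candidates(db, q)
      if (!length(cand)) return(NA_integer_)
      ident <- .alignment_identity(db$sequence[cand], q)
      best <- max(ident)
      if (best < min_identity) return(NA_integer_)
      hits <- cand[ident >= best - 1e-12]
      if (length(hits) > 1L) ties <<- ties + 1L
      min(hits)
    }, integer(1), USE.NAMES = FALSE)
  }

  nref <- length(db$ref_id)
  counts <- matrix(0L, length(reads), nref,
                   dimnames = list(names(reads), db$ref_id))
  excluded <- stats::setNames(integer(length(reads)), names(reads))
  for (s in seq_along(reads)) {
    seqs <- reads[[s]]$sequence
    useq <- unique(seqs)
    asg <- classify_unique(useq)[match(seqs, useq)]
    excluded[s] <- sum(is.na(asg))
    tab <- tabulate(asg[!is.na(asg)], nbins = nref)
    counts[s, ] <- tab
  }
  genus <- vapply(strsplit(db$taxonomy, ";", fixed = TRUE), function(r)
    trimws(r[min(6L, length(r))]), character(1))
  taxon <- vapply(strsplit(db$taxonomy, ";", fixed = TRUE), function(r)
    trimws(r[length(r)]), character(1))
  meta <- data.frame(feature_id = db$ref_id, tier = "reference",
                     genus = genus, taxon = taxon, stringsAsFactors = FALSE)
  list(table = abundance_table(counts, meta), excluded = excluded, ties = ties)
}
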