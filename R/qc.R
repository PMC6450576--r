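#' Quality-control parameters
#'
#' Defaults mirror the upstream pipeline settings: bases below Phred 25 are
#' "low-quality calls", and a read is rejected when it carries any
#' ambiguous base or a run of more than three consecutive low-quality
#' calls. A single isolated low-quality base does not reject a read.
#'
#' @param min_phred Phred threshold below which a base call counts as
#'   low quality (default 25).
#' @param max_consecutive_low longest tolerated run of low-quality calls
#'   (default 3; a run of 4 or more rejects the read).
#' @param reject_ambiguous reject reads containing any non-ACGT base
#'   (default `TRUE`).
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_phred = 25L, max_consecutive_low = 3L,
                      reject_ambiguous = TRUE) {
  stopifnot(min_phred >= 0, max_consecutive_low >= 0)
  structure(list(min_phred = as.integer(min_phred),
                 max_consecutive_low = as.integer(max_consecutive_low),
                 reject_ambiguous = isTRUE(reject_ambiguous)),
            class = "qc_params")
}

#' Paired-end join parameters
#'
#' Defaults follow the fastq-join conventions: minimum overlap 6 nt,
#' maximum mismatch fraction 8% within the overlap.
#'
#' @param min_overlap smallest acceptable overlap (nt).
#' @param max_mismatch_fraction largest tolerated mismatch fraction within
#'   the overlap.
#' @return list of class `join_params`.
#' @export
join_params <- function(min_overlap = 6L, max_mismatch_fraction = 0.08) {
  stopifnot(min_overlap >= 1, max_mismatch_fraction >= 0, max_mismatch_fraction <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_fraction = max_mismatch_fraction),
            class = "join_params")
}

#' Demultiplex reads by barcode
#'
#' Each read is assigned to the sample whose barcode lies within
#' `max_mismatch` Hamming distance of the read's barcode. A read matching
#' no map entry, or more than one (ambiguous), is left unmatched, so every
#' read lands in exactly one bucket.
#'
#' @param reads a `read_set`.
#' @param barcodes character vector of observed barcodes, one per read. If
#'   `NULL`, the barcode is taken as the final `:`-separated field of each
#'   read id (Illumina index convention).
#' @param barcode_map data.frame with columns `barcode`, `sample_id`
#'   (equal-length barcodes), or a named character vector
#'   (names = barcodes, values = sample ids).
#' @param max_mismatch maximum Hamming distance for a barcode match.
#' @return list with `samples` (named list of `read_set`), `unmatched`
#'   (count) and `unmatched_ids`.
#' @export
demultiplex <- function(reads, barcode_map, barcodes = NULL, max_mismatch = 0L) {
  if (!is.data.frame(barcode_map))
    barcode_map <- data.frame(barcode = names(barcode_map),
                              sample_id = unname(barcode_map),
                              stringsAsFactors = FALSE)
  bl <- nchar(barcode_map$barcode)
  if (length(unique(bl)) != 1L)
    stop("barcodes in the map must all have equal length")
  if (anyDuplicated(barcode_map$barcode))
    stop("duplicate barcodes in map")
  if (is.null(barcodes))
    barcodes <- sub("^.*:", "", reads$read_id)
  stopifnot(length(barcodes) == nrow(reads))

  map_raw <- lapply(barcode_map$barcode, charToRaw)
  assign_one <- function(bc) {
    if (nchar(bc) != bl[1]) return(NA_integer_)
    r <- charToRaw(bc)
    d <- vapply(map_raw, function(m) sum(m != r), integer(1))
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) hit else NA_integer_  # 0 or ambiguous -> unmatched
  }
  idx <- vapply(barcodes, assign_one, integer(1), USE.NAMES = FALSE)

  samples <- lapply(seq_len(nrow(barcode_map)), function(i) {
    sub <- reads[which(idx == i), , drop = FALSE]
    read_set(sub$read_id, sub$sequence, sub$quality)
  })
  names(samples) <- barcode_map$sample_id
  list(samples = samples,
       unmatched = sum(is.na(idx)),
       unmatched_ids = reads$read_id[is.na(idx)])
}

## Join one pair given raw byte vectors; returns NULL on failure.
.join_one <- function(s1, q1, s2rc, q2rev, min_overlap, max_mm) {
  n1 <- length(s1); n2 <- length(s2rc)
  omax <- min(n1, n2)
  if (omax < min_overlap) return(NULL)
  best_o <- 0L; best_f <- Inf
  for (o in min_overlap:omax) {
    mm <- sum(s1[(n1 - o + 1L):n1] != s2rc[1:o])
    f <- mm / o
    if (f <= max_mm && (f < best_f || (f == best_f && o > best_o))) {
      best_f <- f; best_o <- o
    }
  }
  if (best_o == 0L) return(NULL)
  o <- best_o
  i1 <- (n1 - o + 1L):n1
  i2 <- 1:o
  take2 <- q2rev[i2] > q1[i1]          # consensus base from the higher-Phred mate
  cons_s <- s1[i1]; cons_s[take2] <- s2rc[i2][take2]
  cons_q <- pmax(q1[i1], q2rev[i2])    # joined quality = max of the two
  tail2 <- if (o < n2) (o + 1L):n2 else integer(0)
  list(seq = c(s1[seq_len(n1 - o)], cons_s, s2rc[tail2]),
       qual = c(q1[seq_len(n1 - o)], cons_q, q2rev[tail2]),
       overlap = o)
}

#' Join paired-end reads
#'
#' The mate (`r2`) is reverse-complemented and slid against the forward
#' read; among overlaps of at least `min_overlap` nt with mismatch
#' fraction at most `max_mismatch_fraction`, the lowest-mismatch (ties:
#' longest) overlap wins. In the overlap the consensus base is taken from
#' the mate with the higher Phred score at that position and the joined
#' quality is the maximum of the two. Pairs with no acceptable overlap are
#' dropped and counted.
#'
#' @param r1,r2 `read_set`s of equal length, mates in order.
#' @param params a `join_params`.
#' @return list with `joined` (a `read_set`), `failed` (count) and
#'   `failed_ids`.
#' @export
join_pairs <- function(r1, r2, params = join_params()) {
  stopifnot(nrow(r1) == nrow(r2))
  n <- nrow(r1)
  s2rc_all <- revcomp(r2$sequence)
  out_seq <- character(n); out_qual <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    j <- .join_one(charToRaw(r1$sequence[i]),
                   as.integer(charToRaw(r1$quality[i])) - 33L,
                   charToRaw(s2rc_all[i]),
                   rev(as.integer(charToRaw(r2$quality[i])) - 33L),
                   params$min_overlap, params$max_mismatch_fraction)
    if (!is.null(j)) {
      ok[i] <- TRUE
      out_seq[i] <- rawToChar(as.raw(j$seq))
      out_qual[i] <- rawToChar(as.raw(j$qual + 33L))
    }
  }
  list(joined = read_set(r1$read_id[ok], out_seq[ok], out_qual[ok]),
       failed = sum(!ok),
       failed_ids = r1$read_id[!ok])
}

#' Quality-filter reads
#'
#' Rejects reads containing any ambiguous (non-ACGT) base, and reads
#' carrying a run of more than `max_consecutive_low` consecutive calls
#' below `min_phred`. Whole reads are rejected, never truncated. Every
#' input read ends up either kept or counted under exactly one rejection
#' reason, and filtering already-kept reads is a no-op.
#'
#' @param reads a `read_set`.
#' @param params a `qc_params`.
#' @return list with `kept` (a `read_set`) and `rejected` (named integer
#'   vector with reasons `ambiguous` and `low_quality_run`), plus
#'   `rejected_ids`.
#' @export
quality_filter <- function(reads, params = qc_params()) {
  n <- nrow(reads)
  ambig <- if (params$reject_ambiguous) grepl("[^ACGT]", reads$sequence) else rep(FALSE, n)
  lowrun <- logical(n)
  for (i in seq_len(n)) {
    if (ambig[i]) next
    q <- as.integer(charToRaw(reads$quality[i])) - 33L
    r <- rle(q < params$min_phred)
    lowrun[i] <- any(r$values & r$lengths > params$max_consecutive_low)
  }
  keep <- !ambig & !lowrun
  kept <- reads[keep, , drop = FALSE]
  list(kept = read_set(kept$read_id, kept$sequence, kept$quality),
       rejected = c(ambiguous = sum(ambig), low_quality_run = sum(lowrun)),
       rejected_ids = reads$read_id[!keep])
}
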