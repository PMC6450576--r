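#' Construct a set of sequencing reads
#'
#' Reads are held as a plain data.frame with one row per read: `read_id`,
#' `sequence` (may contain IUPAC ambiguity codes before quality filtering)
#' and `quality` (offset-33 ASCII Phred string, same length as the
#' sequence). Phred scores must lie in [0, 60].
#'
#' @param read_id character vector of identifiers.
#' @param sequence character vector of DNA sequences.
#' @param quality character vector of Phred+33 quality strings, or a list of
#'   integer Phred vectors.
#' @return object of class `read_set` (a data.frame).
#' @export
read_set <- function(read_id, sequence, quality) {
  if (is.list(quality)) quality <- phred_to_ascii(quality)
  stopifnot(length(read_id) == length(sequence), length(sequence) == length(quality))
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) != nchar(quality)))
    stop("sequence and quality lengths differ for read(s): ",
         paste(head(read_id[nchar(sequence) != nchar(quality)], 5), collapse = ", "))
  codes <- unlist(lapply(quality, function(q) as.integer(charToRaw(q))))
  if (length(codes) && (min(codes) < 33L || max(codes) > 93L))
    stop("Phred scores outside [0, 60] under offset-33 encoding; ",
         "offset-64 FASTQ input is not supported")
  structure(data.frame(read_id = as.character(read_id), sequence = sequence,
                       quality = as.character(quality), stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, lengths %s\n", nrow(x),
              if (nrow(x)) paste(range(nchar(x$sequence)), collapse = "-") else "-"))
  invisible(x)
}

#' Read a FASTQ file
#'
#' Gzip-transparent FASTQ reader (offset-33 qualities only; an input whose
#' quality codes imply offset 64 is refused rather than silently rescaled).
#'
#' @param path FASTQ path (optionally `.gz`).
#' @return `read_set`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_set(names(x), as.character(x),
           as.character(S4Vectors::mcols(x)$qualities))
}

#' @rdname read_fastq
#' @param reads a `read_set`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
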