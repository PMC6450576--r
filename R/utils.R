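#' @importFrom stats rmultinom sd cmdscale rbinom
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Strict ACGT(N/IUPAC) reverse complement, vectorised over character input.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Phred <-> ASCII (offset 33 only; see read_fastq for offset-64 refusal)
phred_to_ascii <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1), USE.NAMES = FALSE)
}

ascii_to_phred <- function(s) {
  lapply(s, function(v) as.integer(charToRaw(v)) - 33L)
}

## Run a block with a private, seeded RNG stream; global RNG state untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Largest-remainder apportionment of n into parts proportional to p.
## Guarantees sum(result) == n; ties on remainder broken by component order.
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), abs(sum(p) - 1) < 1e-9)
  quota <- n * p
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

## Deterministic per-stage seed derived from a global seed and a stage name,
## kept within 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}
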