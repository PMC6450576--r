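#' Construct a probe set
#'
#' A probe set is the knowledge base of the two-tier classifier: a collection
#' of short (17-40 nt) DNA subsequences diagnostic for oral taxa, each at
#' either species or genus level. Species probes report exactly one taxon;
#' genus probes typically list several congeneric species that lack a
#' species-specific probe.
#'
#' @param probes data.frame with columns `probe_id`, `level`
#'   (`"species"`/`"genus"`), `genus`, `target_taxa` (list column or
#'   semicolon-separated character), `sequence` (ACGT, 17-40 nt).
#' @param validate if `TRUE` (default), invariant violations raise an error.
#' @return object of class `probe_set`.
#' @export
probe_set <- function(probes, validate = TRUE) {
  stopifnot(is.data.frame(probes))
  need <- c("probe_id", "level", "genus", "target_taxa", "sequence")
  miss <- setdiff(need, names(probes))
  if (length(miss))
    stop("probe table is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.list(probes$target_taxa))
    probes$target_taxa <- strsplit(as.character(probes$target_taxa), ";", fixed = TRUE)
  probes$probe_id <- as.character(probes$probe_id)
  probes$level <- as.character(probes$level)
  probes$genus <- as.character(probes$genus)
  probes$sequence <- toupper(as.character(probes$sequence))
  ps <- structure(list(probes = probes), class = "probe_set")
  if (validate) {
    rep <- validate_probe_set(ps)
    if (length(rep$violations))
      stop("invalid probe set:\n  ", paste(rep$violations, collapse = "\n  "))
  }
  ps
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: %d probes (%d species-level, %d genus-level), %d genera\n",
              nrow(x$probes), species_count(x), genus_count(x),
              length(unique(x$probes$genus))))
  invisible(x)
}

#' @rdname probe_set
#' @param ps a `probe_set`.
#' @export
species_count <- function(ps) sum(ps$probes$level == "species")

#' @rdname probe_set
#' @export
genus_count <- function(ps) sum(ps$probes$level == "genus")

#' Validate a probe set
#'
#' Checks every structural invariant (length 17-40, ACGT-only alphabet --
#' degenerate IUPAC codes are rejected, no expansion rule is defined --,
#' unique probe ids, species probes with exactly one target, known levels,
#' no duplicated sequence within a level) and, separately, warns when a
#' genus probe's sequence duplicates or contains/is contained in a species
#' probe's sequence: such probes can double-count the same read across
#' tiers, over-representing those organisms.
#'
#' @param ps a `probe_set` (may be constructed with `validate = FALSE`).
#' @return list with character vectors `violations` and `warnings`; both
#'   empty iff the set is clean.
#' @export
validate_probe_set <- function(ps) {
  p <- ps$probes
  v <- character(0)
  w <- character(0)
  len <- nchar(p$sequence)
  bad_len <- which(len < 17 | len > 40)
  for (i in bad_len)
    v <- c(v, sprintf("probe %s: sequence length %d outside [17, 40]", p$probe_id[i], len[i]))
  bad_alpha <- which(grepl("[^ACGT]", p$sequence))
  for (i in bad_alpha)
    v <- c(v, sprintf("probe %s: sequence contains non-ACGT characters", p$probe_id[i]))
  dup_id <- unique(p$probe_id[duplicated(p$probe_id)])
  for (d in dup_id) v <- c(v, sprintf("duplicate probe_id: %s", d))
  bad_level <- which(!p$level %in% c("species", "genus"))
  for (i in bad_level)
    v <- c(v, sprintf("probe %s: unknown level '%s'", p$probe_id[i], p$level[i]))
  n_targets <- lengths(p$target_taxa)
  for (i in which(n_targets < 1))
    v <- c(v, sprintf("probe %s: no target taxa", p$probe_id[i]))
  for (i in which(p$level == "species" & n_targets != 1))
    v <- c(v, sprintf("probe %s: species probe must target exactly one taxon (has %d)",
                      p$probe_id[i], n_targets[i]))
  key <- paste(p$level, p$sequence)
  for (k in unique(key[duplicated(key)])) {
    ids <- p$probe_id[key == k]
    v <- c(v, sprintf("probes %s share level and sequence", paste(ids, collapse = ", ")))
  }
  ## cross-tier overlap: genus probe sequence inside (or equal to, or
  ## containing) a species probe sequence
  sp <- p[p$level == "species", , drop = FALSE]
  ge <- p[p$level == "genus", , drop = FALSE]
  if (nrow(sp) && nrow(ge)) {
    for (i in seq_len(nrow(ge))) {
      hit <- vapply(sp$sequence, function(s) {
        grepl(ge$sequence[i], s, fixed = TRUE) || grepl(s, ge$sequence[i], fixed = TRUE)
      }, logical(1))
      for (j in which(hit))
        w <- c(w, sprintf("genus probe %s overlaps species probe %s: reads may be over-represented",
                          ge$probe_id[i], sp$probe_id[j]))
    }
  }
  list(violations = v, warnings = w)
}

#' Read a probe table
#'
#' Probe tables are flat TSV files with header
#' `probe_id  level  genus  target_taxa  sequence`; `target_taxa` is
#' semicolon-separated.
#'
#' @param path path to a probe TSV.
#' @return validated `probe_set`.
#' @export
load_probe_set <- function(path) {
  if (!file.exists(path)) stop("probe table not found: ", path)
  tab <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
               quote = "", comment.char = ""),
    error = function(e) stop("failed to parse probe table ", path, ": ", conditionMessage(e))
  )
  need <- c("probe_id", "level", "genus", "target_taxa", "sequence")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("probe table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!nzchar(tab$sequence) | !nzchar(tab$probe_id))
  if (length(bad))
    stop("malformed probe table row (line ", bad[1] + 1L, "): empty probe_id or sequence")
  probe_set(tab[, need])
}

#' @rdname load_probe_set
#' @param ps a `probe_set`.
#' @param path output file path.
#' @export
write_probe_set <- function(ps, path) {
  p <- ps$probes
  out <- data.frame(probe_id = p$probe_id, level = p$level, genus = p$genus,
                    target_taxa = vapply(p$target_taxa, paste, character(1), collapse = ";"),
                    sequence = p$sequence, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export probe sequences as FASTA
#'
#' @param ps a `probe_set`.
#' @param path output FASTA path; probe ids become headers.
#' @export
write_probe_fasta <- function(ps, path) {
  x <- Biostrings::DNAStringSet(ps$probes$sequence)
  names(x) <- ps$probes$probe_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
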