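#' Generate a synthetic reference panel with probes, taxonomy and tree
#'
#' Builds the fixtures a mock-community experiment needs: amplicon-length
#' (441 nt by default) template sequences for `n_taxa` taxa spread over
#' `n_genera` genera, a probe set covering them, a reference database
#' with seven-rank taxonomy strings, and a genus-structured rooted tree.
#'
#' A fraction of taxa (`fraction_species_probes`, of the probe-covered
#' taxa) receives a dedicated species-level probe; every probe-covered
#' taxon also carries its genus's shared probe site, mirroring real probe
#' panels in which genus probes can match species-level sequences as
#' well. Taxa without a species probe are therefore reported only through
#' their genus probe. A further fraction (`fraction_probe_free`) of taxa
#' carries no probe site at all, producing unassigned reads at a designed
#' rate. Probe sequences are verified to occur nowhere (forward or
#' reverse complement) except at their designed sites; templates are
#' resampled on collision.
#'
#' @param n_taxa number of taxa (templates).
#' @param n_genera number of genera (taxa are distributed round-robin).
#' @param fraction_species_probes fraction of probe-covered taxa with a
#'   dedicated species probe.
#' @param fraction_probe_free fraction of taxa carrying no probe site.
#' @param seed integer seed; identical seeds give identical panels.
#' @param template_length template length in nt (default 441, the joined
#'   length of a 2 x 250 nt pair with 59 nt overlap).
#' @param probe_length_range min/max probe length; defaults 18-22 nt,
#'   typical oligonucleotide probe lengths (the validator accepts 17-40).
#' @return list of class `reference_panel`: `templates` (data.frame:
#'   taxon, genus, sequence, has_species_probe, probe_free), `probe_set`,
#'   `db` (a `reference_db`), `tree` (rooted `phylo`).
#' @export
generate_reference_set <- function(n_taxa, n_genera,
                                   fraction_species_probes = 0.7,
                                   fraction_probe_free = 0,
                                   seed = 1L,
                                   template_length = 441L,
                                   probe_length_range = c(18L, 22L)) {
  stopifnot(n_genera <= n_taxa, n_genera >= 1,
            fraction_species_probes >= 0, fraction_species_probes <= 1,
            fraction_probe_free >= 0, fraction_probe_free <= 1)
  n_free <- round(fraction_probe_free * n_taxa)
  if (n_taxa - n_free < 1 && fraction_probe_free < 1)
    stop("infeasible fractions: no probe-covered taxa left")
  with_seed(seed, {
    genus_names <- sprintf("Genus%02d", seq_len(n_genera))
    genus_of <- genus_names[(seq_len(n_taxa) - 1L) %% n_genera + 1L]
    taxon <- sprintf("%s_sp%02d", genus_of, seq_len(n_taxa))

    free <- rep(FALSE, n_taxa)
    if (n_free > 0) free[sample.int(n_taxa, n_free)] <- TRUE
    covered <- which(!free)
    n_sp <- round(fraction_species_probes * length(covered))
    has_sp <- rep(FALSE, n_taxa)
    if (n_sp > 0) has_sp[sample(covered, n_sp)] <- TRUE

    plen <- function() sample(probe_length_range[1]:probe_length_range[2], 1L)
    ## genus probe sequences: one shared site per genus with covered members
    genus_probe_seq <- stats::setNames(rep(NA_character_, n_genera), genus_names)
    for (g in genus_names) {
      if (any(!free & genus_of == g))
        genus_probe_seq[g] <- random_dna(1, plen())
    }
    sp_probe_seq <- rep(NA_character_, n_taxa)
    for (i in which(has_sp)) sp_probe_seq[i] <- random_dna(1, plen())

    ## templates: random backbone with probe sites spliced in fixed regions
    ## (species site in the first half, genus site in the second half)
    make_template <- function(i) {
      s <- random_dna(1, template_length)
      if (!free[i]) {
        gseq <- genus_probe_seq[genus_of[i]]
        gpos <- template_length - 120L
        substr(s, gpos, gpos + nchar(gseq) - 1L) <- gseq
        if (has_sp[i]) {
          pseq <- sp_probe_seq[i]
          substr(s, 60L, 60L + nchar(pseq) - 1L) <- pseq
        }
      }
      s
    }
    templates <- vapply(seq_len(n_taxa), make_template, character(1))

    ## collision control: a probe (either strand) may occur only at its
    ## designed sites; offending templates are resampled
    all_probes <- c(stats::na.omit(sp_probe_seq),
                    stats::na.omit(unname(genus_probe_seq)))
    count_occ <- function(p, s) {
      sum(gregexpr(p, s, fixed = TRUE)[[1]] > 0) +
        sum(gregexpr(revcomp(p), s, fixed = TRUE)[[1]] > 0)
    }
    ok_template <- function(i) {
      s <- templates[i]
      for (p in all_probes) {
        allowed <- !free[i] &&
          (identical(p, unname(genus_probe_seq[genus_of[i]])) ||
             (has_sp[i] && identical(p, sp_probe_seq[i])))
        n_occ <- count_occ(p, s)
        if (n_occ != if (allowed) 1L else 0L) return(FALSE)
      }
      TRUE
    }
    for (i in seq_len(n_taxa)) {
      tries <- 0L
      while (!ok_template(i)) {
        templates[i] <- make_template(i)
        tries <- tries + 1L
        if (tries > 100L) stop("could not place probe sites without collisions")
      }
    }
    if (anyDuplicated(templates)) stop("duplicate templates generated; use a longer template_length")

    ## probe table
    rows <- list()
    for (i in which(has_sp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = sprintf("sp_%03d", i), level = "species",
        genus = genus_of[i], target_taxa = taxon[i],
        sequence = sp_probe_seq[i], stringsAsFactors = FALSE)
    }
    for (g in genus_names) {
      if (is.na(genus_probe_seq[g])) next
      members <- taxon[!free & genus_of == g]
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = paste0("ge_", g), level = "genus", genus = g,
        target_taxa = paste(members, collapse = ";"),
        sequence = unname(genus_probe_seq[g]), stringsAsFactors = FALSE)
    }
    ps <- probe_set(do.call(rbind, rows))

    taxonomy <- sprintf("Bacteria;Phylum01;Class01;Order01;Family01;%s;%s",
                        genus_of, taxon)
    db <- build_reference_index(stats::setNames(templates, taxon),
                                stats::setNames(taxonomy, taxon))

    ## genus-structured rooted binary-backbone tree, random branch lengths
    subtrees <- vapply(genus_names, function(g) {
      tips <- taxon[genus_of == g]
      bl <- round(stats::runif(length(tips), 0.02, 0.2), 4)
      inner <- paste(sprintf("%s:%s", tips, bl), collapse = ",")
      if (length(tips) == 1L) sprintf("%s:%s", tips, bl)
      else sprintf("(%s):%s", inner, round(stats::runif(1, 0.05, 0.3), 4))
    }, character(1))
    newick <- Reduce(function(a, b)
      sprintf("(%s,%s):%s", a, b, round(stats::runif(1, 0.05, 0.3), 4)),
      subtrees)
    if (!startsWith(newick, "(")) newick <- sprintf("(%s)", newick)
    tree <- ape::read.tree(text = paste0(newick, ";"))

    structure(list(templates = data.frame(taxon = taxon, genus = genus_of,
                                          sequence = templates,
                                          has_species_probe = has_sp,
                                          probe_free = free,
                                          stringsAsFactors = FALSE),
                   probe_set = ps, db = db, tree = tree),
              class = "reference_panel")
  })
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d taxa / %d genera; %d species + %d genus probes; %d probe-free taxa\n",
              nrow(x$templates), length(unique(x$templates$genus)),
              species_count(x$probe_set), genus_count(x$probe_set),
              sum(x$templates$probe_free)))
  invisible(x)
}

#' Define a mixture of taxa at known proportions
#'
#' @param taxa character vector of taxon labels (must exist in the panel).
#' @param proportions positive, summing to 1 (within 1e-9).
#' @param n_reads total read pairs to emit.
#' @param error_rate substitution probability per sequenced base.
#' @param allocation `"exact"` (largest-remainder apportionment, read
#'   counts sum to `n_reads` exactly) or `"multinomial"` (seeded draw).
#' @param seed integer seed.
#' @param paper_style if `TRUE`, require 6-23 components, the range used
#'   for PCR-product validation mixtures.
#' @return list of class `mixture_design`.
#' @export
mixture_design <- function(taxa, proportions, n_reads, error_rate = 0,
                           allocation = c("exact", "multinomial"),
                           seed = 1L, paper_style = FALSE) {
  allocation <- match.arg(allocation)
  stopifnot(length(taxa) == length(proportions), all(proportions > 0))
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (anyDuplicated(taxa)) stop("duplicate taxa in design")
  if (paper_style && (length(taxa) < 6 || length(taxa) > 23))
    stop("validation-style mixtures use 6 to 23 components")
  structure(list(taxa = taxa, proportions = proportions,
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 allocation = allocation, seed = as.integer(seed)),
            class = "mixture_design")
}

## substitution errors with Phred 38 for correct calls, 15 at error sites
.sequence_read <- function(s, error_rate) {
  n <- nchar(s)
  qual <- rep(38L, n)
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate)
    if (length(err)) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (i in err) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
      s <- paste(ch, collapse = "")
      qual[err] <- 15L
    }
  }
  list(seq = s, qual = qual)
}

#' Simulate paired-end reads from a mixture
#'
#' Emits a paired-end library from the designed mixture: per-taxon read
#' counts by largest-remainder apportionment (`exact`) or a seeded
#' multinomial draw; each pair covers the full template (R1 = first
#' `read_length` nt, R2 = reverse complement of the last `read_length`
#' nt, so the designed overlap is `2 * read_length - template_length`).
#' Substitution errors are applied independently per sequenced base of
#' each mate; correct calls get Phred 38, error positions Phred 15.
#'
#' @param design a `mixture_design`.
#' @param panel a `reference_panel` (or a data.frame like its
#'   `templates` element).
#' @param read_length mate length in nt (default 250).
#' @return list of class `mock_library`: `r1`, `r2` (`read_set`s),
#'   `truth` (data.frame taxon, genus, probe_free, true_count,
#'   proportion), `design`.
#' @export
simulate_mixture <- function(design, panel, read_length = 250L) {
  templates <- if (inherits(panel, "reference_panel")) panel$templates else panel
  idx <- match(design$taxa, templates$taxon)
  if (anyNA(idx))
    stop("taxa absent from the panel: ",
         paste(design$taxa[is.na(idx)], collapse = ", "))
  tl <- unique(nchar(templates$sequence[idx]))
  if (length(tl) != 1L) stop("templates in a mixture must share one length")
  if (2L * read_length - tl < 1L)
    stop("read geometry mismatch: mates of ", read_length,
         " nt cannot overlap on a ", tl, " nt template")
  with_seed(design$seed, {
    counts <- if (design$allocation == "exact") {
      largest_remainder(design$n_reads, design$proportions)
    } else {
      as.integer(rmultinom(1, design$n_reads, design$proportions))
    }
    taxon_per_read <- rep(idx, counts)
    n <- length(taxon_per_read)
    comments <- templates$taxon[taxon_per_read]
    ids1 <- sprintf("read%06d/1 taxon=%s", seq_len(n), comments)
    ids2 <- sprintf("read%06d/2 taxon=%s", seq_len(n), comments)
    s1 <- character(n); q1 <- vector("list", n)
    s2 <- character(n); q2 <- vector("list", n)
    for (r in seq_len(n)) {
      tmpl <- templates$sequence[taxon_per_read[r]]
      m1 <- .sequence_read(substr(tmpl, 1L, read_length), design$error_rate)
      m2 <- .sequence_read(revcomp(substr(tmpl, tl - read_length + 1L, tl)),
                           design$error_rate)
      s1[r] <- m1$seq; q1[[r]] <- m1$qual
      s2[r] <- m2$seq; q2[[r]] <- m2$qual
    }
    truth <- data.frame(taxon = templates$taxon[idx],
                        genus = templates$genus[idx],
                        probe_free = templates$probe_free[idx],
                        true_count = counts,
                        proportion = design$proportions,
                        stringsAsFactors = FALSE)
    structure(list(r1 = read_set(ids1, s1, q1),
                   r2 = read_set(ids2, s2, q2),
                   truth = truth, design = design),
              class = "mock_library")
  })
}

#' @export
print.mock_library <- function(x, ...) {
  cat(sprintf("mock_library: %d read pairs from %d taxa (error rate %g, %s allocation)\n",
              nrow(x$r1), nrow(x$truth), x$design$error_rate,
              x$design$allocation))
  invisible(x)
}

#' Write all artifacts of a panel + library to a directory
#'
#' Paired FASTQ (gzipped), reference FASTA, taxonomy TSV, probe TSV,
#' newick tree, truth TSV and a key-value design manifest.
#'
#' @param panel a `reference_panel`.
#' @param lib a `mock_library` (optional).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_mock_artifacts <- function(panel, lib = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reference_fasta = file.path(dir, "reference.fasta"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    probes = file.path(dir, "probes.tsv"),
    tree = file.path(dir, "tree.nwk"))
  refs <- Biostrings::DNAStringSet(panel$templates$sequence)
  names(refs) <- panel$templates$taxon
  Biostrings::writeXStringSet(refs, paths["reference_fasta"])
  write.table(data.frame(ref_id = panel$db$ref_id, taxonomy = panel$db$taxonomy),
              paths["taxonomy"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_probe_set(panel$probe_set, paths["probes"])
  ape::write.tree(panel$tree, paths["tree"])
  if (!is.null(lib)) {
    paths <- c(paths,
               r1 = file.path(dir, "reads_R1.fastq.gz"),
               r2 = file.path(dir, "reads_R2.fastq.gz"),
               truth = file.path(dir, "truth.tsv"),
               manifest = file.path(dir, "design.txt"))
    write_fastq(lib$r1, paths["r1"])
    write_fastq(lib$r2, paths["r2"])
    write.table(lib$truth, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
    d <- lib$design
    writeLines(c(paste0("n_reads=", d$n_reads),
                 paste0("error_rate=", d$error_rate),
                 paste0("allocation=", d$allocation),
                 paste0("seed=", d$seed),
                 paste0("components=", length(d$taxa))),
               paths["manifest"])
  }
  paths
}
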