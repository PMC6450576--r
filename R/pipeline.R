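## Stage registry: allowed config keys with defaults (NA = required).
## Defaults follow the upstream pipeline settings: Phred 25 / run 3 QC,
## 0.01% abundance filter, 99% identity, 1,000 permutations.
.stage_defs <- list(
  simulate = list(out_dir = NA, n_taxa = 24L, n_genera = 8L,
                  fraction_species_probes = 0.7, fraction_probe_free = 0.2,
                  components = 12L, n_reads = 2000L, error_rate = 0,
                  allocation = "exact"),
  qc = list(r1 = NA, r2 = NA, out_fastq = NA, report = NA,
            min_phred = 25L, max_consecutive_low = 3L,
            min_overlap = 6L, max_mismatch_fraction = 0.08),
  `classify-probes` = list(fastq = NA, probes = NA, out_table = NA,
                           policy = "all_matches", sample_id = "sample",
                           scan_reverse_complement = TRUE),
  `classify-ref` = list(fastq = NA, reference = NA, taxonomy = NA,
                        out_table = NA, min_identity = 0.99,
                        sample_id = "sample"),
  table = list(in_table = NA, out_table = NA, filter_fraction = 1e-4,
               drop_singletons = TRUE, to_genus = FALSE, rarefy_depth = 0L),
  diversity = list(in_table = NA, tree = "", out_prefix = NA,
                   weighted = FALSE, min_depth = 100L, max_depth = 0L,
                   step = 2064L, reps = 10L),
  compare = list(table_a = NA, table_b = NA, out_table = NA)
)

.stage_config <- function(stage, config) {
  defs <- .stage_defs[[stage]]
  if (is.null(defs)) stop("unknown stage: ", stage)
  unknown <- setdiff(names(config), c(names(defs), "seed"))
  if (length(unknown))
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "))
  for (k in names(config)) defs[[k]] <- config[[k]]
  required <- names(defs)[vapply(defs, function(v) length(v) == 1 && is.na(v), logical(1))]
  if (length(required))
    stop("stage '", stage, "' requires config key(s): ",
         paste(required, collapse = ", "))
  defs
}

.write_manifest <- function(path, stage, cfg, seed) {
  writeLines(c(paste0("stage=", stage), paste0("stage_seed=", seed),
               vapply(names(cfg), function(k)
                 paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1))),
             path)
}

#' Run one pipeline stage
#'
#' Chains the package's operations behind a single config-driven entry
#' point. Stages: `simulate` (panel + mock library to a directory), `qc`
#' (join pairs, quality filter), `classify-probes`, `classify-ref`,
#' `table` (filter / singleton removal / genus aggregation / rarefaction),
#' `diversity` (alpha curves, UniFrac, PCoA), `compare` (per-sample
#' agreement of two tables). Unknown config keys are rejected; every
#' stage writes a `.manifest` of the parameters used; on error, partial
#' outputs of the stage are removed. Each stage draws its own seed from
#' the global seed and the stage name, so stages are independently
#' reproducible.
#'
#' @param stage stage name (see above).
#' @param config named list of stage parameters, or the path of a YAML
#'   file holding them.
#' @param seed global integer seed.
#' @return named character vector of written artifact paths, invisibly.
#' @export
run_stage <- function(stage, config = list(), seed = 1L) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (!is.null(config$seed)) seed <- config$seed
  cfg <- .stage_config(stage, config)
  stage_seed <- derive_seed(seed, stage)
  ## candidate output paths, so a failing stage can clean up partial files
  expected <- unlist(cfg[grepl("^(out_|report)", names(cfg))], use.names = FALSE)
  expected <- expected[nzchar(expected)]
  res <- tryCatch({
    outputs <- switch(
      stage,
      simulate = .stage_simulate(cfg, stage_seed),
      qc = .stage_qc(cfg),
      `classify-probes` = .stage_classify_probes(cfg),
      `classify-ref` = .stage_classify_ref(cfg),
      table = .stage_table(cfg, stage_seed),
      diversity = .stage_diversity(cfg, stage_seed),
      compare = .stage_compare(cfg))
    manifest <- paste0(outputs[[1]], ".manifest")
    .write_manifest(manifest, stage, cfg, stage_seed)
    c(outputs, manifest = manifest)
  }, error = function(e) {
    files <- expected[file.exists(expected) & !dir.exists(expected)]
    unlink(files)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

.stage_simulate <- function(cfg, seed) {
  panel <- generate_reference_set(cfg$n_taxa, cfg$n_genera,
                                  cfg$fraction_species_probes,
                                  cfg$fraction_probe_free,
                                  seed = seed)
  k <- min(cfg$components, cfg$n_taxa)
  props <- with_seed(derive_seed(seed, "proportions"), {
    taxa <- sample(panel$templates$taxon, k)
    w <- sort(exp(stats::runif(k, log(0.005), log(0.6))), decreasing = TRUE)
    list(taxa = taxa, p = w / sum(w))
  })
  design <- mixture_design(props$taxa, props$p, cfg$n_reads,
                           error_rate = cfg$error_rate,
                           allocation = cfg$allocation,
                           seed = derive_seed(seed, "reads"))
  lib <- simulate_mixture(design, panel)
  write_mock_artifacts(panel, lib, cfg$out_dir)
}

.stage_qc <- function(cfg) {
  r1 <- read_fastq(cfg$r1); r2 <- read_fastq(cfg$r2)
  j <- join_pairs(r1, r2, join_params(cfg$min_overlap, cfg$max_mismatch_fraction))
  qf <- quality_filter(j$joined, qc_params(cfg$min_phred, cfg$max_consecutive_low))
  write_fastq(qf$kept, cfg$out_fastq)
  rep <- data.frame(reason = c("join_failed", names(qf$rejected), "kept"),
                    count = c(j$failed, unname(qf$rejected), nrow(qf$kept)))
  write.table(rep, cfg$report, sep = "\t", quote = FALSE, row.names = FALSE)
  c(out_fastq = cfg$out_fastq, report = cfg$report)
}

.stage_classify_probes <- function(cfg) {
  reads <- read_fastq(cfg$fastq)
  ps <- load_probe_set(cfg$probes)
  idx <- build_matcher(ps, cfg$scan_reverse_complement)
  tally <- classify_sample(reads, idx, policy = cfg$policy,
                           sample_id = cfg$sample_id)
  write_abundance(tallies_to_table(list(tally), ps), cfg$out_table)
  acc <- read_accounting(list(tally))
  write.table(acc, paste0(cfg$out_table, ".accounting"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c(out_table = cfg$out_table,
    accounting = paste0(cfg$out_table, ".accounting"))
}

.stage_classify_ref <- function(cfg) {
  reads <- read_fastq(cfg$fastq)
  db <- build_reference_index(cfg$reference, cfg$taxonomy)
  res <- closed_reference_classify(stats::setNames(list(reads), cfg$sample_id),
                                   db, min_identity = cfg$min_identity)
  write_abundance(res$table, cfg$out_table)
  c(out_table = cfg$out_table)
}

.stage_table <- function(cfg, seed) {
  x <- read_abundance(cfg$in_table)
  if (cfg$filter_fraction > 0) x <- filter_low_abundance(x, cfg$filter_fraction)
  if (isTRUE(cfg$drop_singletons)) x <- drop_singletons(x)
  if (isTRUE(cfg$to_genus)) x <- aggregate_to_genus(x)
  if (cfg$rarefy_depth > 0) x <- rarefy_table(x, cfg$rarefy_depth, seed = seed)
  write_abundance(x, cfg$out_table)
  c(out_table = cfg$out_table)
}

.stage_diversity <- function(cfg, seed) {
  x <- read_abundance(cfg$in_table)
  max_depth <- if (cfg$max_depth > 0) cfg$max_depth else min(sample_totals(x))
  curves <- alpha_rarefaction(x, cfg$min_depth, max_depth, cfg$step,
                              reps = cfg$reps, seed = seed)
  curves_path <- paste0(cfg$out_prefix, "_alpha.tsv")
  write.table(curves, curves_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(alpha = curves_path)
  if (nzchar(cfg$tree) && nrow(x$counts) >= 2) {
    tree <- read_phylo_tree(cfg$tree)
    d <- unifrac(x, tree, weighted = isTRUE(cfg$weighted))
    d_path <- paste0(cfg$out_prefix, "_unifrac.tsv")
    write_distance_matrix(d, d_path)
    ord <- pcoa_ordination(d)
    ord_path <- paste0(cfg$out_prefix, "_pcoa.tsv")
    write.table(cbind(sample_id = rownames(ord$coordinates),
                      as.data.frame(ord$coordinates)),
                ord_path, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, unifrac = d_path, pcoa = ord_path)
  }
  out
}

.stage_compare <- function(cfg) {
  a <- read_abundance(cfg$table_a)
  b <- read_abundance(cfg$table_b)
  res <- agreement_metrics(a, b)
  write.table(res, cfg$out_table, sep = "\t", quote = FALSE, row.names = FALSE)
  c(out_table = cfg$out_table)
}

#' List available pipeline stages
#' @return character vector of stage names.
#' @export
pipeline_stages <- function() names(.stage_defs)
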