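## Shared fixtures and independent oracles for the test suite.

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE),
                                function(ch) paste(rev(ch), collapse = ""),
                                character(1)))
}

rand_seq <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

## small abundance table from a matrix (samples x features)
make_table <- function(m, genus = NULL, tier = NULL) {
  if (ncol(m) > 0 && is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  meta <- if (ncol(m) == 0) {
    data.frame(feature_id = character(0), tier = character(0),
               genus = character(0), taxon = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = colnames(m),
               tier = if (is.null(tier)) "species" else tier,
               genus = if (is.null(genus)) paste0("G", seq_len(ncol(m))) else genus,
               taxon = colnames(m), stringsAsFactors = FALSE)
  }
  abundance_table(m, meta)
}

## probe data.frame builder
probe_df <- function(probe_id, level, genus, target_taxa, sequence) {
  data.frame(probe_id = probe_id, level = level, genus = genus,
             target_taxa = target_taxa, sequence = sequence,
             stringsAsFactors = FALSE)
}

uniform_reads <- function(seqs, phred = 30L, prefix = "r") {
  read_set(paste0(prefix, seq_along(seqs)), seqs,
           lapply(nchar(seqs), function(n) rep(phred, n)))
}

## ---- independent oracles -------------------------------------------------

## Brute-force UniFrac: explicit loop over every branch, tips enumerated by
## naive recursion over the edge table. `ca`, `cb` are counts named by tip.
oracle_unifrac <- function(tree, ca, cb, weighted = FALSE, normalized = TRUE) {
  ntip <- length(tree$tip.label)
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  A <- ca / sum(ca); B <- cb / sum(cb)
  num <- den <- uniq <- unionl <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tl <- tree$tip.label[tips_under(tree$edge[k, 2])]
    bl <- tree$edge.length[k]
    if (weighted) {
      num <- num + bl * abs(sum(A[tl]) - sum(B[tl]))
      den <- den + bl * (sum(A[tl]) + sum(B[tl]))
    } else {
      pa <- sum(ca[tl]) > 0; pb <- sum(cb[tl]) > 0
      if (xor(pa, pb)) uniq <- uniq + bl
      if (pa || pb) unionl <- unionl + bl
    }
  }
  if (weighted) {
    if (normalized) num / den else num
  } else {
    if (unionl > 0) uniq / unionl else 0
  }
}

## Naive per-probe substring scan with species-first masking (grepl-based,
## independent of the Biostrings matching path).
oracle_classify <- function(seqs, probes, policy = "all_matches", rc = TRUE) {
  hit <- function(p) {
    h <- grepl(p, seqs, fixed = TRUE)
    if (rc) h <- h | grepl(rc_chr(p), seqs, fixed = TRUE)
    h
  }
  hits_for <- function(df) {
    if (!nrow(df)) return(matrix(FALSE, length(seqs), 0))
    m <- vapply(df$sequence, hit, logical(length(seqs)))
    matrix(m, nrow = length(seqs), dimnames = list(NULL, df$probe_id))
  }
  sp <- hits_for(probes[probes$level == "species", , drop = FALSE])
  ge <- hits_for(probes[probes$level == "genus", , drop = FALSE])
  sp_any <- rowSums(sp) > 0
  ge_eff <- ge & !sp_any            # species-first masking
  ge_any <- rowSums(ge_eff) > 0
  count_tier <- function(h) {
    if (policy == "unique") colSums(h & rowSums(h) == 1)
    else colSums(h)
  }
  list(species_tier = sum(sp_any), genus_tier = sum(ge_any),
       unassigned = length(seqs) - sum(sp_any) - sum(ge_any),
       counts = c(count_tier(sp), count_tier(ge_eff)))
}

## random rooted tree with branch lengths, tips labelled t1..tn
random_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
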