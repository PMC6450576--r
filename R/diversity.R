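#' Alpha diversity metrics
#'
#' `shannon` computes the Shannon index H = -sum p_i log2 p_i (bits by
#' default; set `base = exp(1)` for nats). `chao1` computes the
#' bias-corrected Chao1 richness estimate
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)), where F1 and F2 are the numbers of
#' singleton and doubleton features, a form defined even when no
#' doubletons are present. `observed_features` counts features with a
#' nonzero count.
#'
#' @param counts non-negative numeric vector of feature counts for one
#'   sample.
#' @param base logarithm base for `shannon` (default 2).
#' @return a single numeric value.
#' @export
shannon <- function(counts, base = 2) {
  tot <- sum(counts)
  if (tot <= 0) stop("Shannon index undefined for an all-zero sample")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
chao1 <- function(counts) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname shannon
#' @export
observed_features <- function(counts) sum(counts > 0)

#' Rarefaction depth schedule
#'
#' Arithmetic sequence from `min_depth` in steps of `step`, capped at
#' `max_depth`; `max_depth` is appended when the progression does not land
#' on it exactly (printed pipeline endpoints such as 100 to 20,640 by
#' 2,064 are not reachable by a pure progression).
#'
#' @param min_depth,max_depth,step integers, `min_depth <= max_depth`,
#'   `step >= 1`.
#' @return integer vector of depths.
#' @export
rarefaction_schedule <- function(min_depth, max_depth, step) {
  stopifnot(min_depth <= max_depth, step >= 1)
  d <- seq(from = min_depth, to = max_depth, by = step)
  if (d[length(d)] < max_depth) d <- c(d, max_depth)
  as.integer(d)
}

#' Alpha rarefaction curves
#'
#' For every depth in the schedule, each retained sample is rarefied
#' `reps` independent times and each metric summarised as mean and sd.
#' Samples whose total is below a given depth are omitted at that depth
#' (ids recorded in attribute `dropped`).
#'
#' @param x an `abundance_table`.
#' @param min_depth,max_depth,step schedule parameters (see
#'   [rarefaction_schedule()]).
#' @param reps rarefactions per depth (default 10).
#' @param seed integer seed; per-depth/rep substreams are derived from it.
#' @param metrics named list of metric functions on a count vector;
#'   default Shannon, Chao1 and observed features.
#' @return long data.frame: `depth`, `sample_id`, `metric`, `mean`, `sd`,
#'   `n_reps`.
#' @export
alpha_rarefaction <- function(x, min_depth, max_depth, step, reps = 10L,
                              seed = 1L,
                              metrics = list(shannon = shannon, chao1 = chao1,
                                             observed = observed_features)) {
  stopifnot(reps >= 1)
  depths <- rarefaction_schedule(min_depth, max_depth, step)
  dropped <- character(0)
  rows <- list()
  for (d in depths) {
    vals <- list()  # [[rep]] -> samples x metrics matrix
    for (r in seq_len(reps)) {
      rt <- rarefy_table(x, d, seed = derive_seed(seed, paste0("rarefy:", d, ":", r)))
      dropped <- union(dropped, attr(rt, "dropped"))
      vals[[r]] <- vapply(metrics, function(f) apply(rt$counts, 1, f),
                          numeric(nrow(rt$counts)))
      if (nrow(rt$counts) == 1L)
        vals[[r]] <- matrix(vals[[r]], nrow = 1,
                            dimnames = list(rownames(rt$counts), names(metrics)))
    }
    if (!nrow(vals[[1]])) next
    for (m in names(metrics)) {
      per_rep <- vapply(vals, function(v) v[, m], numeric(nrow(vals[[1]])))
      per_rep <- matrix(per_rep, nrow = nrow(vals[[1]]))
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, sample_id = rownames(vals[[1]]), metric = m,
        mean = rowMeans(per_rep), sd = apply(per_rep, 1, sd),
        n_reps = reps, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

## per-edge accumulated values: tips initialised from M (samples x tips),
## internal nodes summed child-up in postorder. Returns edges x samples.
.edge_values <- function(tree, M) {
  po <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  V <- matrix(0, nnode, nrow(M))
  V[seq_len(ntip), ] <- t(M[, tree$tip.label, drop = FALSE])
  for (k in seq_len(nrow(po$edge))) {
    V[po$edge[k, 1L], ] <- V[po$edge[k, 1L], ] + V[po$edge[k, 2L], ]
  }
  list(E = V[po$edge[, 2L], , drop = FALSE], bl = po$edge.length)
}

#' UniFrac distances
#'
#' Phylogenetic beta diversity between all sample pairs of a count table
#' over a rooted tree with branch lengths. Unweighted UniFrac is the
#' branch length unique to either sample's feature set divided by the
#' branch length covered by their union. Weighted UniFrac weights each
#' branch by the absolute difference in the proportion of each community
#' descending from it; the normalized variant (default) divides by the
#' abundance-weighted total branch length so both metrics live in [0, 1].
#'
#' @param x an `abundance_table`; every feature with a nonzero count must
#'   be a tip of `tree`.
#' @param tree a rooted `phylo` object with branch lengths.
#' @param weighted use abundance weighting.
#' @param normalized for weighted UniFrac, divide by the total
#'   abundance-weighted branch length (ignored when `weighted = FALSE`).
#' @return symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
unifrac <- function(x, tree, weighted = FALSE, normalized = TRUE) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  used <- colnames(x$counts)[colSums(x$counts) > 0]
  miss <- setdiff(used, tree$tip.label)
  if (length(miss))
    stop("feature(s) absent from the tree: ", paste(miss, collapse = ", "))
  ns <- nrow(x$counts)
  ## counts mapped onto the tip set (tips absent from the table count 0)
  M <- matrix(0, ns, length(tree$tip.label),
              dimnames = list(rownames(x$counts), tree$tip.label))
  common <- intersect(colnames(x$counts), tree$tip.label)
  M[, common] <- x$counts[, common]

  D <- matrix(0, ns, ns, dimnames = list(rownames(M), rownames(M)))
  if (weighted) {
    tot <- rowSums(M)
    if (any(tot == 0)) stop("weighted UniFrac undefined for empty samples")
    ev <- .edge_values(tree, M / tot)
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (j <= i) next
      num <- sum(ev$bl * abs(ev$E[, i] - ev$E[, j]))
      D[i, j] <- D[j, i] <- if (normalized)
        num / sum(ev$bl * (ev$E[, i] + ev$E[, j])) else num
    }
  } else {
    ev <- .edge_values(tree, (M > 0) * 1)
    P <- ev$E > 0
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (j <= i) next
      either <- P[, i] | P[, j]
      uniq <- xor(P[, i], P[, j])
      denom <- sum(ev$bl[either])
      D[i, j] <- D[j, i] <- if (denom > 0) sum(ev$bl[uniq]) / denom else 0
    }
  }
  D
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' squared-distance matrix. Coordinates are returned for axes with
#' positive eigenvalues; negative eigenvalues are retained in the
#' `eigenvalues` field (their axes carry no coordinates). Proportion
#' explained is relative to the sum of positive eigenvalues.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return object of class `ordination`: `coordinates` (samples x axes),
#'   `eigenvalues`, `proportion_explained`.
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(abs(eig)) * 1e-9)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = ifelse(eig > 0, eig / sum(eig[eig > 0]), 0)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d axes (first axis %.1f%% of positive inertia)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$proportion_explained[1]))
  invisible(x)
}

## center and scale a configuration to unit Frobenius norm
.procrustes_prep <- function(X) {
  X <- scale(X, center = TRUE, scale = FALSE)
  nrm <- sqrt(sum(X^2))
  if (nrm == 0) stop("degenerate configuration (all points coincide)")
  X / nrm
}

## symmetric Procrustes residual between prepped configurations:
## m^2 = 1 - (sum of singular values of X'Y)^2, optimal rotation/reflection
## and uniform scaling implicit
.m_squared <- function(Xp, Yp) {
  sv <- svd(crossprod(Xp, Yp))$d
  max(0, 1 - sum(sv)^2)
}

#' Procrustes comparison of two ordinations
#'
#' Superimposes two sample configurations by optimal translation, uniform
#' scaling and rotation (reflections allowed), after scaling both to unit
#' norm; the residual m^2 lies in [0, 1], with 0 meaning the
#' configurations are identical up to similarity transform. Significance
#' is a Monte Carlo permutation test: sample labels of the second
#' configuration are permuted and p = (# permutations with m^2 <=
#' observed + 1) / (n_perm + 1).
#'
#' @param a,b `ordination` objects (or coordinate matrices) over the same
#'   sample set; axes are truncated to the common count.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list of class `procrustes_fit`: `m_squared`, `p_value`,
#'   `n_permutations`.
#' @export
procrustes_compare <- function(a, b, n_perm = 1000L, seed = 1L) {
  A <- if (inherits(a, "ordination")) a$coordinates else as.matrix(a)
  B <- if (inherits(b, "ordination")) b$coordinates else as.matrix(b)
  if (is.null(rownames(A)) || is.null(rownames(B)))
    stop("configurations must carry sample ids as rownames")
  if (!setequal(rownames(A), rownames(B)))
    stop("sample sets differ between the two configurations")
  B <- B[rownames(A), , drop = FALSE]
  k <- min(ncol(A), ncol(B))
  Xp <- .procrustes_prep(A[, seq_len(k), drop = FALSE])
  Yp <- .procrustes_prep(B[, seq_len(k), drop = FALSE])
  m2 <- .m_squared(Xp, Yp)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      .m_squared(Xp, Yp[sample.int(nrow(Yp)), , drop = FALSE])
    }, numeric(1)) <= m2)
  })
  structure(list(m_squared = m2, p_value = (hits + 1) / (n_perm + 1),
                 n_permutations = as.integer(n_perm)),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Procrustes: m^2 = %.4g, p = %.4g (%d permutations)\n",
              x$m_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Tree and distance-matrix IO
#'
#' `read_phylo_tree` reads a rooted newick tree and insists on branch
#' lengths. `write_distance_matrix`/`read_distance_matrix` handle square
#' labelled TSVs.
#'
#' @param path file path.
#' @return `read_phylo_tree`: an ape `phylo`; `read_distance_matrix`: a
#'   symmetric matrix.
#' @export
read_phylo_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths: ", path)
  tr
}

#' @rdname read_phylo_tree
#' @param d symmetric matrix with dimnames.
#' @export
write_distance_matrix <- function(d, path) {
  write.table(cbind(sample_id = rownames(d), as.data.frame(d)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_phylo_tree
#' @export
read_distance_matrix <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$sample_id
  m
}
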