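test_that("alpha metrics match closed forms and hand computations", {
  expect_equal(shannon(rep(25, 4)), 2)          # uniform over 4 -> log2 4
  expect_equal(shannon(c(10, 0, 0)), 0)
  ## hand-computed: -(0.5 log2 0.5 + 0.3 log2 0.3 + 0.2 log2 0.2)
  expect_equal(shannon(c(50, 30, 20)), 1.4854753, tolerance = 1e-7)
  expect_equal(shannon(rep(10, 8), base = exp(1)), log(8))
  expect_error(shannon(c(0, 0)), "all-zero")

  expect_equal(chao1(c(5, 7, 9)), 3)            # no singletons -> S_obs
  ## S_obs = 10, F1 = 3, F2 = 2 -> 10 + 3*2 / (2*3) = 11
  expect_equal(chao1(c(1, 1, 1, 2, 2, 5, 6, 7, 8, 9)), 11)
  set.seed(12)
  for (i in 1:25) {
    x <- rpois(40, 2)
    if (sum(x) == 0) next
    expect_gte(chao1(x), observed_features(x))
  }

  expect_equal(observed_features(c(0, 0, 0)), 0)
  expect_equal(observed_features(c(0, 2, 0)), 1)
  x <- rpois(100, 1)
  expect_equal(observed_features(x), sum(vapply(x, function(v) v > 0, logical(1))))
})

test_that("rarefaction schedules follow the step-and-cap rule", {
  s <- rarefaction_schedule(100, 20640, 2064)
  expect_length(s, 11)
  expect_equal(s[1:3], c(100, 2164, 4228))
  expect_equal(s[10:11], c(18676, 20640))      # max appended, not reached by step

  s2 <- rarefaction_schedule(100, 21009, 2100)
  expect_equal(s2[length(s2)], 21009)
  expect_equal(diff(s2)[1], 2100)
  expect_length(s2, 11)

  expect_equal(rarefaction_schedule(10, 50, 20), c(10, 30, 50))  # lands exactly
})

test_that("alpha rarefaction at full depth with one rep equals the plain metric", {
  m <- matrix(c(12L, 30L, 8L, 0L, 20L, 10L, 10L, 10L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("f", 1:4)))
  tab <- make_table(m)
  cur <- alpha_rarefaction(tab, 50, 50, 10, reps = 1, seed = 1)
  sh <- cur[cur$metric == "shannon", ]
  expect_equal(sh$mean[sh$sample_id == "s1"], shannon(m[1, ]))
  expect_equal(sh$mean[sh$sample_id == "s2"], shannon(m[2, ]))
  ob <- cur[cur$metric == "observed", ]
  expect_equal(ob$mean, c(3, 4))
})

test_that("UniFrac trivial geometries behave", {
  tree <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  same <- make_table(matrix(c(3L, 1L, 0L, 2L, 3L, 1L, 0L, 2L), nrow = 2,
                            byrow = TRUE,
                            dimnames = list(c("a", "b"), paste0("t", 1:4))))
  expect_equal(unname(unifrac(same, tree)["a", "b"]), 0)
  expect_equal(unname(unifrac(same, tree, weighted = TRUE)["a", "b"]), 0)

  ## star tree, unit branches, disjoint sets -> unweighted 1
  disj <- make_table(matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 2L, 5L), nrow = 2,
                            byrow = TRUE,
                            dimnames = list(c("a", "b"), paste0("t", 1:4))))
  expect_equal(unname(unifrac(disj, tree)["a", "b"]), 1)
  expect_equal(unname(unifrac(disj, tree, weighted = TRUE)["a", "b"]), 1)

  bad <- make_table(matrix(c(1L, 1L), 1, dimnames = list("a", c("t1", "zz"))))
  expect_error(unifrac(bad, tree), "zz")
})

test_that("UniFrac equals the brute-force per-branch oracle on random trees", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(4:16, 1)
    tr <- random_tree(n)
    m <- matrix(rpois(2 * n, 1.2), nrow = 2,
                dimnames = list(c("a", "b"), tr$tip.label))
    if (any(rowSums(m) == 0)) next
    tab <- make_table(m)
    ca <- m["a", ]; cb <- m["b", ]
    expect_equal(unname(unifrac(tab, tr)["a", "b"]),
                 oracle_unifrac(tr, ca, cb), tolerance = 1e-12)
    expect_equal(unname(unifrac(tab, tr, weighted = TRUE)["a", "b"]),
                 oracle_unifrac(tr, ca, cb, weighted = TRUE), tolerance = 1e-12)
    expect_equal(unname(unifrac(tab, tr, weighted = TRUE, normalized = FALSE)["a", "b"]),
                 oracle_unifrac(tr, ca, cb, weighted = TRUE, normalized = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("UniFrac agrees with the phyloseq implementation", {
  set.seed(99)
  tr <- random_tree(8)
  m <- matrix(rpois(4 * 8, 2) + 1L, nrow = 4,
              dimnames = list(paste0("s", 1:4), tr$tip.label))
  tab <- make_table(m)
  phy <- phyloseq::phyloseq(phyloseq::otu_table(t(m), taxa_are_rows = TRUE), tr)
  expect_equal(as.matrix(phyloseq::UniFrac(phy, weighted = FALSE))[rownames(m), rownames(m)],
               unifrac(tab, tr), tolerance = 1e-10)
  expect_equal(as.matrix(phyloseq::UniFrac(phy, weighted = TRUE, normalized = TRUE))[rownames(m), rownames(m)],
               unifrac(tab, tr, weighted = TRUE), tolerance = 1e-10)
})

test_that("PCoA reconstructs Euclidean geometry and orders eigenvalues", {
  ## two samples at distance d separate by d on the first axis
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoa_ordination(d2)
  expect_equal(unname(abs(diff(ord2$coordinates[, 1]))), 3)

  set.seed(5)
  pts <- matrix(rnorm(12), ncol = 2,
                dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa_ordination(d)
  expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))

  asym <- d; asym[1, 2] <- asym[1, 2] + 1
  expect_error(pcoa_ordination(asym), "symmetric")
})

test_that("Procrustes recovers similarity transforms and respects relabeling", {
  set.seed(31)
  A <- matrix(rnorm(40), ncol = 2, dimnames = list(paste0("s", 1:20), NULL))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  B <- (A %*% R) * 2.5
  B <- sweep(B, 2, c(10, -4), "+")
  rownames(B) <- rownames(A)
  fit <- procrustes_compare(A, B, n_perm = 49, seed = 1)
  expect_lte(fit$m_squared, 1e-12)

  ## reflection is allowed
  Brefl <- B %*% diag(c(-1, 1)); rownames(Brefl) <- rownames(A)
  expect_lte(procrustes_compare(A, Brefl, n_perm = 9, seed = 1)$m_squared, 1e-12)

  ## relabeling both configurations identically leaves m^2 unchanged
  C <- matrix(rnorm(40), ncol = 2, dimnames = list(rownames(A), NULL))
  perm <- sample(20)
  m_orig <- procrustes_compare(A, C, n_perm = 9, seed = 1)$m_squared
  A2 <- A[perm, ]; C2 <- C[perm, ]
  expect_equal(procrustes_compare(A2, C2, n_perm = 9, seed = 1)$m_squared, m_orig)

  rownames(C) <- paste0("x", 1:20)
  expect_error(procrustes_compare(A, C), "sample sets")
})

test_that("Procrustes m^2 matches vegan's symmetric statistic", {
  set.seed(13)
  A <- matrix(rnorm(30), ncol = 2, dimnames = list(paste0("s", 1:15), NULL))
  B <- matrix(rnorm(30), ncol = 2, dimnames = list(paste0("s", 1:15), NULL))
  fit <- procrustes_compare(A, B, n_perm = 9, seed = 1)
  veg <- vegan::procrustes(A, B, symmetric = TRUE)
  expect_equal(fit$m_squared, veg$ss, tolerance = 1e-10)
})

test_that("trees and distance matrices round-trip through files", {
  tr <- random_tree(6)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- read_phylo_tree(f)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-8)

  d <- as.matrix(dist(matrix(rnorm(12), ncol = 2)))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  fd <- tempfile(fileext = ".tsv")
  write_distance_matrix(d, fd)
  expect_equal(read_distance_matrix(fd), d, tolerance = 1e-12)
})
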