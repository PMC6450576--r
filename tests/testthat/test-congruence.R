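tiny_tally <- function(id, unassigned, total) {
  structure(list(sample_id = id, probe_counts = integer(0),
                 reads_species_tier = total - unassigned, reads_genus_tier = 0L,
                 reads_unassigned = unassigned, total_reads = total,
                 ambiguous = c(species = 0L, genus = 0L), policy = "all_matches"),
            class = "assignment_tally")
}

test_that("unassigned fractions line up per sample across both arms", {
  tallies <- list(tiny_tally("s1", 15L, 100L), tiny_tally("s2", 0L, 50L))
  up <- unassigned_profile(tallies,
                           ref_excluded = c(s1 = 4, s2 = 10),
                           ref_totals = c(s1 = 100, s2 = 50))
  expect_equal(up$probe_arm, c(0.15, 0))
  expect_equal(up$reference_arm, c(0.04, 0.2))
  expect_error(unassigned_profile(tallies, c(s1 = 1, sX = 2),
                                  c(s1 = 10, sX = 10)),
               "differ")
})

test_that("paired genus profiles use the reference sample's top-k label space", {
  m <- matrix(c(50L, 30L, 15L, 5L,
                10L, 10L, 40L, 40L), nrow = 2, byrow = TRUE,
              dimnames = list(c("ref", "other"), c("g1", "g2", "g3", "g4")))
  tA <- make_table(m); tB <- make_table(m)

  pp <- paired_genus_profiles(tA, tB, top_k = 2, reference_sample = "ref")
  expect_equal(pp$labels, c("g1", "g2"))
  covA <- pp$coverage[pp$coverage$method == "A", ]
  expect_equal(covA$coverage[covA$sample_id == "ref"], 0.8)
  expect_equal(covA$coverage[covA$sample_id == "other"], 0.2)

  ## top_k >= all genera -> full coverage; identical tables, identical vectors
  full <- paired_genus_profiles(tA, tB, top_k = 10, reference_sample = "ref")
  expect_true(all(abs(full$coverage$coverage - 1) < 1e-12))
  a_side <- full$profiles[full$profiles$method == "A", ]
  b_side <- full$profiles[full$profiles$method == "B", ]
  expect_equal(a_side$proportion, b_side$proportion)

  expect_error(paired_genus_profiles(tA, tB, 2, reference_sample = "nope"),
               "nope")
})

test_that("coverage map resolves species to probes with species priority", {
  ps <- probe_set(probe_df(
    c("sp1", "ge1"), c("species", "genus"), c("G", "G"),
    c("G_a", "G_a;G_b"),
    c(strrep("AC", 10), strrep("GT", 10))))
  cm <- coverage_map(ps, c("G_a", "G_b", "G_c"))
  expect_equal(cm$coverage, c("species-probe", "genus-probe", "uncovered"))
  expect_equal(cm$probe_id, c("sp1", "ge1", NA))
})

test_that("agreement metrics match hand-computed Bray-Curtis and are symmetric", {
  a <- matrix(c(50L, 30L, 20L), 1, dimnames = list("s1", c("x", "y", "z")))
  b <- matrix(c(20L, 30L, 50L), 1, dimnames = list("s1", c("x", "y", "z")))
  tA <- make_table(a); tB <- make_table(b)
  am <- agreement_metrics(tA, tB)
  ## rel abundances (.5,.3,.2) vs (.2,.3,.5): sum|a-b| / sum(a+b) = 0.6/2
  expect_equal(am$bray_curtis, 0.3)
  expect_equal(am$total_variation, 0.6)
  expect_equal(am$shared_labels, 3)

  ## zero dissimilarity on identical tables; symmetry in method order
  expect_equal(agreement_metrics(tA, tA)$bray_curtis, 0)
  expect_equal(agreement_metrics(tB, tA)$bray_curtis, am$bray_curtis)

  dis <- make_table(matrix(1L, 1, 1, dimnames = list("s1", "other")))
  expect_error(agreement_metrics(tA, dis), "share no feature")
})

test_that("coverage collapse matches label spaces and ignores species ordering", {
  ps <- probe_set(probe_df(
    c("spA", "geG"), c("species", "genus"), c("G", "G"),
    c("G_a", "G_b;G_c"),
    c(strrep("AG", 10), strrep("TC", 10))))
  ## species-level arm: counts for G_a (species probe), G_b + G_c (genus probe)
  a <- matrix(c(40L, 25L, 15L), 1, dimnames = list("s1", c("G_a", "G_b", "G_c")))
  metaA <- data.frame(feature_id = colnames(a), tier = "reference",
                      genus = "G", taxon = colnames(a), stringsAsFactors = FALSE)
  tA <- abundance_table(a, metaA)
  ## probe-level arm
  b <- matrix(c(40L, 40L), 1, dimnames = list("s1", c("spA", "geG")))
  tB <- make_table(b)
  am <- agreement_metrics(tA, tB, after_coverage_collapse = TRUE, ps = ps)
  expect_equal(am$shared_labels, 2)
  expect_equal(am$bray_curtis, 0)   # 40 vs 40 and (25+15) vs 40

  ## permuting method-A species columns changes nothing
  perm <- c(3, 1, 2)
  tAp <- abundance_table(a[, perm, drop = FALSE], metaA[perm, ])
  expect_equal(agreement_metrics(tAp, tB, after_coverage_collapse = TRUE, ps = ps),
               am)
})

test_that("designed probe-free mass reappears as the probe-arm unassigned fraction", {
  panel <- generate_reference_set(15, 5, fraction_species_probes = 1,
                                  fraction_probe_free = 0.4, seed = 44)
  free <- panel$templates$taxon[panel$templates$probe_free]
  cov <- panel$templates$taxon[!panel$templates$probe_free]
  taxa <- c(cov[1:5], free[1:3])
  props <- c(rep(0.8 / 5, 5), rep(0.2 / 3, 3))
  lib <- simulate_mixture(mixture_design(taxa, props, 1000, seed = 3), panel)
  reads <- join_pairs(lib$r1, lib$r2)$joined
  tal <- classify_sample(reads, build_matcher(panel$probe_set), sample_id = "m")
  expect_equal(tal$reads_unassigned / tal$total_reads, 0.2, tolerance = 1e-9)
})
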