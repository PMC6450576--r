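test_that("reference panels are seeded, probe-covered, and internally consistent", {
  p1 <- generate_reference_set(12, 4, fraction_probe_free = 0, seed = 3)
  p2 <- generate_reference_set(12, 4, fraction_probe_free = 0, seed = 3)
  expect_identical(p1$templates, p2$templates)
  expect_identical(p1$probe_set$probes, p2$probe_set$probes)
  expect_identical(ape::write.tree(p1$tree), ape::write.tree(p2$tree))

  ## every template carries at least one probe site when none are probe-free
  probes <- p1$probe_set$probes$sequence
  hit <- vapply(p1$templates$sequence, function(s)
    any(vapply(probes, function(p) grepl(p, s, fixed = TRUE), logical(1))),
    logical(1))
  expect_true(all(hit))

  ## probe-free templates contain no probe sequence on either strand
  pf <- generate_reference_set(15, 5, fraction_probe_free = 0.4, seed = 6)
  probes <- pf$probe_set$probes$sequence
  free_seqs <- pf$templates$sequence[pf$templates$probe_free]
  expect_true(length(free_seqs) > 0)
  clean <- vapply(free_seqs, function(s)
    !any(vapply(probes, function(p)
      grepl(p, s, fixed = TRUE) || grepl(rc_chr(p), s, fixed = TRUE),
      logical(1))),
    logical(1))
  expect_true(all(clean))

  ## tree leaves are exactly the taxa; all probes pass validation
  expect_setequal(p1$tree$tip.label, p1$templates$taxon)
  expect_length(validate_probe_set(p1$probe_set)$violations, 0)
})

test_that("full species-probe coverage leaves genus probes uncredited on clean reads", {
  panel <- generate_reference_set(12, 4, fraction_species_probes = 1,
                                  fraction_probe_free = 0, seed = 10)
  des <- mixture_design(panel$templates$taxon[1:6], rep(1/6, 6),
                        n_reads = 120, seed = 2)
  lib <- simulate_mixture(des, panel)
  reads <- join_pairs(lib$r1, lib$r2)$joined
  tal <- classify_sample(reads, build_matcher(panel$probe_set))
  expect_equal(tal$reads_genus_tier, 0)
  expect_equal(tal$reads_unassigned, 0)
})

test_that("exact allocation follows the largest-remainder rule", {
  expect_equal(probetax:::largest_remainder(1000, c(0.5, 0.5)), c(500L, 500L))
  expect_equal(probetax:::largest_remainder(10000, c(0.008, 0.992)),
               c(80L, 9920L))
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    p <- runif(k); p <- p / sum(p)
    n <- sample(50:5000, 1)
    a <- probetax:::largest_remainder(n, p)
    expect_equal(sum(a), n)
    expect_true(all(abs(a - n * p) < 1))
  }
})

test_that("error-free libraries are exact template substrings with designed truth", {
  panel <- generate_reference_set(10, 5, fraction_probe_free = 0, seed = 8)
  taxa <- panel$templates$taxon[c(1, 4, 7)]
  des <- mixture_design(taxa, c(0.5, 0.3, 0.2), n_reads = 200, seed = 4)
  lib <- simulate_mixture(des, panel)
  expect_equal(lib$truth$true_count, c(100L, 60L, 40L))
  expect_equal(sum(lib$truth$true_count), nrow(lib$r1))

  tmpl <- setNames(panel$templates$sequence, panel$templates$taxon)
  src <- sub("^.*taxon=", "", lib$r1$read_id)
  expect_true(all(substr(tmpl[src], 1, 250) == lib$r1$sequence))
  expect_true(all(rc_chr(substr(tmpl[src], 192, 441)) == lib$r2$sequence))

  ## multinomial allocation is seeded and conserves totals
  des_m <- mixture_design(taxa, c(0.5, 0.3, 0.2), n_reads = 200,
                          allocation = "multinomial", seed = 4)
  lib_m1 <- simulate_mixture(des_m, panel)
  lib_m2 <- simulate_mixture(des_m, panel)
  expect_identical(lib_m1$truth$true_count, lib_m2$truth$true_count)
  expect_equal(sum(lib_m1$truth$true_count), 200)

  expect_error(simulate_mixture(des, panel, read_length = 100), "geometry")
  expect_error(mixture_design(taxa, c(0.5, 0.5, 0.2), 100), "sum to 1")
  expect_error(mixture_design(taxa[1:3], c(0.4, 0.3, 0.3), 100, paper_style = TRUE),
               "6 to 23")
})

test_that("simulated substitution errors carry low Phred scores at error sites", {
  panel <- generate_reference_set(6, 2, fraction_probe_free = 0, seed = 5)
  des <- mixture_design(panel$templates$taxon[1:2], c(0.5, 0.5),
                        n_reads = 60, error_rate = 0.05, seed = 9)
  lib <- simulate_mixture(des, panel)
  tmpl <- setNames(panel$templates$sequence, panel$templates$taxon)
  src <- sub("^.*taxon=", "", lib$r1$read_id)
  for (i in seq_len(10)) {
    truth <- substr(tmpl[src[i]], 1, 250)
    obs <- lib$r1$sequence[i]
    q <- as.integer(charToRaw(lib$r1$quality[i])) - 33L
    mism <- which(strsplit(truth, "")[[1]] != strsplit(obs, "")[[1]])
    expect_true(all(q[mism] == 15L))
    expect_true(all(q[setdiff(seq_along(q), mism)] == 38L))
  }
})

test_that("mock artifacts are written and re-loadable, reproducing the panel", {
  panel <- generate_reference_set(8, 4, fraction_probe_free = 0.25, seed = 12)
  des <- mixture_design(panel$templates$taxon[1:6], rep(1/6, 6),
                        n_reads = 60, seed = 1)
  lib <- simulate_mixture(des, panel)
  dir <- tempfile()
  paths <- write_mock_artifacts(panel, lib, dir)
  expect_true(all(file.exists(paths)))

  ps <- load_probe_set(paths["probes"])
  expect_identical(ps$probes, panel$probe_set$probes)
  db <- build_reference_index(paths["reference_fasta"], paths["taxonomy"])
  expect_identical(db$sequence, panel$db$sequence)
  tr <- read_phylo_tree(paths["tree"])
  expect_setequal(tr$tip.label, panel$templates$taxon)
  r1 <- read_fastq(paths["r1"])
  expect_equal(r1$sequence, lib$r1$sequence)
  expect_equal(r1$quality, lib$r1$quality)
})
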