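test_that("MPD and MNTD match hand values and brute-force loops", {
  # explicit 3-tip distance matrix: pairwise d = (2, 4, 6)
  D <- matrix(c(0, 2, 6,
                2, 0, 4,
                6, 4, 0), 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  expect_equal(mpd(c("a", "b", "c"), D), 4)
  # nearest-taxon distances: a->b 2, b->a 2, c->b 4
  expect_equal(mntd(c("a", "b", "c"), D), 8 / 3)

  # two members: both metrics are the pairwise distance
  expect_equal(mpd(c("a", "c"), D), 6)
  expect_equal(mntd(c("a", "c"), D), 6)

  # random communities on a random tree vs explicit double loops
  set.seed(23)
  tr <- ape::rtree(40)
  Dt <- cophenetic_distances(tr)
  for (i in 1:25) {
    comm <- sample(tr$tip.label, 15)
    expect_equal(mpd(comm, Dt), brute_force_mpd(comm, Dt))
    expect_equal(mntd(comm, Dt), brute_force_mntd(comm, Dt))
    expect_lte(mntd(comm, Dt), mpd(comm, Dt))
  }

  expect_error(mpd("a", D), ">= 2")
  expect_error(mpd(c("a", "zz"), D), "not in distance matrix")
})

test_that("abundance weighting recovers the unweighted metrics at equal weights", {
  set.seed(24)
  tr <- ape::rtree(20)
  D <- cophenetic_distances(tr)
  comm <- sample(tr$tip.label, 8)
  w_eq <- stats::setNames(rep(2, 8), comm)
  expect_equal(mpd(comm, D, weights = w_eq), mpd(comm, D))
  expect_equal(mntd(comm, D, weights = w_eq), mntd(comm, D))
  # skewed weights pull MPD toward the dominant pair's distance
  w <- stats::setNames(c(100, 100, rep(1e-6, 6)), comm)
  expect_equal(mpd(comm, D, weights = w), D[comm[1], comm[2]],
               tolerance = 1e-3)
})

test_that("SES under the tip-shuffle null is calibrated and reproducible", {
  tr <- simulate_yule_tree(48, 1, seed = 30)
  D <- cophenetic_distances(tr)

  # whole-pool community: shuffle-invariant, SES = 0, degenerate flag
  res <- ses_phylo(tr$tip.label, D, "MPD", n_permutations = 99, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$ses, 0)

  # reproducibility
  comm <- sample(tr$tip.label, 12)
  r1 <- ses_phylo(comm, D, "MNTD", n_permutations = 199, seed = 7)
  r2 <- ses_phylo(comm, D, "MNTD", n_permutations = 199, seed = 7)
  expect_equal(r1, r2)
  expect_equal(r1$ses, (r1$observed - r1$null_mean) / r1$null_sd)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)

  # SES invariant to uniform branch-length scaling
  D10 <- D * 10
  r10 <- ses_phylo(comm, D10, "MNTD", n_permutations = 199, seed = 7)
  expect_equal(r10$ses, r1$ses, tolerance = 1e-9)
  expect_equal(r10$p_value, r1$p_value)

  expect_error(ses_phylo(comm, D, n_permutations = 50), ">= 99")
})

test_that("filtered communities score negative SES, random near zero", {
  tr <- simulate_yule_tree(64, 1, seed = 31)
  D <- cophenetic_distances(tr)

  ses_f <- vapply(1:40, function(s) {
    comm <- simulate_community(tr, "filtered", richness = 12, seed = s)$otu_id
    ses_phylo(comm, D, "MPD", n_permutations = 199, seed = s)$ses
  }, numeric(1))
  expect_gte(mean(ses_f < 0), 0.9)

  ses_r <- vapply(1:100, function(s) {
    comm <- simulate_community(tr, "random", richness = 12, seed = s)$otu_id
    ses_phylo(comm, D, "MPD", n_permutations = 199, seed = s + 5000)$ses
  }, numeric(1))
  expect_lt(abs(mean(ses_r)), 0.2)

  # overdispersed communities score positive SES
  ses_o <- vapply(1:20, function(s) {
    comm <- simulate_community(tr, "overdispersed", richness = 12,
                               seed = s)$otu_id
    ses_phylo(comm, D, "MPD", n_permutations = 199, seed = s)$ses
  }, numeric(1))
  expect_gt(mean(ses_o), 0)
})

test_that("structure_table emits one row per sample x fraction x metric", {
  sim <- simulate_microbiome(n_samples = 5, n_pool_otus = 40,
                             richness_per_sample = 15,
                             sequencing_depth = 500, seed = 41)
  st <- structure_table(sim$table, sim$tree, n_permutations = 99, seed = 2)
  expect_equal(nrow(st), 5 * 2 * 2)
  expect_setequal(unique(st$metric), c("MPD", "MNTD"))
  expect_equal(sum(st$metric == "MPD"), 10)
  expect_true(all(st$n_otus > 0))
  expect_equal(st, structure_table(sim$table, sim$tree,
                                   n_permutations = 99, seed = 2))

  # empty fractions are flagged rows, not dropped
  empty_rna <- toy_table(matrix(c(3, 4, 2, 5), 2),
                         matrix(c(2, 3, 0, 0), 2))
  tiny_tree <- ape::read.tree(text = "((o1:1,o2:1):1,(x:1,y:1):1);")
  st2 <- suppressWarnings(
    structure_table(empty_rna, tiny_tree, metrics = "MPD",
                    n_permutations = 99, seed = 1, max_missing = 1,
                    check_abundance_signal = FALSE)
  )
  expect_equal(nrow(st2), 4)
  expect_true(any(st2$degenerate & st2$fraction == "RNA"))

  # too many OTUs missing from the tree aborts
  expect_error(
    structure_table(empty_rna,
                    ape::read.tree(text = "((o1:1,q:1):1,(x:1,y:1):1);"),
                    max_missing = 0.05, n_permutations = 99),
    "max_missing"
  )
})

test_that("by-fraction pools reuse only that fraction's OTUs", {
  sim <- simulate_microbiome(n_samples = 4, n_pool_otus = 30,
                             richness_per_sample = 12,
                             sequencing_depth = 400, seed = 42)
  st <- structure_table(sim$table, sim$tree, metrics = "MPD",
                        n_permutations = 99, seed = 3, pool = "by_fraction")
  expect_equal(nrow(st), 8)
  expect_true(all(is.finite(st$ses)))
})
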