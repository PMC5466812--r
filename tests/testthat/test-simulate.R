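test_that("Yule trees are rooted, bifurcating, ultrametric and reproducible", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)

  t50 <- simulate_yule_tree(50, 1, seed = 1)
  expect_equal(t50$Nnode, 49) # bifurcating: n - 1 internal nodes
  expect_true(ape::is.rooted(t50))
  expect_true(ape::is.binary(t50))

  depths <- ape::node.depth.edgelength(t50)[seq_len(50)]
  expect_lt(max(depths) - min(depths), 1e-9)

  expect_equal(simulate_yule_tree(20, 2, seed = 9),
               simulate_yule_tree(20, 2, seed = 9))
  expect_error(simulate_yule_tree(1, 1), "n_tips")
})

test_that("Brownian trait simulation matches its closed-form moments", {
  # degenerate diffusion: all tips at the root value
  tr <- simulate_yule_tree(10, 1, seed = 2)
  flat <- simulate_bm_trait(tr, sigma2 = 0, root_value = 3.5, seed = 1)
  expect_true(all(flat$value == 3.5))

  # star tree: tip variance = sigma2 * t
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2,e:2,f:2,g:2,h:2);")
  vals <- vapply(seq_len(1000), function(s) {
    simulate_bm_trait(star, sigma2 = 0.5, seed = s)$value
  }, numeric(8))
  expect_equal(var(as.vector(vals)), 0.5 * 2, tolerance = 0.1)
  expect_equal(mean(vals), 0, tolerance = 0.05)

  # sister tips: covariance = sigma2 * shared path length
  sis <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  pair <- vapply(seq_len(500), function(s) {
    simulate_bm_trait(sis, sigma2 = 1, seed = s)$value[1:2]
  }, numeric(2))
  expect_equal(cov(pair[1, ], pair[2, ]), 1, tolerance = 0.3)
  expect_equal(var(pair[1, ]), 2, tolerance = 0.4)

  expect_error(simulate_bm_trait(tr, sigma2 = -1), "sigma2")
})

test_that("community assembly modes honour their contracts", {
  tr <- simulate_yule_tree(32, 1, seed = 5)

  # full-pool richness returns the whole pool in every mode
  for (mode in c("random", "filtered", "overdispersed")) {
    mem <- simulate_community(tr, mode, richness = 32, seed = 3)
    expect_setequal(mem$otu_id, tr$tip.label)
  }

  mem <- simulate_community(tr, "random", richness = 10, n_samples = 5,
                            seed = 3)
  expect_equal(nrow(mem), 50)
  expect_true(all(table(mem$sample_id) == 10))
  expect_false(any(duplicated(mem[c("sample_id", "otu_id")])))

  # filtered communities sit inside a single clade
  memf <- simulate_community(tr, "filtered", richness = 8, seed = 3)
  mrca <- ape::getMRCA(tr, memf$otu_id)
  clade <- ape::extract.clade(tr, mrca)$tip.label
  expect_lt(length(clade), 32) # not the root clade
  expect_true(all(memf$otu_id %in% clade))

  # no non-root clade can hold the whole pool: explicit failure
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_error(simulate_community(bal, "filtered", richness = 3),
               "no non-root clade")

  # overdispersed max-min selection includes the most distant pair
  D <- cophenetic_distances(tr)
  memo <- simulate_community(tr, "overdispersed", richness = 6, seed = 3)
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_true(all(rownames(D)[far] %in% memo$otu_id))
  # and its minimum pairwise distance beats a random draw's (clear margin)
  minpair <- function(ids) min(D[ids, ids][upper.tri(D[ids, ids])])
  memr <- simulate_community(tr, "random", richness = 6, seed = 3)
  expect_gt(minpair(memo$otu_id), minpair(memr$otu_id))

  expect_error(simulate_community(tr, "random", richness = 33), "richness")
})

test_that("paired counts conserve depth and respect activity boundaries", {
  tr <- simulate_yule_tree(6, 1, seed = 1)
  mem <- simulate_community(tr, "random", richness = 6, n_samples = 3,
                            seed = 1)
  act <- c(otu_1 = 0, otu_2 = 1, otu_3 = 0.5, otu_4 = 0.5, otu_5 = 0.2,
           otu_6 = 0.8)
  tab <- simulate_paired_counts(mem, act, depth = 300, n_tech_replicates = 3,
                                seed = 4)
  # multinomial conservation per sample x fraction x replicate
  totals <- tapply(tab$count,
                   paste(tab$sample_id, tab$fraction, tab$replicate),
                   sum)
  expect_true(all(totals == 300))
  # boundary activities silence one fraction entirely
  expect_true(all(tab$count[tab$otu_id == "otu_1" & tab$fraction == "RNA"] == 0))
  expect_true(all(tab$count[tab$otu_id == "otu_2" & tab$fraction == "DNA"] == 0))
  # bit-identical under the same seed
  expect_equal(tab, simulate_paired_counts(mem, act, depth = 300,
                                           n_tech_replicates = 3, seed = 4))

  expect_error(simulate_paired_counts(mem, act * 2, depth = 300), "activity")
  expect_error(
    simulate_paired_counts(mem, act[-1], depth = 300),
    "undefined"
  )
})

test_that("estimated expression ratio orders OTUs by generative activity", {
  # two OTUs, activity 0.2 vs 0.8: estimated ratio strictly ordered in
  # at least 95% of seeds
  tr <- ape::read.tree(text = "(otu_1:1,otu_2:1);")
  act <- c(otu_1 = 0.2, otu_2 = 0.8)
  mem <- tibble::tibble(sample_id = rep(paste0("s", 1:19), each = 2),
                        otu_id = rep(c("otu_1", "otu_2"), 19))
  ordered_ok <- vapply(seq_len(100), function(s) {
    tab <- simulate_paired_counts(mem, act, depth = 1000, seed = s)
    mer <- mean_expression_ratio(collapse_replicates(tab))
    mer$value[mer$otu_id == "otu_1"] < mer$value[mer$otu_id == "otu_2"]
  }, logical(1))
  expect_gte(sum(ordered_ok), 95)
})

test_that("the one-call generator is reproducible and internally consistent", {
  sim <- simulate_microbiome(n_samples = 4, n_pool_otus = 30,
                             richness_per_sample = 12, sequencing_depth = 400,
                             seed = 11)
  expect_equal(length(sim$tree$tip.label), 30)
  expect_equal(nrow(sim$activity), 30)
  expect_true(all(sim$activity$activity >= 0 & sim$activity$activity <= 1))
  expect_equal(dplyr::n_distinct(sim$table$sample_id), 4)
  sim2 <- simulate_microbiome(n_samples = 4, n_pool_otus = 30,
                              richness_per_sample = 12,
                              sequencing_depth = 400, seed = 11)
  expect_equal(sim$table, sim2$table)
  expect_equal(ape::write.tree(sim$tree), ape::write.tree(sim2$tree))
})
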