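test_that("Blomberg's K is exactly 1 on a star tree and invariant as claimed", {
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2,e:2,f:2);")
  set.seed(51)
  for (i in 1:5) {
    x <- stats::setNames(rnorm(6), star$tip.label)
    expect_equal(blomberg_k(star, x), 1, tolerance = 1e-10)
  }

  tr <- simulate_yule_tree(40, 1, seed = 52)
  x <- stats::setNames(rnorm(40), tr$tip.label)
  k <- blomberg_k(tr, x)
  # affine invariance
  expect_equal(blomberg_k(tr, 3 * x - 7), k, tolerance = 1e-10)
  # branch-length scale invariance
  tr10 <- tr
  tr10$edge.length <- tr$edge.length * 10
  expect_equal(blomberg_k(tr10, x), k, tolerance = 1e-10)
  expect_gte(k, 0)

  expect_warning(kc <- blomberg_k(tr, stats::setNames(rep(1, 40),
                                                      tr$tip.label)),
                 "constant")
  expect_true(is.na(kc))
  expect_error(blomberg_k(ape::read.tree(text = "(a:1,b:1);"),
                          c(a = 1, b = 2)), ">= 4")
})

test_that("K distinguishes Brownian from tree-free traits", {
  tr <- simulate_yule_tree(64, 1, seed = 53)
  k_bm <- vapply(1:100, function(s) {
    blomberg_k(tr, simulate_bm_trait(tr, sigma2 = 1, seed = s))
  }, numeric(1))
  k_wn <- vapply(1:100, function(s) {
    blomberg_k(tr, simulate_white_noise_trait(tr, seed = s + 10000))
  }, numeric(1))
  expect_gt(mean(k_bm), 0.8)
  expect_lt(mean(k_wn), 0.6)
  expect_gt(mean(k_bm), mean(k_wn))
})

test_that("Kse reduces to K at zero SE and corrects noise attenuation", {
  tr <- simulate_yule_tree(50, 1, seed = 54)
  trait <- simulate_bm_trait(tr, sigma2 = 1, seed = 9)
  x <- stats::setNames(trait$value, trait$otu_id)
  zero_se <- stats::setNames(rep(0, 50), names(x))
  fit <- kse(tr, x, se = zero_se)
  expect_equal(fit$k, blomberg_k(tr, x), tolerance = 1e-9)
  expect_false(fit$used_se)

  # BM trait plus iid observation noise with known SE: Kse recovers more of
  # the signal than plain K computed on the noisy values
  se_val <- 0.6
  k_plain <- numeric(40)
  k_se <- numeric(40)
  for (s in seq_len(40)) {
    tru <- simulate_bm_trait(tr, sigma2 = 1, seed = 100 + s)
    noisy <- stats::setNames(
      tru$value + withr::with_seed(200 + s, rnorm(50, sd = se_val)),
      tru$otu_id
    )
    k_plain[s] <- blomberg_k(tr, noisy)
    k_se[s] <- kse(tr, noisy,
                   se = stats::setNames(rep(se_val, 50), tru$otu_id))$k
  }
  expect_lt(abs(mean(k_se) - 1), abs(mean(k_plain) - 1))
  expect_lt(mean(k_plain), 1) # noise attenuates plain K

  # overwhelming measurement error: flagged unidentifiable
  expect_warning(
    big <- kse(tr, x, se = stats::setNames(rep(1e6, 50), names(x))),
    "unidentifiable"
  )
  expect_true(big$se_dominated)

  expect_error(kse(tr, x, se = stats::setNames(rep(NA_real_, 50), names(x))),
               "finite")
  expect_error(kse(tr, x), "no standard errors")
})

test_that("contrast-variance permutation test is valid and powered", {
  tr <- simulate_yule_tree(50, 1, seed = 55)
  trait <- simulate_bm_trait(tr, sigma2 = 1, seed = 1)
  p1 <- k_significance(tr, trait, n_permutations = 199, seed = 3)
  expect_equal(p1, k_significance(tr, trait, n_permutations = 199, seed = 3))
  expect_gt(p1, 0)
  expect_lte(p1, 1)

  # strong BM signal on many tips: small p
  big <- simulate_yule_tree(100, 1, seed = 56)
  p_bm <- k_significance(big, simulate_bm_trait(big, 1, seed = 2),
                         n_permutations = 199, seed = 4)
  expect_lt(p_bm, 0.05)

  expect_warning(pc <- k_significance(
    tr, stats::setNames(rep(2, 50), tr$tip.label), n_permutations = 199
  ), "constant")
  expect_equal(pc, 1)
  expect_error(k_significance(tr, trait, n_permutations = 10), ">= 99")
})

test_that("k_signal objects print, tidy and glance coherently", {
  tr <- simulate_yule_tree(30, 1, seed = 57)
  trait <- simulate_bm_trait(tr, sigma2 = 2, seed = 5)
  trait$se <- rep(0.05, 30)
  fit <- k_signal(tr, trait, n_permutations = 199, seed = 6,
                  scope = "demo")
  expect_s3_class(fit, "k_signal")
  expect_output(print(fit), "Kse")
  td <- tidy(fit)
  expect_equal(td$scope, "demo")
  expect_equal(td$k, fit$k)
  expect_true(td$used_se)
  expect_match(td$stars, "^\\**$")
  gl <- glance(fit)
  expect_equal(gl$n_tips, 30)
  expect_true(is.finite(gl$sigma2))
})

test_that("signal_table scopes per-phylum trees and drops traitless tips", {
  tr <- make_two_clade_tree(16, seed = 58)
  trait <- simulate_bm_trait(tr, sigma2 = 1, seed = 7)
  trait$se <- rep(0.02, 32)

  # single global scope: one row
  one <- signal_table(tr, trait, n_permutations = 99, seed = 8)
  expect_equal(nrow(one), 1)
  expect_equal(one$scope, "all")
  expect_equal(one$n_tips, 32)

  scopes <- list(
    all = tr,
    clade_a = ape::keep.tip(tr, grep("^a_", tr$tip.label, value = TRUE)),
    clade_b = ape::keep.tip(tr, grep("^b_", tr$tip.label, value = TRUE))
  )
  st <- signal_table(scopes, trait, n_permutations = 99, seed = 8)
  expect_equal(nrow(st), 3)
  expect_setequal(st$scope, c("all", "clade_a", "clade_b"))

  # reference tips without trait values are pruned before fitting
  ref_tree <- tr
  ref_tree$tip.label[1] <- "reference_species"
  st_ref <- signal_table(ref_tree, trait, n_permutations = 99, seed = 8)
  expect_equal(st_ref$n_tips, 31)

  # scopes with < 4 usable tips are skipped with a warning
  small <- ape::keep.tip(tr, c("a_1", "a_2", "a_3"))
  expect_warning(st_small <- signal_table(list(tiny = small), trait,
                                          n_permutations = 99, seed = 8),
                 "skipped")
  expect_equal(nrow(st_small), 0)
})
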