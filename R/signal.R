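#' Blomberg's K phylogenetic signal
#'
#' Ratio-of-ratios statistic comparing how the observed trait variance
#' partitions on the tree with its Brownian-motion expectation. With
#' phylogenetic GLS mean \eqn{\hat a = (1'C^{-1}x)/(1'C^{-1}1)},
#' \eqn{MSE_0 = (x-\hat a)'(x-\hat a)/(n-1)},
#' \eqn{MSE = (x-\hat a)'C^{-1}(x-\hat a)/(n-1)} and BM expectation
#' \eqn{E[MSE_0/MSE] = (tr(C) - n/(1'C^{-1}1))/(n-1)},
#' \deqn{K = \frac{(MSE_0/MSE)_{obs}}{E[MSE_0/MSE]}.}
#' K = 1 matches Brownian motion, K < 1 weaker signal than BM, K > 1
#' stronger (relatives more similar than BM predicts). K is invariant to
#' affine trait transformations and to uniform branch-length scaling.
#'
#' @param tree A rooted `phylo` object with >= 4 tips.
#' @param trait Named numeric vector or tibble (`otu_id`, `value`) covering
#'   every tip.
#' @return K (scalar >= 0); `NA` with a warning for a constant trait.
#' @export
blomberg_k <- function(tree, trait) {
  check_tree(tree)
  x <- as_trait_vector(trait, tree$tip.label)
  if (length(x) < 4) stop("need >= 4 tips", call. = FALSE)
  k_statistic(x, vcv_matrix(tree))
}

# Core K computation given any (possibly error-inflated) covariance C.
k_statistic <- function(x, C) {
  n <- length(x)
  Ci <- chol_solve(C)
  one <- rep(1, n)
  denom <- sum(Ci %*% one)
  a <- sum(Ci %*% x) / denom
  dev <- x - a
  mse0 <- sum(dev^2) / (n - 1)
  mse <- as.numeric(t(dev) %*% Ci %*% dev) / (n - 1)
  if (mse0 == 0 || mse == 0) {
    warning("constant trait: K undefined", call. = FALSE)
    return(NA_real_)
  }
  expected <- (sum(diag(C)) - n / denom) / (n - 1)
  (mse0 / mse) / expected
}

# Inverse via Cholesky, with a trace-scaled jitter retry on failure.
chol_solve <- function(C) {
  n <- nrow(C)
  L <- tryCatch(chol(C), error = function(e) {
    jitter <- 1e-10 * sum(diag(C)) / n
    message("VCV Cholesky needed jitter ", signif(jitter, 3))
    chol(C + diag(jitter, n))
  })
  chol2inv(L)
}

#' Blomberg's K with trait measurement error (Kse)
#'
#' Extends [blomberg_k()] to traits observed with known per-tip standard
#' errors, the situation of a mean expression ratio estimated from a finite
#' number of plants. The observation model is
#' \eqn{x \sim N(\hat a 1, \sigma^2 C + diag(se^2))}: the Brownian rate
#' \eqn{\sigma^2} is estimated by maximum likelihood, and K is then computed
#' with \eqn{C^* = \hat\sigma^2 C + diag(se^2)} in place of C. With all
#' standard errors zero this reduces exactly to Blomberg's K (K is invariant
#' to the overall scale of C).
#'
#' @param tree A rooted `phylo` object with >= 4 tips.
#' @param trait Named numeric vector or tibble (`otu_id`, `value`).
#' @param se Named numeric vector or taken from the trait tibble's `se`
#'   column; must be finite and non-negative for every tip.
#' @return A list: `k`, `sigma2` (ML Brownian rate), `used_se`,
#'   `se_dominated` (TRUE when the estimated tree variance is negligible
#'   next to the measurement variance, leaving the signal unidentifiable).
#' @export
kse <- function(tree, trait, se = NULL) {
  check_tree(tree)
  x <- as_trait_vector(trait, tree$tip.label)
  if (is.null(se)) {
    if (!is.data.frame(trait) || !"se" %in% names(trait)) {
      stop("no standard errors supplied", call. = FALSE)
    }
    se <- as_trait_vector(trait, tree$tip.label, column = "se")
  } else {
    se <- as_trait_vector(se, tree$tip.label)
  }
  if (any(!is.finite(se)) || any(se < 0)) {
    stop("standard errors must be finite and non-negative", call. = FALSE)
  }
  n <- length(x)
  if (n < 4) stop("need >= 4 tips", call. = FALSE)
  C <- vcv_matrix(tree)

  if (all(se == 0)) {
    return(list(k = k_statistic(x, C), sigma2 = NA_real_, used_se = FALSE,
                se_dominated = FALSE))
  }

  D2 <- se^2
  negloglik <- function(log_s2) {
    V <- exp(log_s2) * C + diag(D2, n)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    Vi <- chol2inv(L)
    one <- rep(1, n)
    a <- sum(Vi %*% x) / sum(Vi %*% one)
    dev <- x - a
    as.numeric(sum(log(diag(L))) + 0.5 * t(dev) %*% Vi %*% dev)
  }
  # bracket the rate around a moments-based guess
  s2_guess <- max(stats::var(x), mean(D2), 1e-12) / mean(diag(C))
  opt <- stats::optimize(negloglik, interval = log(s2_guess) + c(-15, 15))
  if (!is.finite(opt$objective) || opt$objective >= 1e10) {
    stop("Kse maximum-likelihood fit did not converge", call. = FALSE)
  }
  sigma2 <- exp(opt$minimum)
  se_dominated <- sigma2 * mean(diag(C)) < 1e-3 * mean(D2)
  if (se_dominated) {
    warning("measurement error dominates the trait variance; ",
            "phylogenetic signal unidentifiable", call. = FALSE)
  }
  Cstar <- sigma2 * C + diag(D2, n)
  list(k = k_statistic(x, Cstar), sigma2 = sigma2, used_se = TRUE,
       se_dominated = se_dominated)
}

#' Permutation significance of phylogenetic signal
#'
#' Tests whether trait values are non-randomly distributed over the tips:
#' the statistic is the variance (mean square) of the phylogenetically
#' independent contrasts, which is small when close relatives hold similar
#' values; the null distribution shuffles the trait values across the tips.
#' \eqn{p = (\#\{null \le obs\} + 1)/(n_{perm} + 1)} (lower tail: low
#' contrast variance = strong signal).
#'
#' @param tree A rooted `phylo` object.
#' @param trait Named numeric vector or tibble (`otu_id`, `value`).
#' @param n_permutations Number of shuffles (>= 99; default 999).
#' @param seed Integer seed.
#' @return The permutation p-value in (0, 1].
#' @export
k_significance <- function(tree, trait, n_permutations = 999L, seed = 1L) {
  if (n_permutations < 99) stop("n_permutations must be >= 99", call. = FALSE)
  check_tree(tree)
  x <- as_trait_vector(trait, tree$tip.label)
  if (stats::sd(x) == 0) {
    warning("constant trait: signal test degenerate; p = 1", call. = FALSE)
    return(1)
  }
  tree <- regularize_tree(tree)
  x <- x[tree$tip.label]
  obs <- mean(ape::pic(x, tree)^2)
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      xs <- x[sample.int(length(x))]
      names(xs) <- names(x)
      mean(ape::pic(xs, tree)^2)
    }, numeric(1))
  })
  (sum(null <= obs) + 1) / (n_permutations + 1)
}

#' Fit phylogenetic signal for one tree and trait
#'
#' Convenience wrapper bundling the K (or Kse) point estimate and its
#' contrast-variance permutation p-value into a fitted-model-style object
#' with [generics::tidy()] and [generics::glance()] methods.
#'
#' @param tree A rooted `phylo` object.
#' @param trait Named numeric vector or tibble (`otu_id`, `value`[, `se`]).
#' @param se Optional named SE vector; when present (or found in the trait
#'   tibble) the Kse variant is used.
#' @param use_se Set `FALSE` to ignore available SEs and fit plain K.
#' @param n_permutations Shuffles for the significance test.
#' @param seed Integer seed.
#' @param scope Label for the fitted scope (e.g., a phylum name).
#' @return An object of class `k_signal`.
#' @export
k_signal <- function(tree, trait, se = NULL, use_se = NULL,
                     n_permutations = 999L, seed = 1L, scope = "all") {
  has_se <- !is.null(se) ||
    (is.data.frame(trait) && "se" %in% names(trait))
  if (is.null(use_se)) use_se <- has_se
  fit <- if (use_se) {
    kse(tree, trait, se = se)
  } else {
    list(k = blomberg_k(tree, trait), sigma2 = NA_real_, used_se = FALSE,
         se_dominated = FALSE)
  }
  p <- k_significance(tree, trait, n_permutations = n_permutations,
                      seed = seed)
  structure(
    list(scope = scope, k = fit$k, used_se = fit$used_se,
         sigma2 = fit$sigma2, se_dominated = fit$se_dominated,
         p_value = p, n_permutations = as.integer(n_permutations),
         n_tips = length(tree$tip.label), seed = as.integer(seed)),
    class = "k_signal"
  )
}

#' @export
print.k_signal <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic signal [%s]: %s = %.3f, p = %.4g (%d tips, %d permutations)\n",
    x$scope, if (x$used_se) "Kse" else "K", x$k, x$p_value, x$n_tips,
    x$n_permutations
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phylogenetic-signal fit
#'
#' @param x A `k_signal` object.
#' @param ... Unused.
#' @return A one-row tibble: `scope`, `k`, `used_se`, `p_value`,
#'   `n_permutations`, `n_tips`, `stars` (`**` p < 0.01, `***` p < 0.001).
#' @export
tidy.k_signal <- function(x, ...) {
  tibble::tibble(
    scope = x$scope, k = x$k, used_se = x$used_se, p_value = x$p_value,
    n_permutations = x$n_permutations, n_tips = x$n_tips,
    stars = significance_stars(x$p_value)
  )
}

#' Glance at a phylogenetic-signal fit
#'
#' @param x A `k_signal` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `sigma2`, `p_value`, `n_tips`,
#'   `se_dominated`.
#' @export
glance.k_signal <- function(x, ...) {
  tibble::tibble(k = x$k, sigma2 = x$sigma2, p_value = x$p_value,
                 n_tips = x$n_tips, se_dominated = x$se_dominated)
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Phylogenetic-signal table over several tree scopes
#'
#' Fits Kse (or K) for a global tree and/or per-phylum subtrees against one
#' trait table. Tree tips without a trait value (e.g., reference species
#' included for tree construction) are pruned before fitting; scopes left
#' with fewer than 4 tips are skipped with a warning.
#'
#' @param trees A named list of `phylo` objects (names become `scope`), or a
#'   single tree (scope `"all"`).
#' @param trait A `trait_vector` tibble (`otu_id`, `value`[, `se`]) as from
#'   [mean_expression_ratio()].
#' @param use_se Use the Kse variant where SEs are available.
#' @param n_permutations Shuffles per scope.
#' @param seed Integer seed; per-scope seeds derived.
#' @return A tibble of class `k_table`: one [tidy.k_signal()] row per scope.
#' @export
signal_table <- function(trees, trait, use_se = NULL,
                         n_permutations = 999L, seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(all = trees)
  if (is.null(names(trees)) || any(names(trees) == "")) {
    names(trees) <- paste0("scope_", seq_along(trees))
  }
  seeds <- derive_seeds(seed, length(trees))
  rows <- purrr::imap_dfr(trees, function(tree, scope) {
    keep <- intersect(tree$tip.label, trait$otu_id)
    if (length(keep) < 4) {
      warning("scope '", scope, "' has fewer than 4 tips with trait ",
              "values; skipped", call. = FALSE)
      return(tibble::tibble())
    }
    sub <- ape::keep.tip(tree, keep)
    fit <- k_signal(sub, trait[trait$otu_id %in% keep, , drop = FALSE],
                    use_se = use_se, n_permutations = n_permutations,
                    seed = seeds[match(scope, names(trees))], scope = scope)
    tidy(fit)
  })
  class(rows) <- c("k_table", class(rows))
  rows
}
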