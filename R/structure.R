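#' Mean pairwise phylogenetic distance of a community
#'
#' Unweighted: the mean of d(i, j) over all unordered pairs of community
#' members. With abundance weights, each pair contributes proportionally to
#' the product of its members' abundances.
#'
#' @param community Character vector (>= 2) of OTU ids, all rows/columns of
#'   `dist`.
#' @param dist A cophenetic distance matrix as from
#'   [cophenetic_distances()].
#' @param weights Optional named abundances over `community`.
#' @return Mean pairwise distance (scalar).
#' @export
mpd <- function(community, dist, weights = NULL) {
  idx <- community_index(community, dist)
  if (length(idx) < 2) stop("community must have >= 2 members", call. = FALSE)
  D <- dist[idx, idx, drop = FALSE]
  if (is.null(weights)) {
    sum(D) / (length(idx) * (length(idx) - 1))
  } else {
    w <- weights[community]
    W <- outer(w, w)
    diag(W) <- 0
    sum(W * D) / sum(W)
  }
}

#' Mean nearest taxon distance of a community
#'
#' Mean over community members of the distance to their closest co-occurring
#' relative; always <= MPD.
#'
#' @inheritParams mpd
#' @return Mean nearest-taxon distance (scalar).
#' @export
mntd <- function(community, dist, weights = NULL) {
  idx <- community_index(community, dist)
  if (length(idx) < 2) stop("community must have >= 2 members", call. = FALSE)
  D <- dist[idx, idx, drop = FALSE]
  diag(D) <- Inf
  nt <- apply(D, 1, min)
  if (is.null(weights)) {
    mean(nt)
  } else {
    w <- weights[community]
    sum(w * nt) / sum(w)
  }
}

community_index <- function(community, dist) {
  idx <- match(community, rownames(dist))
  if (anyNA(idx)) {
    stop("community member(s) not in distance matrix: ",
         paste(utils::head(community[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Standardized effect size of MPD or MNTD under a tip-shuffle null
#'
#' Compares the observed metric with its distribution when tip labels are
#' shuffled across the phylogeny while community membership, richness,
#' occupancy and abundances stay fixed — for a single community this is
#' equivalent to drawing random same-sized communities from the pool.
#' \eqn{SES = (obs - \bar{null}) / sd(null)}; the p-value is lower-tailed
#' (\eqn{(\#\{null \le obs\} + 1) / (n_{perm} + 1)}), so small p with
#' negative SES indicates phylogenetic clustering. A two-tailed p doubles
#' the smaller tail.
#'
#' @param community Character vector of OTU ids (>= 2).
#' @param dist Cophenetic distance matrix over the OTU pool (the universe
#'   the null shuffles over).
#' @param metric `"MPD"` or `"MNTD"`.
#' @param n_permutations Number of label shuffles (>= 99; default 999, i.e.,
#'   a 1,000-permutation test counting the observed community).
#' @param seed Integer seed.
#' @param tail `"lower"` (clustering, default) or `"two_sided"`.
#' @return A one-row tibble of class `ses_result`: `n_otus`, `metric`,
#'   `observed`, `null_mean`, `null_sd`, `ses`, `p_value`,
#'   `n_permutations`, `degenerate`.
#' @export
ses_phylo <- function(community, dist, metric = c("MPD", "MNTD"),
                      n_permutations = 999L, seed = 1L,
                      tail = c("lower", "two_sided")) {
  metric <- match.arg(metric)
  tail <- match.arg(tail)
  if (n_permutations < 99) stop("n_permutations must be >= 99", call. = FALSE)
  idx <- community_index(community, dist)
  k <- length(idx)
  if (k < 2) stop("community must have >= 2 members", call. = FALSE)
  n_pool <- nrow(dist)
  obs <- metric_value(idx, dist, metric)
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      metric_value(sample.int(n_pool, k), dist, metric)
    }, numeric(1))
  })
  mu <- mean(null)
  sdv <- stats::sd(null)
  degenerate <- !is.finite(sdv) || sdv == 0
  ses <- if (degenerate) {
    if (isTRUE(all.equal(obs, mu))) 0 else NA_real_
  } else {
    (obs - mu) / sdv
  }
  p_low <- (sum(null <= obs) + 1) / (n_permutations + 1)
  p_high <- (sum(null >= obs) + 1) / (n_permutations + 1)
  p <- if (tail == "lower") p_low else min(1, 2 * min(p_low, p_high))
  out <- tibble::tibble(
    n_otus = k, metric = metric, observed = obs, null_mean = mu,
    null_sd = sdv, ses = ses, p_value = p,
    n_permutations = as.integer(n_permutations), degenerate = degenerate
  )
  class(out) <- c("ses_result", class(out))
  out
}

metric_value <- function(idx, dist, metric) {
  D <- dist[idx, idx, drop = FALSE]
  if (metric == "MPD") {
    sum(D) / (length(idx) * (length(idx) - 1))
  } else {
    diag(D) <- Inf
    mean(apply(D, 1, min))
  }
}

#' Phylogenetic structure table across all sample x fraction communities
#'
#' Runs [ses_phylo()] for every sample x fraction community of a paired OTU
#' table against the pooled OTU list (union over all samples and both
#' fractions, pruned to the tree). Before the null models run, Blomberg's K
#' of per-OTU total abundance is computed; a significant abundance signal
#' would undermine the tip-shuffle null's fixed-abundance assumption, so a
#' warning is raised in that case.
#'
#' @param table A [paired_otu_table()].
#' @param tree A `phylo` object whose tips cover the table's OTUs.
#' @param metrics Subset of `c("MPD", "MNTD")`.
#' @param n_permutations Shuffles per community (default 999).
#' @param seed Integer seed.
#' @param pool `"all"` (union of both fractions, the headline analysis) or
#'   `"by_fraction"` (DNA communities judged against the DNA pool, RNA
#'   against RNA — the robustness variant).
#' @param max_missing Abort if more than this proportion of table OTUs is
#'   absent from the tree (those present are used, with a warning).
#' @param check_abundance_signal Compute the abundance-K validity check.
#' @return A tibble of class `ses_table`: one row per sample x fraction x
#'   metric with the [ses_phylo()] columns plus `sample_id`, `fraction`,
#'   `significant` (p < 0.05). The abundance check is attached as attribute
#'   `abundance_k`.
#' @export
structure_table <- function(table, tree, metrics = c("MPD", "MNTD"),
                            n_permutations = 999L, seed = 1L,
                            pool = c("all", "by_fraction"),
                            max_missing = 0.05,
                            check_abundance_signal = TRUE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  pool <- match.arg(pool)
  tab <- collapse_replicates(table)
  otus <- unique(tab$otu_id)
  in_tree <- intersect(otus, tree$tip.label)
  missing <- setdiff(otus, tree$tip.label)
  if (length(missing) / length(otus) > max_missing) {
    stop(length(missing), " of ", length(otus),
         " OTUs absent from tree (over max_missing)", call. = FALSE)
  }
  if (length(missing) > 0) {
    warning(length(missing), " OTU(s) absent from tree dropped",
            call. = FALSE)
    tab <- tab[tab$otu_id %in% in_tree, , drop = FALSE]
    tab <- paired_otu_table(tab)
  }

  abundance_k <- NULL
  if (check_abundance_signal) {
    totals <- tapply(tab$count, tab$otu_id, sum)
    pool_tree <- ape::keep.tip(tree, in_tree)
    if (length(in_tree) >= 4 && stats::sd(totals[pool_tree$tip.label]) > 0) {
      abundance_k <- k_signal(pool_tree, totals[pool_tree$tip.label],
                              n_permutations = min(n_permutations, 999L),
                              seed = seed)
      if (abundance_k$p_value < 0.05) {
        warning("phylogenetic signal detected in OTU abundance (K = ",
                signif(abundance_k$k, 3), ", p = ",
                signif(abundance_k$p_value, 3),
                "); tip-shuffle null may be anticonservative", call. = FALSE)
      }
    }
  }

  seeds <- derive_seeds(seed, 2 * dplyr::n_distinct(tab$sample_id) *
                          length(metrics))
  m <- otu_matrix(tab)
  parts <- stringr::str_split_fixed(colnames(m), stringr::fixed("|"), 2)
  i <- 0L
  rows <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    comm <- rownames(m)[m[, j] > 0]
    fr <- parts[j, 2]
    pool_otus <- if (pool == "all") {
      in_tree
    } else {
      frac_m <- otu_matrix(tab, fraction = fr)
      rownames(frac_m)[rowSums(frac_m) > 0]
    }
    dist <- cophenetic_distances(ape::keep.tip(tree, pool_otus))
    purrr::map_dfr(metrics, function(met) {
      i <<- i + 1L
      if (length(comm) < 2) {
        return(tibble::tibble(
          sample_id = parts[j, 1], fraction = fr, n_otus = length(comm),
          metric = met, observed = NA_real_, null_mean = NA_real_,
          null_sd = NA_real_, ses = NA_real_, p_value = NA_real_,
          n_permutations = as.integer(n_permutations), degenerate = TRUE,
          significant = NA
        ))
      }
      res <- ses_phylo(comm, dist, metric = met,
                       n_permutations = n_permutations, seed = seeds[i])
      dplyr::mutate(
        tibble::as_tibble(res),
        sample_id = parts[j, 1], fraction = fr,
        significant = .data$p_value < 0.05, .before = 1
      )
    })
  })
  rows <- dplyr::relocate(rows, "sample_id", "fraction")
  class(rows) <- c("ses_table", class(rows))
  attr(rows, "abundance_k") <- abundance_k
  rows
}

#' Plot a phylogenetic-structure table
#'
#' SES per sample, faceted by metric, coloured by fraction; points below the
#' zero line indicate clustering, filled points are significant at p < 0.05.
#'
#' @param object A `ses_table` from [structure_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ses_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sample_id, y = .data$ses, colour = .data$fraction,
    shape = .data$significant
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                na.translate = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "Sample", y = "Standardized effect size",
                  colour = "Fraction", shape = "p < 0.05") +
    ggplot2::theme_minimal()
}
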