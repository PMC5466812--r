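#' Simulate a Yule (pure-birth) phylogeny
#'
#' Stand-in for an inferred OTU phylogeny: a rooted, bifurcating, ultrametric
#' tree with `n_tips` labelled tips, simulated under a constant per-lineage
#' birth rate and no extinction.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Per-lineage speciation rate (> 0).
#' @param seed Integer seed; fixed seed gives a bit-identical tree.
#' @return An [ape::rphylo()]-style `phylo` object with tips
#'   `otu_1 ... otu_n`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  tree <- withr::with_seed(as.integer(seed), {
    ape::rphylo(n_tips, birth = birth_rate, death = 0)
  })
  tree$tip.label <- paste0("otu_", seq_len(n_tips))
  tree
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Draws one trait value per tip from the multivariate normal implied by
#' Brownian motion: mean `root_value` everywhere and covariance
#' `sigma2 * C`, where `C` is the phylogenetic variance-covariance matrix
#' (shared root-to-MRCA path lengths).
#'
#' @param tree A `phylo` object with positive finite branch lengths.
#' @param sigma2 Trait variance accrued per unit branch length (>= 0).
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return A tibble with columns `otu_id` and `value`, in tip order.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root_value = 0, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    return(tibble::tibble(otu_id = tree$tip.label,
                          value = rep(root_value, n)))
  }
  C <- vcv_matrix(tree)
  L <- chol(sigma2 * C + diag(1e-12, n))
  z <- withr::with_seed(as.integer(seed), stats::rnorm(n))
  tibble::tibble(otu_id = tree$tip.label,
                 value = root_value + as.vector(crossprod(L, z)))
}

#' Simulate a white-noise (tree-free) trait
#'
#' iid normal tip values carrying no phylogenetic signal; the contrast to
#' [simulate_bm_trait()] in calibration experiments.
#'
#' @inheritParams simulate_bm_trait
#' @param sd Standard deviation of the iid tip values.
#' @param mean Mean of the tip values.
#' @return A tibble with columns `otu_id` and `value`.
#' @export
simulate_white_noise_trait <- function(tree, mean = 0, sd = 1, seed = 1L) {
  n <- length(tree$tip.label)
  tibble::tibble(
    otu_id = tree$tip.label,
    value = withr::with_seed(as.integer(seed), stats::rnorm(n, mean, sd))
  )
}

#' Simulate community membership on a tree
#'
#' Draws which OTUs from the regional pool (the tree's tips) occur in each of
#' `n_samples` communities, under one of three assembly modes:
#' \describe{
#'   \item{random}{tips drawn uniformly without replacement (neutral).}
#'   \item{filtered}{tips drawn from within one randomly chosen non-root
#'     clade of at least `richness` tips, emulating environmental filtering
#'     and producing phylogenetic clustering.}
#'   \item{overdispersed}{greedy max-min selection: starting from the most
#'     distant tip pair, each added tip maximizes its minimum distance to the
#'     already-selected set, producing overdispersion.}
#' }
#'
#' @param tree A `phylo` object.
#' @param assembly_mode `"random"`, `"filtered"` or `"overdispersed"`.
#' @param richness Number of OTUs per community (<= number of tips).
#' @param n_samples Number of communities to draw.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id` and `otu_id` (long membership).
#' @export
simulate_community <- function(tree,
                               assembly_mode = c("random", "filtered",
                                                 "overdispersed"),
                               richness, n_samples = 1L, seed = 1L) {
  assembly_mode <- match.arg(assembly_mode)
  tips <- tree$tip.label
  n <- length(tips)
  if (richness > n) stop("richness exceeds number of tips", call. = FALSE)
  if (richness < 1) stop("richness must be >= 1", call. = FALSE)

  draw_one <- function() {
    switch(
      assembly_mode,
      random = sample(tips, richness, replace = FALSE),
      filtered = {
        if (richness == n) {
          return(tips) # full pool: filtering is vacuous in every mode
        }
        clades <- clade_tip_sets(tree)
        big <- clades[vapply(clades, length, integer(1)) >= richness]
        if (length(big) == 0) {
          stop("no non-root clade holds >= ", richness,
               " tips; cannot emulate filtering", call. = FALSE)
        }
        clade <- big[[sample.int(length(big), 1)]]
        sample(clade, richness, replace = FALSE)
      },
      overdispersed = {
        D <- cophenetic_distances(tree)
        pick <- which(D == max(D), arr.ind = TRUE)[1, ]
        sel <- as.integer(pick)
        while (length(sel) < richness) {
          rest <- setdiff(seq_len(n), sel)
          mind <- apply(D[rest, sel, drop = FALSE], 1, min)
          best <- rest[mind == max(mind)]
          sel <- c(sel, if (length(best) > 1) sample(best, 1) else best)
        }
        tips[sel[seq_len(richness)]]
      }
    )
  }

  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_samples), function(i) {
      tibble::tibble(sample_id = sprintf("s%d", i), otu_id = draw_one())
    })
  })
}

# Tip sets of every non-root internal node.
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 1]), n + 1L)
  lapply(internal, function(node) {
    ape::extract.clade(tree, node)$tip.label
  })
}

#' Simulate paired DNA/RNA counts with technical replicates
#'
#' For each sample, latent OTU abundances are drawn log-normally
#' (`meanlog = 0`, `sdlog = 1.5` by default, emulating the strong dominance
#' structure of root fungal communities). Read counts are then multinomial
#' at composition `abundance * (1 - activity)` for the DNA fraction and
#' `abundance * activity` for the RNA fraction, so an OTU's expected mean
#' expression ratio increases monotonically with its latent `activity`,
#' `activity = 0` yields no RNA reads and `activity = 1` no DNA reads. Each
#' fraction is emitted as `n_tech_replicates` independent multinomial draws
#' of `depth` reads from the same latent composition.
#'
#' @param membership Long membership tibble (`sample_id`, `otu_id`) as from
#'   [simulate_community()].
#' @param activity Named numeric vector in `[0, 1]`, one entry per pool OTU.
#' @param depth Reads per sample x fraction x replicate (> 0).
#' @param n_tech_replicates Technical replicates per fraction (>= 2).
#' @param sdlog Log-scale standard deviation of latent abundances.
#' @param seed Integer seed.
#' @return A [paired_otu_table()] with a `replicate` column.
#' @export
simulate_paired_counts <- function(membership, activity, depth = 10000L,
                                   n_tech_replicates = 2L, sdlog = 1.5,
                                   seed = 1L) {
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (n_tech_replicates < 2) {
    stop("n_tech_replicates must be >= 2", call. = FALSE)
  }
  if (any(is.na(activity)) || any(activity < 0) || any(activity > 1)) {
    stop("activity must lie in [0, 1]", call. = FALSE)
  }
  otus <- sort(unique(membership$otu_id))
  missing <- setdiff(otus, names(activity))
  if (length(missing) > 0) {
    stop("activity undefined for OTU(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  samples <- unique(membership$sample_id)
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map_dfr(samples, function(s) {
      member <- membership$otu_id[membership$sample_id == s]
      ab <- stats::rlnorm(length(member), meanlog = 0, sdlog = sdlog)
      act <- activity[member]
      purrr::map_dfr(c("DNA", "RNA"), function(fr) {
        w <- if (fr == "DNA") ab * (1 - act) else ab * act
        purrr::map_dfr(seq_len(n_tech_replicates), function(r) {
          cnt <- if (sum(w) == 0) {
            integer(length(member))
          } else {
            as.integer(stats::rmultinom(1, size = depth, prob = w / sum(w)))
          }
          tibble::tibble(otu_id = member, sample_id = s, fraction = fr,
                         replicate = r, count = cnt)
        })
      })
    })
    paired_otu_table(rows)
  })
}

#' Simulate a complete paired-fraction microbiome data set
#'
#' One-call generator tying the pieces together: a Yule tree over the OTU
#' pool, a latent activity trait on the tree (Brownian motion mapped through
#' the logistic function, white noise, or constant 0.5), community
#' memberships under the chosen assembly mode, and paired DNA/RNA count
#' tables with technical replicates.
#'
#' @param n_samples Number of plants/samples (default 19, the size of the
#'   study population the generator emulates).
#' @param n_pool_otus Regional pool size.
#' @param richness_per_sample OTUs per sample.
#' @param assembly_mode Passed to [simulate_community()].
#' @param trait_model `"brownian"`, `"white_noise"` or `"constant"`; the
#'   latent trait is mapped to `[0, 1]` activities via the logistic function
#'   (constant gives activity 0.5 everywhere).
#' @param bm_rate Brownian variance per unit branch length for the latent
#'   trait.
#' @param sequencing_depth Reads per sample x fraction x replicate.
#' @param n_tech_replicates Technical replicates per fraction.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A list with elements `tree` (phylo), `activity` (tibble `otu_id`,
#'   `activity`), `membership`, `table` (a [paired_otu_table()] with
#'   replicates) and `config` (the parameters, for the run manifest).
#' @export
simulate_microbiome <- function(n_samples = 19L, n_pool_otus = 200L,
                                richness_per_sample = 60L,
                                assembly_mode = "random",
                                trait_model = c("brownian", "white_noise",
                                                "constant"),
                                bm_rate = 1, sequencing_depth = 10000L,
                                n_tech_replicates = 2L, seed = 1L) {
  trait_model <- match.arg(trait_model)
  if (richness_per_sample > n_pool_otus) {
    stop("richness_per_sample exceeds n_pool_otus", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 4)
  tree <- simulate_yule_tree(n_pool_otus, birth_rate = 1, seed = seeds[1])
  latent <- switch(
    trait_model,
    brownian = simulate_bm_trait(tree, sigma2 = bm_rate, seed = seeds[2]),
    white_noise = simulate_white_noise_trait(tree, sd = sqrt(bm_rate),
                                             seed = seeds[2]),
    constant = tibble::tibble(otu_id = tree$tip.label, value = 0)
  )
  activity <- stats::plogis(latent$value)
  names(activity) <- latent$otu_id
  membership <- simulate_community(tree, assembly_mode,
                                   richness = richness_per_sample,
                                   n_samples = n_samples, seed = seeds[3])
  table <- simulate_paired_counts(membership, activity,
                                  depth = sequencing_depth,
                                  n_tech_replicates = n_tech_replicates,
                                  seed = seeds[4])
  list(
    tree = tree,
    activity = tibble::tibble(otu_id = latent$otu_id,
                              activity = unname(activity)),
    membership = membership,
    table = table,
    config = list(
      n_samples = n_samples, n_pool_otus = n_pool_otus,
      richness_per_sample = richness_per_sample,
      assembly_mode = assembly_mode, trait_model = trait_model,
      bm_rate = bm_rate, sequencing_depth = sequencing_depth,
      n_tech_replicates = n_tech_replicates, seed = seed,
      stage_seeds = seeds
    )
  )
}

# Deterministic stage seeds below 2^31, spread out from a master seed.
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647L)
}
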