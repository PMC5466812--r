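# Shared fixtures: tiny tables and trees built in code, plus independent
# oracles used to cross-check the tree numerics.

toy_table <- function(counts_dna, counts_rna, otus = NULL, samples = NULL) {
  # counts_*: OTU x sample matrices of equal shape
  counts_dna <- as.matrix(counts_dna)
  counts_rna <- as.matrix(counts_rna)
  stopifnot(all(dim(counts_dna) == dim(counts_rna)))
  if (is.null(otus)) otus <- paste0("o", seq_len(nrow(counts_dna)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(counts_dna)))
  long <- rbind(
    data.frame(
      otu_id = rep(otus, times = ncol(counts_dna)),
      sample_id = rep(samples, each = nrow(counts_dna)),
      fraction = "DNA", count = as.integer(counts_dna)
    ),
    data.frame(
      otu_id = rep(otus, times = ncol(counts_rna)),
      sample_id = rep(samples, each = nrow(counts_rna)),
      fraction = "RNA", count = as.integer(counts_rna)
    )
  )
  paired_otu_table(long)
}

# Independent patristic-distance oracle: Dijkstra-free path enumeration on
# the tree's (unrooted) weighted adjacency via breadth-first traversal.
brute_force_cophenetic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(start) {
    d <- rep(NA_real_, n_node)
    d[start] <- 0
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (is.na(d[u])) {
          d[u] <- d[v] + w
          queue <- c(queue, u)
        }
      }
    }
    d[seq_len(n_tip)]
  }
  D <- t(vapply(seq_len(n_tip), dist_from, numeric(n_tip)))
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# Brute-force MPD/MNTD by explicit loops over members.
brute_force_mpd <- function(community, D) {
  tot <- 0; np <- 0
  for (i in seq_along(community)) {
    for (j in seq_along(community)) {
      if (i < j) {
        tot <- tot + D[community[i], community[j]]
        np <- np + 1
      }
    }
  }
  tot / np
}

brute_force_mntd <- function(community, D) {
  mins <- vapply(community, function(a) {
    min(vapply(setdiff(community, a), function(b) D[a, b], numeric(1)))
  }, numeric(1))
  mean(mins)
}

# Two Yule clades of equal size glued at the root, each scaled to depth 1;
# tips "a_*" in the first clade, "b_*" in the second.
make_two_clade_tree <- function(n_per_clade, seed = 1L) {
  scale_depth <- function(tr) {
    d <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / d
    tr
  }
  t1 <- scale_depth(simulate_yule_tree(n_per_clade, 1, seed = seed))
  t2 <- scale_depth(simulate_yule_tree(n_per_clade, 1, seed = seed + 1000L))
  t1$tip.label <- paste0("a_", seq_len(n_per_clade))
  t2$tip.label <- paste0("b_", seq_len(n_per_clade))
  nwk <- sprintf("(%s:0.5,%s:0.5);",
                 sub(";$", "", ape::write.tree(t1)),
                 sub(";$", "", ape::write.tree(t2)))
  ape::read.tree(text = nwk)
}
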