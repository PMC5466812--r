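#' OTUs shared by every sample (the core microbiome)
#'
#' The "DNA core" is the set of OTUs present (count >= 1) in the DNA
#' fraction of every listed sample; the "RNA core" likewise; `mode = "both"`
#' requires presence in both fractions of every sample, the strictest
#' definition of a population-level core.
#'
#' @param table A [paired_otu_table()] (by convention unrarefied: the core
#'   is computed on the full data set).
#' @param samples Character vector of sample ids (default: all samples).
#' @param mode `"DNA"`, `"RNA"` or `"both"`.
#' @return Character vector of core OTU ids, sorted.
#' @export
shared_otus <- function(table, samples = NULL, mode = c("both", "DNA", "RNA")) {
  mode <- match.arg(mode)
  tab <- collapse_replicates(table)
  all_samples <- unique(tab$sample_id)
  if (is.null(samples)) samples <- all_samples
  unknown <- setdiff(samples, all_samples)
  if (length(unknown) > 0) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- otu_matrix(tab)
  present_in_all <- function(fr) {
    cols <- paste0(samples, "|", fr)
    rownames(m)[rowSums(m[, cols, drop = FALSE] > 0) == length(cols)]
  }
  out <- switch(mode,
    DNA = present_in_all("DNA"),
    RNA = present_in_all("RNA"),
    both = intersect(present_in_all("DNA"), present_in_all("RNA"))
  )
  sort(out)
}

#' Core size as a function of sampling effort
#'
#' Resampling curve for the shared-OTU count: for each sampling size k from
#' 1 to the number of samples, draws `n_resamples` uniform k-subsets of
#' samples (without replacement within a draw) and records the mean and sd
#' of the core size. The curve is non-increasing in k and deterministic at
#' k = n (all samples).
#'
#' @param table A [paired_otu_table()].
#' @param mode Passed to [shared_otus()].
#' @param n_resamples Resamples per sampling size (default 1000).
#' @param seed Integer seed.
#' @return A tibble of class `core_curve` with columns `sampling_size`,
#'   `mean_core_size`, `sd_core_size`, `n_resamples`, `mode`.
#' @export
core_resampling_curve <- function(table, mode = "both", n_resamples = 1000L,
                                  seed = 1L) {
  stopifnot(n_resamples >= 1)
  tab <- collapse_replicates(table)
  samples <- unique(tab$sample_id)
  n <- length(samples)
  m <- otu_matrix(tab)
  pres <- list(
    DNA = m[, paste0(samples, "|", "DNA"), drop = FALSE] > 0,
    RNA = m[, paste0(samples, "|", "RNA"), drop = FALSE] > 0
  )
  core_size <- function(idx) {
    switch(mode,
      DNA = sum(rowSums(pres$DNA[, idx, drop = FALSE]) == length(idx)),
      RNA = sum(rowSums(pres$RNA[, idx, drop = FALSE]) == length(idx)),
      both = sum(rowSums(pres$DNA[, idx, drop = FALSE] &
                           pres$RNA[, idx, drop = FALSE]) == length(idx))
    )
  }
  out <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n), function(k) {
      sizes <- if (k == n) {
        rep(core_size(seq_len(n)), 1L)
      } else {
        vapply(seq_len(n_resamples),
               function(i) core_size(sample.int(n, k)), numeric(1))
      }
      tibble::tibble(
        sampling_size = k,
        mean_core_size = mean(sizes),
        sd_core_size = if (length(sizes) > 1) stats::sd(sizes) else 0,
        n_resamples = length(sizes), mode = mode
      )
    })
  })
  class(out) <- c("core_curve", class(out))
  out
}

#' Sequence share of a core OTU set
#'
#' Fraction of all reads carried by the core OTUs, with the DNA/RNA split of
#' those core reads — the companion statistic to the core's (typically tiny)
#' OTU share.
#'
#' @param table A [paired_otu_table()].
#' @param core Character vector of OTU ids, subset of the table's OTUs.
#' @return A one-row tibble: `core_fraction` (of all reads),
#'   `core_dna_share`, `core_rna_share` (the within-core fraction split).
#' @export
core_sequence_fraction <- function(table, core) {
  tab <- collapse_replicates(table)
  unknown <- setdiff(core, unique(tab$otu_id))
  if (length(unknown) > 0) {
    stop("core OTU(s) not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  total <- sum(tab$count)
  if (total == 0) stop("empty table", call. = FALSE)
  core_tab <- tab[tab$otu_id %in% core, , drop = FALSE]
  core_total <- sum(core_tab$count)
  dna <- sum(core_tab$count[core_tab$fraction == "DNA"])
  tibble::tibble(
    core_fraction = core_total / total,
    core_dna_share = if (core_total > 0) dna / core_total else NA_real_,
    core_rna_share = if (core_total > 0) 1 - dna / core_total else NA_real_
  )
}

#' Plot a core resampling curve
#'
#' Mean core size against sampling effort with a +/- 1 sd ribbon.
#'
#' @param object A `core_curve` tibble from [core_resampling_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.core_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sampling_size,
                                       y = .data$mean_core_size)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_core_size - .data$sd_core_size,
      ymax = .data$mean_core_size + .data$sd_core_size
    ), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of samples", y = "Shared OTUs") +
    ggplot2::theme_minimal()
}
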