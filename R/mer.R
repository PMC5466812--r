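#' Mean expression ratio per OTU
#'
#' The package's activity trait: for each OTU,
#' \deqn{ratio = \frac{\overline{RA}_{RNA}}{\overline{RA}_{RNA} +
#'   \overline{RA}_{DNA}}}
#' where each mean relative abundance is taken over exactly the n samples in
#' which the OTU is present in the DNA and/or the RNA fraction (zeros in the
#' other fraction of those samples are included in the mean; samples where
#' the OTU is absent from both fractions contribute nothing). A ratio of 0
#' means the OTU was never detected in RNA, 1 never in DNA, and 0.5 that the
#' mean relative abundances were equal in the two fractions.
#'
#' The standard error defaults to the SEM of the n per-sample ratios
#' \eqn{r_i = RA_{RNA,i} / (RA_{RNA,i} + RA_{DNA,i})}; a delta-method
#' alternative propagates the SEMs of the two means through the ratio. OTUs
#' supported by a single sample have no sample-to-sample SE; they are
#' flagged and, because the measurement-error signal statistic needs finite
#' SEs, assigned the median SE of the n >= 2 OTUs (configurable).
#'
#' @param table A [paired_otu_table()]; technical replicates are summed.
#' @param se_method `"per_sample_ratio"` (SEM of per-sample ratios) or
#'   `"delta"` (delta-method from the two fraction means).
#' @param n1_se How to fill the SE of single-sample OTUs: `"median"`
#'   (median SE of multi-sample OTUs) or `"na"` (leave missing).
#' @return A tibble of class `trait_vector`: `otu_id`, `value`, `se`, `n`,
#'   `se_imputed` (TRUE where the n = 1 policy applied). OTUs absent from
#'   every sample are excluded.
#' @examples
#' # An OTU with equal mean relative abundance in both fractions -> 0.5
#' @export
mean_expression_ratio <- function(table,
                                  se_method = c("per_sample_ratio", "delta"),
                                  n1_se = c("median", "na")) {
  se_method <- match.arg(se_method)
  n1_se <- match.arg(n1_se)
  ra <- relative_abundance(table)
  wide <- tidyr::pivot_wider(
    ra[, c("otu_id", "sample_id", "fraction", "rel_abund")],
    names_from = "fraction", values_from = "rel_abund", values_fill = 0
  )
  wide <- wide[wide$DNA > 0 | wide$RNA > 0, , drop = FALSE]

  out <- dplyr::summarise(
    dplyr::group_by(wide, .data$otu_id),
    n = dplyr::n(),
    mean_ra_dna = mean(.data$DNA),
    mean_ra_rna = mean(.data$RNA),
    se_ratio = stats::sd(.data$RNA / (.data$RNA + .data$DNA)) / sqrt(dplyr::n()),
    sd_dna = stats::sd(.data$DNA),
    sd_rna = stats::sd(.data$RNA),
    .groups = "drop"
  )
  out$value <- out$mean_ra_rna / (out$mean_ra_rna + out$mean_ra_dna)
  out$se <- if (se_method == "per_sample_ratio") {
    out$se_ratio
  } else {
    delta_ratio_se(out$mean_ra_rna, out$mean_ra_dna,
                   out$sd_rna / sqrt(out$n), out$sd_dna / sqrt(out$n))
  }
  out$se_imputed <- out$n == 1L
  if (n1_se == "median" && any(out$se_imputed)) {
    fill <- stats::median(out$se[!out$se_imputed], na.rm = TRUE)
    if (!is.finite(fill)) fill <- 0
    out$se[out$se_imputed] <- fill
  }
  res <- tibble::tibble(
    otu_id = out$otu_id, value = out$value, se = out$se,
    n = as.integer(out$n), se_imputed = out$se_imputed
  )
  res <- dplyr::arrange(res, .data$otu_id)
  class(res) <- c("trait_vector", class(res))
  res
}

# First-order (delta-method) SE of r = R/(R+D) from the SEs of the two
# means, treating them as independent: |dr/dR| = D/(R+D)^2, |dr/dD| =
# R/(R+D)^2.
delta_ratio_se <- function(mean_rna, mean_dna, se_rna, se_dna) {
  s <- mean_rna + mean_dna
  sqrt((mean_dna / s^2 * se_rna)^2 + (mean_rna / s^2 * se_dna)^2)
}

#' Per-sample expression ratios of one OTU
#'
#' The ratios \eqn{r_i} underlying the default SE of
#' [mean_expression_ratio()], over the samples supporting the OTU.
#'
#' @param table A [paired_otu_table()].
#' @param otu_id A single OTU id present in the table.
#' @return A tibble: `sample_id`, `ra_dna`, `ra_rna`, `ratio`.
#' @export
per_sample_ratios <- function(table, otu_id) {
  ra <- relative_abundance(table)
  ra <- ra[ra$otu_id == otu_id, , drop = FALSE]
  if (nrow(ra) == 0) stop("unknown otu_id: ", otu_id, call. = FALSE)
  wide <- tidyr::pivot_wider(
    ra[, c("sample_id", "fraction", "rel_abund")],
    names_from = "fraction", values_from = "rel_abund", values_fill = 0
  )
  wide <- wide[wide$DNA > 0 | wide$RNA > 0, , drop = FALSE]
  if (nrow(wide) == 0) stop("OTU absent from every sample", call. = FALSE)
  tibble::tibble(
    sample_id = wide$sample_id, ra_dna = wide$DNA, ra_rna = wide$RNA,
    ratio = wide$RNA / (wide$RNA + wide$DNA)
  )
}

#' Plot mean expression ratios
#'
#' Per-OTU ratio with +/- 1 SE bars, ordered by ratio; the numeric content
#' of a tree-aligned activity barplot.
#'
#' @param object A `trait_vector` tibble from [mean_expression_ratio()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_vector <- function(object, ...) {
  df <- dplyr::mutate(object,
                      otu_id = stats::reorder(.data$otu_id, .data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$otu_id, y = .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$value - .data$se, 0),
                                        ymax = pmin(.data$value + .data$se, 1)),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean expression ratio") +
    ggplot2::theme_minimal()
}
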