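#' Hill diversity number of order q
#'
#' The effective number of equally abundant OTUs:
#' \eqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}} over positive proportions
#' \eqn{p_i}. Order 0 is OTU richness, order 1 the exponential of Shannon
#' entropy (taken as the limit, with \eqn{0 \log 0 = 0}), order 2 the
#' inverse Simpson concentration.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @param q Diversity order (>= 0).
#' @return The effective OTU number, a scalar >= 1.
#' @examples
#' hill_number(c(8, 1, 1), q = 2) # 1 / (0.8^2 + 0.1^2 + 0.1^2)
#' @export
hill_number <- function(counts, q) {
  if (q < 0) stop("q must be >= 0", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  p <- counts[counts > 0]
  if (length(p) == 0) stop("all-zero count vector", call. = FALSE)
  p <- p / sum(p)
  if (abs(q - 1) < 1e-10) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Hill diversity profile per sample and fraction
#'
#' Evaluates [hill_number()] over a grid of orders for every sample x
#' fraction column of a paired OTU table, the per-sample alpha-diversity
#' profile with richness (q = 0), Shannon (q = 1) and inverse Simpson
#' (q = 2) as special cases.
#'
#' @param table A [paired_otu_table()].
#' @param q Numeric vector of orders (default 0 to 3 in steps of 0.25).
#' @return A tibble of class `hill_profile` with columns `sample_id`,
#'   `fraction`, `q`, `diversity`.
#' @export
hill_profile <- function(table, q = seq(0, 3, by = 0.25)) {
  m <- otu_matrix(table)
  parts <- stringr::str_split_fixed(colnames(m), stringr::fixed("|"), 2)
  out <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    tibble::tibble(
      sample_id = parts[j, 1], fraction = parts[j, 2], q = q,
      diversity = vapply(q, function(qq) hill_number(m[, j], qq), numeric(1))
    )
  })
  class(out) <- c("hill_profile", class(out))
  out
}

#' Chao1 richness estimator (bias-corrected)
#'
#' Estimates total richness including unseen OTUs from the frequencies of
#' rare ones: \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1}
#' singletons and \eqn{F_2} doubletons. The bias-corrected form is finite
#' even when no doubletons are observed.
#'
#' @param counts Non-negative integer vector.
#' @return Estimated richness, always >= observed richness.
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), rep(5, 4))) # S=10, F1=4, F2=2 -> 12
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("Chao1 requires integer counts", call. = FALSE)
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Chao1 per sample x fraction column
#'
#' @param table A [paired_otu_table()].
#' @return A tibble with columns `sample_id`, `fraction`, `richness`,
#'   `chao1`.
#' @export
chao1_profile <- function(table) {
  m <- otu_matrix(table)
  parts <- stringr::str_split_fixed(colnames(m), stringr::fixed("|"), 2)
  tibble::tibble(
    sample_id = parts[, 1], fraction = parts[, 2],
    richness = colSums(m > 0),
    chao1 = apply(m, 2, chao1)
  )
}

#' Bray-Curtis dissimilarity between sample x fraction columns
#'
#' With `transform = "paper_nmds"` the counts are square-root transformed
#' and Wisconsin double-standardized (each OTU divided by its maximum across
#' columns, then each column by its total) before the Bray-Curtis
#' dissimilarity \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)} is taken —
#' the transformation stack conventionally applied ahead of NMDS ordination.
#' `"none"` computes plain Bray-Curtis on the raw counts.
#'
#' @param table A [paired_otu_table()].
#' @param transform `"paper_nmds"` (sqrt + Wisconsin) or `"none"`.
#' @return A symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames `<sample>_<FRACTION>`.
#' @export
bray_curtis_matrix <- function(table, transform = c("paper_nmds", "none")) {
  transform <- match.arg(transform)
  m <- otu_matrix(table)
  if (ncol(m) < 2) stop("need at least 2 columns", call. = FALSE)
  if (any(colSums(m) == 0)) stop("all-zero column", call. = FALSE)
  comm <- t(m) # vegan convention: sites as rows
  if (transform == "paper_nmds") {
    comm <- vegan::wisconsin(sqrt(comm))
  }
  d <- as.matrix(vegan::vegdist(comm, method = "bray"))
  dimnames(d) <- list(sub("\\|", "_", colnames(m)), sub("\\|", "_", colnames(m)))
  d
}

#' Paired comparison of per-sample diversity between fractions
#'
#' Two-sided paired test of per-sample values (e.g., DNA vs RNA alpha
#' diversity of the same plants): Student's paired t-test, or the Wilcoxon
#' signed-rank test when normality is in doubt (zero differences dropped;
#' exact null for n <= 25 without ties, normal approximation otherwise).
#' All-zero differences are degenerate and reported as p = 1 with
#' `degenerate = TRUE` rather than as an error.
#'
#' @param a,b Equal-length (>= 3) numeric vectors paired by sample.
#' @param method `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `n`,
#'   `degenerate`.
#' @export
compare_paired <- function(a, b, method = c("paired_t",
                                            "wilcoxon_signed_rank")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b differ in length", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0) || (method == "paired_t" && stats::sd(d) == 0)) {
    warning("degenerate paired comparison (constant differences); p = 1",
            call. = FALSE)
    return(tibble::tibble(method = method, statistic = NA_real_,
                          p_value = 1, n = length(a), degenerate = TRUE))
  }
  res <- if (method == "paired_t") {
    tryCatch(
      stats::t.test(a, b, paired = TRUE),
      error = function(e) {
        if (grepl("essentially constant", conditionMessage(e))) NULL
        else stop(e)
      }
    )
  } else {
    nz <- d != 0
    n_eff <- sum(nz)
    suppressWarnings(stats::wilcox.test(
      a[nz], b[nz], paired = TRUE,
      exact = n_eff <= 25 && !any(duplicated(abs(d[nz])))
    ))
  }
  if (is.null(res)) {
    warning("degenerate paired comparison (constant differences); p = 1",
            call. = FALSE)
    return(tibble::tibble(method = method, statistic = NA_real_,
                          p_value = 1, n = length(a), degenerate = TRUE))
  }
  tibble::tibble(method = method,
                 statistic = unname(res$statistic),
                 p_value = res$p.value, n = length(a), degenerate = FALSE)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Hill diversity profile
#'
#' Diversity against order q, one line per sample, coloured by fraction —
#' the standard way to show that fraction-level diversity differences are
#' concentrated among rare (low-q-sensitive) OTUs.
#'
#' @param object A `hill_profile` tibble from [hill_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$q, y = .data$diversity, colour = .data$fraction,
    group = interaction(.data$sample_id, .data$fraction)
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Hill order q", y = "Effective number of OTUs",
                  colour = "Fraction") +
    ggplot2::theme_minimal()
}
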