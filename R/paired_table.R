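#' Build a paired DNA/RNA OTU count table
#'
#' The central observation object of the package: one row per OTU x sample x
#' fraction (x optional technical replicate), holding a non-negative integer
#' read count. DNA columns describe community presence; RNA (cDNA) columns
#' describe the metabolically active community amplified from the same
#' co-extracted nucleic acids.
#'
#' @param x A data frame with columns `otu_id`, `sample_id`, `fraction`
#'   (`"DNA"` or `"RNA"`, case-insensitive) and `count`; an optional
#'   `replicate` column indexes technical replicates. Missing
#'   OTU x sample x fraction combinations are filled with zero counts so
#'   every (sample, fraction) column is complete.
#' @return A tibble of class `paired_otu_table` with columns `otu_id`,
#'   `sample_id`, `fraction`, (`replicate`,) `count`, complete over all
#'   combinations.
#' @examples
#' tab <- paired_otu_table(data.frame(
#'   otu_id = c("o1", "o1", "o2", "o2"),
#'   sample_id = "s1",
#'   fraction = c("DNA", "RNA", "DNA", "RNA"),
#'   count = c(5L, 3L, 2L, 0L)
#' ))
#' @export
paired_otu_table <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("otu_id", "sample_id", "fraction", "count")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x$fraction <- normalize_fraction(x$fraction)
  if (any(!is.finite(x$count)) || any(x$count < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(x$count != round(x$count))) {
    stop("counts must be integers", call. = FALSE)
  }
  x$otu_id <- as.character(x$otu_id)
  x$sample_id <- as.character(x$sample_id)
  x$count <- as.integer(round(x$count))

  has_rep <- "replicate" %in% names(x)
  keys <- c("otu_id", "sample_id", "fraction", if (has_rep) "replicate")
  if (anyDuplicated(x[keys]) > 0) {
    dup <- x[duplicated(x[keys]), , drop = FALSE]
    stop("duplicated entries for otu_id ",
         paste(unique(dup$otu_id), collapse = ", "), call. = FALSE)
  }
  x <- tidyr::complete(
    x,
    .data$otu_id, .data$sample_id, .data$fraction,
    !!!(if (has_rep) rlang::syms("replicate") else NULL),
    fill = list(count = 0L)
  )
  x <- dplyr::arrange(x, .data$otu_id, .data$sample_id, .data$fraction)
  class(x) <- c("paired_otu_table", class(x))
  x
}

normalize_fraction <- function(f) {
  f <- toupper(as.character(f))
  bad <- setdiff(unique(f), c("DNA", "RNA"))
  if (length(bad) > 0) {
    stop("unknown fraction label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  f
}

#' @export
print.paired_otu_table <- function(x, ...) {
  cat(sprintf(
    "<paired_otu_table> %d OTUs x %d samples x %d fraction(s)%s\n",
    dplyr::n_distinct(x$otu_id), dplyr::n_distinct(x$sample_id),
    dplyr::n_distinct(x$fraction),
    if ("replicate" %in% names(x)) {
      sprintf(" x %d replicates", dplyr::n_distinct(x$replicate))
    } else ""
  ))
  NextMethod()
}

#' Collapse technical replicates by summation
#'
#' Sums counts across the `replicate` column, returning a table with one
#' column per sample x fraction. Tables without replicates pass through.
#'
#' @param table A [paired_otu_table()].
#' @return A `paired_otu_table` without a `replicate` column.
#' @export
collapse_replicates <- function(table) {
  if (!"replicate" %in% names(table)) {
    return(table)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table),
                    .data$otu_id, .data$sample_id, .data$fraction),
    count = sum(.data$count), .groups = "drop"
  )
  paired_otu_table(out)
}

# Wide matrix view: rows = OTUs, columns = "<sample>|<fraction>" (replicates
# summed). Internal workhorse for diversity/core/structure stages.
otu_matrix <- function(table, fraction = NULL) {
  tab <- collapse_replicates(table)
  if (!is.null(fraction)) {
    tab <- tab[tab$fraction %in% normalize_fraction(fraction), , drop = FALSE]
  }
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(tab),
    id_cols = "otu_id",
    names_from = c("sample_id", "fraction"),
    names_sep = "|",
    values_from = "count",
    values_fill = 0L
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$otu_id
  storage.mode(m) <- "integer"
  m
}

#' Read a paired OTU table from TSV
#'
#' Expects a first column `otu_id` and one column per sample x fraction
#' (x optional replicate) named `<sample>_<DNA|RNA>` or
#' `<sample>_<DNA|RNA>_rep<k>`. Fraction labels are case-insensitive on read
#' and written back in canonical upper case.
#'
#' @param path Path to a tab-separated file.
#' @return A [paired_otu_table()].
#' @export
read_paired_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    otu_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(raw)[1] != "otu_id") {
    stop("first column must be 'otu_id', found '", names(raw)[1], "'",
         call. = FALSE)
  }
  if (anyDuplicated(raw$otu_id) > 0) {
    stop("duplicated otu_id: ",
         paste(unique(raw$otu_id[duplicated(raw$otu_id)]), collapse = ", "),
         call. = FALSE)
  }
  cols <- names(raw)[-1]
  m <- stringr::str_match(cols, "^(.+)_([DdRr][Nn][Aa])(?:_rep(\\d+))?$")
  bad <- cols[is.na(m[, 1])]
  if (length(bad) > 0) {
    stop("cannot parse sample/fraction from column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_cells <- which(as.matrix(raw[, -1]) < 0 |
                       as.matrix(raw[, -1]) != round(as.matrix(raw[, -1])),
                     arr.ind = TRUE)
  if (nrow(bad_cells) > 0) {
    stop(sprintf(
      "negative or non-integer count at row %d, column '%s'",
      bad_cells[1, 1], cols[bad_cells[1, 2]]
    ), call. = FALSE)
  }
  long <- tidyr::pivot_longer(raw, -"otu_id",
                              names_to = "column", values_to = "count")
  key <- match(long$column, cols)
  long$sample_id <- m[key, 2]
  long$fraction <- toupper(m[key, 3])
  has_rep <- any(!is.na(m[, 4]))
  if (has_rep) {
    if (any(is.na(m[, 4]))) {
      stop("mixed replicated and unreplicated columns", call. = FALSE)
    }
    long$replicate <- as.integer(m[key, 4])
  }
  long$column <- NULL
  paired_otu_table(long)
}

#' Write a paired OTU table to TSV
#'
#' Inverse of [read_paired_table()]: columns `<sample>_<FRACTION>[_rep<k>]`,
#' fractions upper-cased, bit-exact round trip.
#'
#' @param table A [paired_otu_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paired_table <- function(table, path) {
  tab <- tibble::as_tibble(table)
  if ("replicate" %in% names(tab)) {
    tab$column <- sprintf("%s_%s_rep%d", tab$sample_id, tab$fraction,
                          tab$replicate)
  } else {
    tab$column <- sprintf("%s_%s", tab$sample_id, tab$fraction)
  }
  wide <- tidyr::pivot_wider(
    tab[, c("otu_id", "column", "count")],
    names_from = "column", values_from = "count", values_fill = 0L
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Retain sequences identical across technical replicates
#'
#' Applies the replicate-consensus rule used when technical PCR replicates of
#' the same library are sequenced: only sequences whose exact string occurs
#' in every replicate are kept, and the retained multiplicity is the summed
#' count across replicates.
#'
#' @param replicates A list (length >= 2) of character vectors, each a
#'   sequence multiset for one technical replicate.
#' @return A tibble with columns `sequence` and `count` (summed across
#'   replicates), sorted by sequence.
#' @examples
#' replicate_consensus_filter(list(c("A", "A", "B"), c("A", "B")))
#' @export
replicate_consensus_filter <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 2) {
    stop("need at least 2 technical replicates", call. = FALSE)
  }
  tabs <- lapply(replicates, function(r) table(as.character(r)))
  shared <- Reduce(intersect, lapply(tabs, names))
  counts <- vapply(shared, function(s) {
    sum(vapply(tabs, function(t) as.integer(t[[s]]), integer(1)))
  }, integer(1))
  out <- tibble::tibble(sequence = as.character(shared),
                        count = as.integer(counts))
  dplyr::arrange(out, .data$sequence)
}

#' Rarefy every sample x fraction column to a fixed depth
#'
#' Subsamples each column without replacement to exactly `depth` reads
#' (a single draw, not an average over draws). Columns whose total is below
#' `depth` are an error by default; with `drop_low = TRUE` they are removed
#' and reported via a warning, mirroring the decision to exclude rather than
#' pad under-sequenced libraries.
#'
#' @param table A [paired_otu_table()] (replicates are collapsed first).
#' @param depth Target reads per sample x fraction column.
#' @param seed Integer seed; the draw is reproducible.
#' @param drop_low Drop deficient columns instead of erroring.
#' @return A rarefied `paired_otu_table`.
#' @export
rarefy_table <- function(table, depth, seed = 1L, drop_low = FALSE) {
  stopifnot(depth > 0)
  tab <- collapse_replicates(table)
  m <- otu_matrix(tab)
  totals <- colSums(m)
  low <- names(totals)[totals < depth]
  if (length(low) > 0) {
    msg <- paste0("column total below rarefaction depth ", depth, ": ",
                  paste(sub("\\|", "_", low), collapse = ", "))
    if (!drop_low) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    m <- m[, setdiff(colnames(m), low), drop = FALSE]
  }
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(m))) {
      if (sum(m[, j]) == depth) next
      pool <- rep.int(seq_len(nrow(m)), m[, j])
      keep <- sample(pool, depth, replace = FALSE)
      m[, j] <- tabulate(keep, nbins = nrow(m))
    }
  })
  matrix_to_paired(m)
}

# Reconstructs a paired_otu_table from the "<sample>|<fraction>" matrix view.
matrix_to_paired <- function(m) {
  parts <- stringr::str_split_fixed(colnames(m), stringr::fixed("|"), 2)
  long <- tibble::tibble(
    otu_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(parts[, 1], each = nrow(m)),
    fraction = rep(parts[, 2], each = nrow(m)),
    count = as.integer(m)
  )
  paired_otu_table(long)
}

#' Per-column relative abundances
#'
#' Converts counts to proportions within each sample x fraction column;
#' every column of the result sums to one.
#'
#' @param table A [paired_otu_table()].
#' @return A tibble with columns `otu_id`, `sample_id`, `fraction`,
#'   `count`, `rel_abund`.
#' @export
relative_abundance <- function(table) {
  tab <- tibble::as_tibble(collapse_replicates(table))
  out <- dplyr::mutate(
    dplyr::group_by(tab, .data$sample_id, .data$fraction),
    total = sum(.data$count)
  )
  if (any(out$total == 0)) {
    bad <- unique(paste0(out$sample_id[out$total == 0], "_",
                         out$fraction[out$total == 0]))
    stop("all-zero column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::ungroup(dplyr::mutate(out, rel_abund = .data$count / .data$total))
  out$total <- NULL
  out
}
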