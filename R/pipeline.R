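#' Run the full ecophylogenetic pipeline
#'
#' Config-driven orchestration of the whole analysis on either simulated or
#' loaded inputs: (simulate or read) paired counts and tree -> collapse
#' technical replicates -> optional rarefaction -> Hill/Chao1 diversity ->
#' core-microbiome resampling curve -> mean expression ratio -> phylogenetic
#' structure (SES of MPD/MNTD) -> phylogenetic signal (Kse). Every stage
#' writes a TSV into `out_dir` and a JSON run manifest records the config,
#' derived stage seeds and per-stage row counts, sufficient to re-run
#' bit-identically.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   elements:
#'   \describe{
#'     \item{simulate}{list of arguments for [simulate_microbiome()]; used
#'       when no `table_path` is given.}
#'     \item{table_path, tree_path}{paths to a TSV paired table and a Newick
#'       tree, used instead of simulation.}
#'     \item{rarefy_depth}{optional depth; columns below it are dropped with
#'       a warning.}
#'     \item{n_permutations}{permutations for structure and signal stages
#'       (default 999).}
#'     \item{seed}{master seed (default 1).}
#'   }
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the stage tibbles (`diversity`, `core`,
#'   `core_curve`, `mer`, `structure`, `signal`) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- as.integer(config$n_permutations %||% 999L)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  if (!is.null(config$table_path)) {
    table <- read_paired_table(config$table_path)
    tree <- ape::read.tree(config$tree_path)
    note("loaded table from ", config$table_path)
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    sim <- do.call(simulate_microbiome, sim_args)
    table <- sim$table
    tree <- sim$tree
    write_paired_table(table, file.path(out_dir, "simulated_counts.tsv"))
    ape::write.tree(tree, file.path(out_dir, "simulated_tree.nwk"))
    readr::write_tsv(sim$activity, file.path(out_dir, "simulated_activity.tsv"),
                     progress = FALSE)
    note("simulated data with seed ", sim_args$seed)
  }

  full_table <- collapse_replicates(table)
  analysis_table <- full_table
  if (!is.null(config$rarefy_depth)) {
    analysis_table <- withCallingHandlers(
      rarefy_table(full_table, depth = config$rarefy_depth,
                   seed = derive_seeds(seed, 5)[5], drop_low = TRUE),
      warning = function(w) {
        note("rarefaction: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    note("rarefied to depth ", config$rarefy_depth)
  }

  diversity <- dplyr::left_join(
    hill_profile(analysis_table),
    chao1_profile(analysis_table),
    by = c("sample_id", "fraction")
  )
  readr::write_tsv(diversity, file.path(out_dir, "diversity.tsv"),
                   progress = FALSE)

  # core uses the full (unrarefied) data set by convention
  core <- shared_otus(full_table, mode = "both")
  core_stats <- core_sequence_fraction(full_table, core)
  core_curve <- core_resampling_curve(
    full_table, mode = "both",
    n_resamples = as.integer(config$core_resamples %||% 1000L),
    seed = derive_seeds(seed, 6)[6]
  )
  readr::write_tsv(core_curve, file.path(out_dir, "core_curve.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(otu_id = core),
                   file.path(out_dir, "core_otus.tsv"), progress = FALSE)
  readr::write_tsv(core_stats, file.path(out_dir, "core_stats.tsv"),
                   progress = FALSE)

  mer <- withCallingHandlers(
    mean_expression_ratio(analysis_table),
    warning = function(w) {
      note("mer: ", conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  readr::write_tsv(mer, file.path(out_dir, "mean_expression_ratio.tsv"),
                   progress = FALSE)

  structure <- withCallingHandlers(
    structure_table(analysis_table, tree, n_permutations = n_perm,
                    seed = derive_seeds(seed, 7)[7]),
    warning = function(w) {
      note("structure: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  readr::write_tsv(structure, file.path(out_dir, "structure.tsv"),
                   progress = FALSE)

  signal <- withCallingHandlers(
    signal_table(tree, mer, n_permutations = n_perm,
                 seed = derive_seeds(seed, 8)[8]),
    warning = function(w) {
      note("signal: ", conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  readr::write_tsv(signal, file.path(out_dir, "signal.tsv"),
                   progress = FALSE)

  manifest <- list(
    tool = "ecophylo",
    version = as.character(utils::packageVersion("ecophylo")),
    config = config,
    seed = seed,
    stage_seeds = list(
      rarefy = derive_seeds(seed, 5)[5], core = derive_seeds(seed, 6)[6],
      structure = derive_seeds(seed, 7)[7], signal = derive_seeds(seed, 8)[8]
    ),
    rows = list(
      diversity = nrow(diversity), core_curve = nrow(core_curve),
      core_otus = length(core), mer = nrow(mer),
      structure = nrow(structure), signal = nrow(signal)
    ),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(diversity = diversity, core = core,
                 core_stats = core_stats, core_curve = core_curve,
                 mer = mer, structure = structure, signal = signal,
                 manifest = manifest))
}
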