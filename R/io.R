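# File formats, configuration and the end-to-end pipeline.

#' Read a protein FASTA file
#'
#' @param path FASTA file path (single- or multi-record).
#' @return data.frame with `id` (first token of the header), `description`
#'   (full header) and `sequence` (upper-cased, `*` stripped).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  headers <- names(set)
  seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  data.frame(
    id = vapply(strsplit(headers, "[ \t]"), `[[`, character(1), 1),
    description = headers,
    sequence = unname(seqs)
  )
}

#' Write sequences to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

# Reject sequences the library builder cannot handle.
.check_library_sequence <- function(sequence) {
  bad <- regmatches(sequence, gregexpr("[UBZX]", sequence))[[1]]
  if (length(bad) > 0) {
    stop("sequence contains ambiguous/non-standard residues (",
         paste(unique(bad), collapse = ", "),
         "); library building needs the 20 standard amino acids")
  }
  invisible(sequence)
}

#' Write / read the library table
#'
#' The library table (`peptide_id`, `sequence`, `link_site`, `group_id`) is
#' written as CSV with a JSON sidecar (`<path>.json`) recording the seed,
#' group sizes and filter settings, so a partition can be reconstructed
#' exactly.
#'
#' @param partition A [partition_groups()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(partition, path) {
  lib <- partition$library[, c("peptide_id", "sequence", "link_site", "group_id")]
  utils::write.csv(lib, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(seed = partition$seed, sizes = partition$sizes)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("peptide_id", "sequence", "link_site", "group_id")
  if (!all(needed %in% names(lib))) {
    stop("library table needs columns: ", paste(needed, collapse = ", "))
  }
  sidecar_path <- paste0(path, ".json")
  seed <- 1L
  sizes <- as.integer(table(lib$group_id))
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    seed <- as.integer(sidecar$seed)
    sizes <- as.integer(sidecar$sizes)
  }
  groups <- split(lib$peptide_id, lib$group_id)
  structure(list(library = lib, groups = groups, sizes = sizes, seed = seed),
            class = "group_partition")
}

#' Write / read a CSM table
#'
#' @param csms CSM data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_csm_table <- function(csms, path) {
  utils::write.csv(csms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_csm_table
#' @export
read_csm_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' A single validated configuration object for [run_pipeline()]; unknown
#' fields are rejected.
#'
#' @param fasta Path to the protein FASTA, or `NULL` with `sequence` given
#'   directly.
#' @param sequence Protein sequence string (alternative to `fasta`).
#' @param outdir Output directory.
#' @param crosslinker Crosslinker name (default `"DSS"`).
#' @param n_peptides,group_sizes,min_len,max_len Library design parameters.
#' @param seed Master seed; stage seeds derive from it.
#' @param simulation A [simulation_config()] (defaults to one built from
#'   `seed`).
#' @param search A [search_config()].
#' @param decoy_strategy Decoy generation strategy for the search database.
#' @param fdr_level,target_fdr Validation level and target.
#' @param exclude_homodimers Evaluation switch.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, sequence = NULL,
                            outdir = tempfile("xlbench_run_"),
                            crosslinker = "DSS",
                            n_peptides = 95, group_sizes = NULL,
                            min_len = 5, max_len = 20,
                            seed = 1L,
                            simulation = NULL,
                            search = search_config(),
                            decoy_strategy = "shuffle_keep_sites",
                            fdr_level = "csm", target_fdr = 0.05,
                            exclude_homodimers = FALSE) {
  if (is.null(fasta) && is.null(sequence)) {
    stop("either 'fasta' or 'sequence' must be given")
  }
  if (is.null(simulation)) simulation <- simulation_config(seed = seed)
  fdr_level <- match.arg(fdr_level, c("csm", "unique_csm", "peptide_pair"))
  structure(list(
    fasta = fasta, sequence = sequence, outdir = outdir,
    crosslinker = crosslinker, n_peptides = n_peptides,
    group_sizes = group_sizes, min_len = min_len, max_len = max_len,
    seed = as.integer(seed), simulation = simulation, search = search,
    decoy_strategy = decoy_strategy, fdr_level = fdr_level,
    target_fdr = target_fdr, exclude_homodimers = exclude_homodimers
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `simulation`
#' and `search` are nested maps passed to [simulation_config()] and
#' [search_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), c("simulation", "search"))
  unknown <- setdiff(names(cfg), c(known, "simulation", "search"))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$simulation)) {
    cfg$simulation <- do.call(simulation_config, cfg$simulation)
  }
  if (!is.null(cfg$search)) cfg$search <- do.call(search_config, cfg$search)
  do.call(pipeline_config, cfg)
}

#' Run the full benchmark pipeline
#'
#' Executes design -> simulate -> search -> validate -> evaluate, writing
#' every intermediate to `config$outdir`: `library.csv` (+ JSON sidecar),
#' `ground_truth.csv`, `spectra.mgf`, `manifest.csv`, `results.csv`,
#' `accepted.csv` and `report.json`, plus a `run_manifest.json` with the
#' resolved seeds, package version, per-file MD5 digests and timestamps.
#' Identical configurations produce identical output digests.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default TRUE).
#' @return A list with `partition`, `ground_truth`, `spectra` (paths),
#'   `results`, `validation`, `report` and `manifest` (the run manifest).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- function(f) file.path(config$outdir, f)

  # --- design
  say("stage design")
  sequence <- if (!is.null(config$sequence)) config$sequence else
    read_fasta(config$fasta)$sequence[1]
  .check_library_sequence(sequence)
  partition <- build_library(sequence, n_peptides = config$n_peptides,
                             group_sizes = config$group_sizes,
                             seed = config$seed,
                             min_len = config$min_len,
                             max_len = config$max_len)
  ground_truth <- enumerate_potential_crosslinks(partition)
  write_library(partition, out("library.csv"))
  utils::write.csv(ground_truth$species, out("ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- simulate
  say("stage simulate")
  xl <- crosslinker(config$crosslinker)
  sim <- simulate_spectra(ground_truth, xl, config$simulation)
  write_mgf(sim$spectra, out("spectra.mgf"))
  utils::write.csv(sim$manifest, out("manifest.csv"), row.names = FALSE,
                   quote = FALSE)

  # --- search
  say("stage search")
  db <- build_candidates(partition$library, xl,
                         decoy_strategy = config$decoy_strategy,
                         seed = config$seed + 1L)
  results <- search_spectra(sim$spectra, db, config$search)
  write_csm_table(results, out("results.csv"))

  # --- validate
  say("stage validate")
  validation <- apply_cutoff(results, level = config$fdr_level,
                             target_fdr = config$target_fdr)
  write_csm_table(validation$accepted_targets, out("accepted.csv"))

  # --- evaluate
  say("stage evaluate")
  report <- calculated_fdr(validation$accepted_targets, partition,
                           level = config$fdr_level,
                           estimated_fdr = validation$estimated_fdr,
                           exclude_homodimers = config$exclude_homodimers)
  redundancy <- csm_redundancy(validation$accepted_targets, partition)
  accounting <- spectra_accounting(
    vapply(sim$spectra, `[[`, integer(1), "scan_id"),
    results, validation$accepted_targets, truth = sim$manifest)
  report_json <- list(
    schema_version = "1.0",
    level = report$level,
    n_correct = report$n_correct,
    n_incorrect = report$n_incorrect,
    calculated_fdr = report$calculated_fdr,
    calculated_fdr_pct_display = round(100 * report$calculated_fdr, 1),
    estimated_fdr = report$estimated_fdr,
    score_threshold = if (is.finite(validation$score_threshold))
      validation$score_threshold else "Inf",
    redundancy = redundancy,
    spectra_accounting = as.list(accounting$counts)
  )
  jsonlite::write_json(report_json, out("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)

  files <- c("library.csv", "library.csv.json", "ground_truth.csv",
             "spectra.mgf", "manifest.csv", "results.csv", "accepted.csv",
             "report.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("xlbench")),
    seed = config$seed,
    crosslinker = xl$name,
    fdr_level = config$fdr_level,
    target_fdr = config$target_fdr,
    digests = as.list(tools::md5sum(file.path(config$outdir, files))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  list(partition = partition, ground_truth = ground_truth,
       spectra_path = out("spectra.mgf"), results = results,
       validation = validation, report = report, redundancy = redundancy,
       accounting = accounting, manifest = manifest)
}
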