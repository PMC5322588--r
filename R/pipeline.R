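# End-to-end orchestration: simulate (or read) -> curate -> extract ->
# distances -> evaluate -> summarize, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Every stage parameter with its default, plus input/output paths. The
#' input is either a list of [genus_sim_config()]s (`genera`, optionally
#' with `defects`) or a FASTA/TSV pair (`input_fasta`, `input_metadata`).
#'
#' @param outdir Output directory.
#' @param genera List of [genus_sim_config()] for the simulate stage.
#' @param defects Optional [defect_config()] for the simulate stage.
#' @param input_fasta,input_metadata Paths of an existing dataset (used when
#'   `genera` is `NULL`).
#' @param enrichment Optional enrichment TSV applied after reading.
#' @param anchors An [anchor_config()].
#' @param min_localities,min_species Curation thresholds.
#' @param markers Markers to evaluate.
#' @param mode Alignment mode for [genus_distance_matrix()].
#' @param match,mismatch,gap Alignment scoring.
#' @param gap_columns Gap-column policy (prealigned mode).
#' @param seed Master seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            genera = NULL,
                            defects = NULL,
                            input_fasta = NULL,
                            input_metadata = NULL,
                            enrichment = NULL,
                            anchors = anchor_config(),
                            min_localities = 3,
                            min_species = 2,
                            markers = c("ITS", "ITS1", "ITS2"),
                            mode = "pairwise",
                            match = 1, mismatch = -1, gap = -2,
                            gap_columns = "pairwise",
                            seed = 1) {
  if (is.null(genera) && (is.null(input_fasta) || is.null(input_metadata)))
    stop("provide either `genera` or `input_fasta` + `input_metadata`",
         call. = FALSE)
  structure(list(
    outdir = outdir, genera = genera, defects = defects,
    input_fasta = input_fasta, input_metadata = input_metadata,
    enrichment = enrichment, anchors = anchors,
    min_localities = min_localities, min_species = min_species,
    markers = markers, mode = mode, match = match, mismatch = mismatch,
    gap = gap, gap_columns = gap_columns,
    seed = check_count(seed, "seed", min = 0)
  ), class = "pipeline_config")
}

#' Run the full marker-evaluation pipeline
#'
#' Executes the stages in order, writes per-stage artifacts under
#' `config$outdir` (simulated/curated FASTA+TSV, curation report JSON,
#' region FASTAs, per-genus distance matrices, the evaluation table, and
#' the marker summary JSON), and a `manifest.json` with parameters,
#' per-stage record counts, and md5 hashes of every output. Identical
#' (config, seed) pairs give identical manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  if (!is.null(config$genera)) {
    genera <- lapply(config$genera, function(g) {
      g$seed <- derive_seed(config$seed, paste0("pipeline:", g$genus_name,
                                                ":", g$seed))
      g
    })
    defects <- config$defects
    if (!is.null(defects))
      defects$seed <- derive_seed(config$seed,
                                  paste0("pipeline:defects:", defects$seed))
    records <- generate_dataset(genera, defects)
    write_dataset(records, file.path(config$outdir, "simulated.fasta"),
                  file.path(config$outdir, "simulated.tsv"))
  } else {
    records <- read_dataset(config$input_fasta, config$input_metadata)
  }
  if (!is.null(config$enrichment))
    records <- enrich_metadata(records, config$enrichment)
  counts$input <- nrow(records)

  cur <- run_curation(records, anchors = config$anchors,
                      min_localities = config$min_localities,
                      min_species = config$min_species)
  curated <- cur$records
  counts$curated <- nrow(curated)
  write_dataset(curated, file.path(config$outdir, "curated.fasta"),
                file.path(config$outdir, "curated.tsv"))
  write_curation_report(cur$report,
                        file.path(config$outdir, "curation_report.json"))
  write_regions(curated, config$outdir, "curated")

  genera_names <- unique(curated$genus)
  counts$genera <- length(genera_names)
  dist_dir <- file.path(config$outdir, "distances")
  dir.create(dist_dir, showWarnings = FALSE)
  eval_rows <- list()
  skipped <- character(0)
  for (g in genera_names) {
    sub <- curated[curated$genus == g, , drop = FALSE]
    res <- tryCatch({
      for (m in config$markers) {
        dm <- genus_distance_matrix(sub, marker = m, mode = config$mode,
                                    gap_columns = config$gap_columns,
                                    match = config$match,
                                    mismatch = config$mismatch,
                                    gap = config$gap)
        write_distance_matrix(dm, file.path(dist_dir,
                                            paste0(g, ".", m, ".tsv")))
      }
      evaluate_genus(sub, markers = config$markers, mode = config$mode,
                     gap_columns = config$gap_columns, match = config$match,
                     mismatch = config$mismatch, gap = config$gap)
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, g) else eval_rows[[g]] <- res
  }
  evaluation <- dplyr::bind_rows(eval_rows)
  counts$evaluated_genera <- length(eval_rows)
  counts$skipped_genera <- length(skipped)

  if (nrow(evaluation) > 0) {
    eval_flat <- evaluation[, c("genus", "marker", "pci", "gap_class",
                                "n_seqs", "n_species",
                                intersect(c("group", "recommended"),
                                          names(evaluation)))]
    eval_flat$gap_class <- as.character(eval_flat$gap_class)
  } else {
    eval_flat <- tibble::tibble(genus = character(0), marker = character(0),
                                pci = numeric(0), gap_class = character(0),
                                n_seqs = integer(0), n_species = integer(0))
  }
  readr::write_tsv(eval_flat, file.path(config$outdir, "evaluation.tsv"),
                   progress = FALSE)

  summary_json <- NULL
  if (nrow(evaluation) > 0 && setequal(config$markers, MARKERS)) {
    wide <- tidyr::pivot_wider(
      eval_flat[, c("genus", "marker", "pci")],
      names_from = "marker", values_from = "pci")
    names(wide) <- tolower(names(wide))
    tab <- tibble::tibble(genus = wide$genus,
                          its = 100 * wide$its,
                          its1 = 100 * wide$its1,
                          its2 = 100 * wide$its2)
    readr::write_tsv(tab, file.path(config$outdir, "pci_table.tsv"),
                     progress = FALSE)
    summary_json <- list(
      mean_pci = lapply(stats::setNames(MARKERS, MARKERS),
                        function(m) mean_pci(tab, m)),
      frac_above_mean = lapply(stats::setNames(MARKERS, MARKERS),
                               function(m) fraction_above_mean(tab, m)),
      spearman = if (nrow(tab) >= 3) list(
        its_its1 = tryCatch(spearman_rho(tab$its, tab$its1),
                            error = function(e) NA),
        its_its2 = tryCatch(spearman_rho(tab$its, tab$its2),
                            error = function(e) NA),
        its1_its2 = tryCatch(spearman_rho(tab$its1, tab$its2),
                             error = function(e) NA)) else NULL,
      group_counts = as.list(table(eval_flat$group[!duplicated(
        eval_flat$genus)]))
    )
    jsonlite::write_json(summary_json,
                         file.path(config$outdir, "marker_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  outputs <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(config$outdir, "manifest.json"))
  manifest <- list(
    seed = config$seed,
    parameters = list(min_localities = config$min_localities,
                      min_species = config$min_species,
                      markers = config$markers, mode = config$mode,
                      match = config$match, mismatch = config$mismatch,
                      gap = config$gap, gap_columns = config$gap_columns),
    counts = counts,
    skipped_genera = skipped,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(sort(outputs))),
      substring(sort(outputs), nchar(config$outdir) + 2)))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
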