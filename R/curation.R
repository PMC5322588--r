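# The quality/logic filter cascade. Each filter is a pure
# record-set -> record-set function; run_curation() fixes the order
# (voucher, ambiguity, names, ITS completeness, lengths, localities,
# minimum species per genus) and keeps per-stage accounting.

#' Keep records with a non-empty voucher
#'
#' Barcode-grade data must trace back to a preserved specimen in a permanent
#' collection; records without a voucher id are removed. Only non-emptiness
#' is tested — no voucher-format validation.
#'
#' @param records Specimen-record tibble.
#' @return Filtered tibble.
#' @export
filter_voucher <- function(records) {
  records[nzchar(trimws(records$voucher)), , drop = FALSE]
}

#' Remove sequences containing IUPAC ambiguity codes
#'
#' A single ambiguous character (anything outside `{A,C,G,T}` after
#' canonicalization) removes the record: ambiguity codes flag low-confidence
#' base calls that would distort distance estimates.
#'
#' @inheritParams filter_voucher
#' @return Filtered tibble.
#' @export
filter_ambiguous <- function(records) {
  records[!grepl("[^ACGT]", records$sequence), , drop = FALSE]
}

#' Remove records with inconclusive species names
#'
#' Removes records whose organism name (epithet plus qualifiers) contains any
#' of the tokens `sp.`, `aff.`, `cf.`, `uncultured` as a whole token,
#' case-insensitive. Tokenization splits on whitespace and strips trailing
#' periods, so epithets that merely contain the letters (e.g. "crassifolia"
#' containing "cf") are not false hits.
#'
#' @inheritParams filter_voucher
#' @return Filtered tibble.
#' @export
filter_species_names <- function(records) {
  bad_tokens <- c("sp", "aff", "cf", "uncultured")
  has_bad <- vapply(species_name(records), function(nm) {
    tokens <- sub("\\.+$", "", tolower(strsplit(trimws(nm), "\\s+")[[1]]))
    any(tokens %in% bad_tokens)
  }, logical(1), USE.NAMES = FALSE)
  records[!has_bad, , drop = FALSE]
}

#' Keep records with a complete, extractable ITS region
#'
#' Attempts the ITS1/5.8S/ITS2 split on every record; records for which both
#' anchors are found and all three parts are non-empty are kept, with the
#' extracted regions and their coordinates attached as columns (`its1`,
#' `s58`, `its2`, `its1_start`, ..., `its2_end`; 0-based half-open).
#' Failures are removals, not errors.
#'
#' @inheritParams filter_voucher
#' @param anchors An [anchor_config()] passed to [split_its()].
#' @return Filtered tibble with region columns attached.
#' @export
filter_its_complete <- function(records, anchors = anchor_config()) {
  extracted <- extract_regions(records, anchors)
  attr(extracted, "n_split_failures") <- NULL
  extracted[!is.na(extracted$its1), , drop = FALSE]
}

#' Keep records within the barcode length window
#'
#' Keeps records whose full ITS length is within `[400, 800]` bp (inclusive
#' at both ends) and whose ITS1 and ITS2 are each at least 100 bp. Requires
#' regions attached by [filter_its_complete()].
#'
#' @inheritParams filter_voucher
#' @return Filtered tibble.
#' @export
filter_lengths <- function(records) {
  if (!"its1" %in% names(records))
    stop("records lack extracted regions; run filter_its_complete() first",
         call. = FALSE)
  full <- nchar(records$sequence)
  keep <- full >= 400 & full <= 800 &
    nchar(records$its1) >= 100 & nchar(records$its2) >= 100
  records[keep, , drop = FALSE]
}

#' Keep species sampled from enough distinct localities
#'
#' First drops records with an empty locality, then keeps only species
#' (grouped by genus and full species name) whose remaining records span at
#' least `min_localities` distinct localities (exact string match after
#' trimming and case-folding). All records of failing species are removed.
#' Requiring geographically distinct sampling guards against scoring a
#' species' intraspecific variation from near-clonal resampling.
#'
#' @inheritParams filter_voucher
#' @param min_localities Minimum number of distinct localities (default 3).
#' @return Filtered tibble.
#' @export
filter_localities <- function(records, min_localities = 3) {
  min_localities <- check_count(min_localities, "min_localities")
  located <- records[nzchar(trimws(records$locality)), , drop = FALSE]
  if (nrow(located) == 0) return(located)
  key <- paste(located$genus, species_name(located), sep = "\r")
  n_loc <- tapply(tolower(trimws(located$locality)), key,
                  function(x) length(unique(x)))
  keep <- n_loc[match(key, names(n_loc))] >= min_localities
  keep[is.na(keep)] <- FALSE
  located[keep, , drop = FALSE]
}

#' Keep genera with enough distinct species
#'
#' Intraspecific and interspecific distances can only be contrasted when a
#' genus retains at least `min_species` distinct species; all records of
#' genera below the threshold are removed.
#'
#' @inheritParams filter_voucher
#' @param min_species Minimum distinct species per genus (default 2).
#' @return Filtered tibble.
#' @export
filter_min_species_per_genus <- function(records, min_species = 2) {
  min_species <- check_count(min_species, "min_species")
  if (nrow(records) == 0) return(records)
  n_sp <- tapply(species_name(records), records$genus,
                 function(x) length(unique(x)))
  keep <- n_sp[match(records$genus, names(n_sp))] >= min_species
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Run the full curation cascade
#'
#' Applies, in order: voucher, ambiguity, species-name, ITS-completeness,
#' length, locality, and minimum-species filters, recording a per-stage
#' report (stage name, records in, records out, removed accessions).
#'
#' @inheritParams filter_voucher
#' @param anchors An [anchor_config()] for the ITS-completeness stage.
#' @param min_localities Passed to [filter_localities()].
#' @param min_species Passed to [filter_min_species_per_genus()].
#' @return A list with elements `records` (the curated tibble, regions
#'   attached) and `report` (a tibble with columns `stage`, `n_in`, `n_out`,
#'   and list-column `removed`).
#' @export
run_curation <- function(records, anchors = anchor_config(),
                         min_localities = 3, min_species = 2) {
  stages <- list(
    voucher = filter_voucher,
    ambiguity = filter_ambiguous,
    species_names = filter_species_names,
    its_complete = function(r) filter_its_complete(r, anchors),
    lengths = filter_lengths,
    localities = function(r) filter_localities(r, min_localities),
    min_species_per_genus = function(r)
      filter_min_species_per_genus(r, min_species)
  )
  report <- vector("list", length(stages))
  current <- records
  for (k in seq_along(stages)) {
    n_in <- nrow(current)
    nxt <- stages[[k]](current)
    report[[k]] <- tibble::tibble(
      stage = names(stages)[k],
      n_in = n_in,
      n_out = nrow(nxt),
      removed = list(setdiff(current$accession, nxt$accession))
    )
    current <- nxt
  }
  list(records = current, report = dplyr::bind_rows(report))
}

#' Write a curation report as JSON
#'
#' @param report The `report` tibble from [run_curation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curation_report <- function(report, path) {
  payload <- lapply(seq_len(nrow(report)), function(k) list(
    stage = report$stage[k],
    n_in = report$n_in[k],
    n_out = report$n_out[k],
    removed_accessions = report$removed[[k]]
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
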