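# Specimen-record I/O: FASTA + metadata TSV, and the enrichment join.
#
# Metadata deliberately lives in a TSV keyed by accession rather than in
# FASTA headers: public-repository header dialects vary, a join table is the
# stable contract. FASTA headers carry the accession only.

METADATA_COLUMNS <- c("accession", "genus", "species", "voucher", "country")

blank_na <- function(x) ifelse(is.na(x), "", x)

# Split a species string into (epithet, qualifiers): first whitespace token
# vs the remainder.
split_species <- function(species) {
  species <- trimws(blank_na(species))
  epithet <- sub("\\s.*$", "", species)
  qualifiers <- trimws(sub("^\\S+\\s*", "", species))
  list(epithet = epithet, qualifiers = qualifiers)
}

#' Full species name of each record
#'
#' @param records Specimen-record tibble.
#' @return Character vector: `species_epithet` and `name_qualifiers` joined
#'   by a space, trimmed.
#' @export
species_name <- function(records) {
  trimws(paste(records$species_epithet, records$name_qualifiers))
}

read_metadata_tsv <- function(path, context = "metadata") {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  missing <- setdiff(METADATA_COLUMNS, names(meta))
  if (length(missing) > 0)
    stop(context, " file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$accession))
    stop("duplicate accession in ", context, " file", call. = FALSE)
  meta
}

#' Read a specimen dataset from FASTA plus metadata TSV
#'
#' One record per FASTA entry, outer-joined to the metadata table by
#' accession (the FASTA header up to the first whitespace). Entries with no
#' metadata row get empty genus/species/voucher/locality and survive only
#' until the relevant curation filter. Sequences are uppercased and `U`
#' normalized to `T`. Metadata rows with no FASTA entry are ignored; their
#' count is reported via a message and the `n_unmatched_metadata` attribute.
#'
#' @param fasta Path to a FASTA file with unique ids.
#' @param metadata Path to a TSV with columns
#'   `accession, genus, species, voucher, country`.
#' @return A specimen-record tibble.
#' @export
read_dataset <- function(fasta, metadata) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate accession in FASTA file", call. = FALSE)
  meta <- read_metadata_tsv(metadata)
  idx <- match(ids, meta$accession)
  sp <- split_species(meta$species[idx])
  records <- tibble::tibble(
    accession = ids,
    genus = blank_na(meta$genus[idx]),
    species_epithet = blank_na(sp$epithet),
    name_qualifiers = blank_na(sp$qualifiers),
    voucher = blank_na(meta$voucher[idx]),
    locality = blank_na(meta$country[idx]),
    sequence = canonicalize_sequence(unname(as.character(seqs)),
                                     "FASTA sequence")
  )
  n_unmatched <- sum(!meta$accession %in% ids)
  if (n_unmatched > 0)
    message(n_unmatched, " metadata row(s) without a FASTA entry ignored")
  attr(records, "n_unmatched_metadata") <- n_unmatched
  records
}

#' Fill empty metadata fields from an enrichment table
#'
#' Emulates joining a second curated source onto repository metadata: for
#' each record, only fields that are empty (`genus`, species name, `voucher`,
#' `locality`) are filled from the enrichment row with the same accession.
#' Populated fields are never overwritten.
#'
#' @param records Specimen-record tibble.
#' @param enrichment Path to a TSV with the same schema as the metadata file.
#' @return A new specimen-record tibble.
#' @export
enrich_metadata <- function(records, enrichment) {
  enr <- read_metadata_tsv(enrichment, context = "enrichment")
  idx <- match(records$accession, enr$accession)
  out <- records
  fill <- function(cur, new) ifelse(nzchar(cur) | is.na(new), cur,
                                    blank_na(new))
  out$genus <- fill(out$genus, enr$genus[idx])
  sp <- split_species(enr$species[idx])
  empty_name <- !nzchar(trimws(paste(out$species_epithet,
                                     out$name_qualifiers)))
  out$species_epithet[empty_name] <- blank_na(sp$epithet[empty_name])
  out$name_qualifiers[empty_name] <- blank_na(sp$qualifiers[empty_name])
  out$voucher <- fill(out$voucher, enr$voucher[idx])
  out$locality <- fill(out$locality, enr$country[idx])
  out
}

#' Write a specimen dataset to FASTA plus metadata TSV
#'
#' Inverse of [read_dataset()]: FASTA wrapped at 80 columns with
#' accession-only headers, and a TSV with columns
#' `accession, genus, species, voucher, country`. Empty fields are written as
#' empty cells, never omitted.
#'
#' @param records Specimen-record tibble.
#' @param fasta,metadata Output paths.
#' @return Invisibly, a named character vector of the two paths.
#' @export
write_dataset <- function(records, fasta, metadata) {
  set <- Biostrings::BStringSet(stats::setNames(as.character(records$sequence),
                                                records$accession))
  Biostrings::writeXStringSet(set, fasta, width = 80L)
  meta <- tibble::tibble(
    accession = records$accession,
    genus = records$genus,
    species = species_name(records),
    voucher = records$voucher,
    country = records$locality
  )
  readr::write_tsv(meta, metadata, progress = FALSE)
  invisible(c(fasta = fasta, metadata = metadata))
}
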