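# ITS1 / 5.8S / ITS2 partition by anchor-motif matching.
#
# A deliberately simple stand-in for profile-HMM rDNA annotators: the
# conserved 5.8S is located by sliding-window Hamming matches of a start and
# an end motif, tolerating a small number of mismatches. Adequate for
# curated complete-ITS inputs, and exactly testable.

#' Anchor motifs for locating the 5.8S core
#'
#' Defaults are the first and last 20 bases of the packaged 5.8S core
#' ([its58_core()]), with one mismatch tolerated.
#'
#' @param s58_start_motif,s58_end_motif Non-empty nucleotide strings marking
#'   the start and end of the 5.8S region.
#' @param max_mismatches Maximum Hamming mismatches tolerated per motif
#'   (>= 0).
#' @return An `anchor_config` list.
#' @export
anchor_config <- function(s58_start_motif = substr(its58_core(), 1, 20),
                          s58_end_motif = substr(its58_core(),
                                                 nchar(its58_core()) - 19,
                                                 nchar(its58_core())),
                          max_mismatches = 1) {
  stopifnot(is.character(s58_start_motif), nzchar(s58_start_motif),
            is.character(s58_end_motif), nzchar(s58_end_motif))
  max_mismatches <- check_count(max_mismatches, "max_mismatches", min = 0)
  structure(list(s58_start_motif = toupper(s58_start_motif),
                 s58_end_motif = toupper(s58_end_motif),
                 max_mismatches = max_mismatches),
            class = "anchor_config")
}

# Best motif hit in s within [from, to) (0-based offsets relative to s).
# Returns the 0-based offset, or NA if absent (no hit within max_mismatches)
# or ambiguous (>= 2 equally good non-overlapping hits). Overlapping equal
# hits resolve to the leftmost.
find_motif <- function(s, motif, max_mismatches, from = 0L) {
  sub <- substr(s, from + 1L, nchar(s))
  counts <- hamming_scan_cpp(sub, motif)
  if (length(counts) == 0) return(NA_integer_)
  best <- min(counts)
  if (best > max_mismatches) return(NA_integer_)
  hits <- which(counts == best) - 1L
  if (length(hits) > 1 &&
      (hits[length(hits)] - hits[1]) >= nchar(motif))
    return(NA_integer_)
  from + hits[1]
}

#' Split a complete ITS sequence into ITS1, 5.8S, and ITS2
#'
#' Locates the 5.8S start and end motifs by sliding-window Hamming match
#' with at most `max_mismatches` mismatches (fewest mismatches wins, then
#' leftmost; the end motif is searched after the start motif). ITS1 is the
#' prefix before the start motif, 5.8S runs from the start-motif start
#' through the end-motif end, ITS2 is the suffix. Returns `NULL` (failure as
#' a value, not an error) when either motif is absent or ambiguous (two or
#' more equally good non-overlapping hits) or any region is empty.
#'
#' @param sequence A nucleotide string (canonicalized: uppercase, `U` as
#'   `T`).
#' @param anchors An [anchor_config()].
#' @return A list with `its1`, `s58`, `its2` (strings) and `coords` (named
#'   integer vector of 0-based half-open interval bounds `its1_start`,
#'   `its1_end`, `s58_start`, `s58_end`, `its2_start`, `its2_end`), or
#'   `NULL` on failure.
#' @examples
#' seq <- paste0(strrep("A", 50), its58_core(), strrep("G", 50))
#' split_its(seq)$coords
#' @export
split_its <- function(sequence, anchors = anchor_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  start_at <- find_motif(sequence, anchors$s58_start_motif,
                         anchors$max_mismatches)
  if (is.na(start_at)) return(NULL)
  end_at <- find_motif(sequence, anchors$s58_end_motif,
                       anchors$max_mismatches,
                       from = start_at + nchar(anchors$s58_start_motif))
  if (is.na(end_at)) return(NULL)
  s58_end <- end_at + nchar(anchors$s58_end_motif)
  if (start_at == 0L || s58_end >= n) return(NULL)
  list(
    its1 = substr(sequence, 1L, start_at),
    s58 = substr(sequence, start_at + 1L, s58_end),
    its2 = substr(sequence, s58_end + 1L, n),
    coords = c(its1_start = 0L, its1_end = start_at,
               s58_start = start_at, s58_end = as.integer(s58_end),
               its2_start = as.integer(s58_end), its2_end = as.integer(n))
  )
}

#' Attach extracted regions to a record set
#'
#' Runs [split_its()] on every record and appends `its1`, `s58`, `its2` and
#' the six coordinate columns; failed records get `NA` in all of them.
#'
#' @param records Specimen-record tibble.
#' @param anchors An [anchor_config()].
#' @return `records` with region columns appended.
#' @export
extract_regions <- function(records, anchors = anchor_config()) {
  splits <- lapply(records$sequence, split_its, anchors = anchors)
  ok <- !vapply(splits, is.null, logical(1))
  pick_chr <- function(field) vapply(splits, function(s)
    if (is.null(s)) NA_character_ else s[[field]], character(1))
  pick_int <- function(field) vapply(splits, function(s)
    if (is.null(s)) NA_integer_ else s$coords[[field]], integer(1))
  out <- records
  out$its1 <- pick_chr("its1")
  out$s58 <- pick_chr("s58")
  out$its2 <- pick_chr("its2")
  for (f in c("its1_start", "its1_end", "s58_start", "s58_end",
              "its2_start", "its2_end"))
    out[[f]] <- pick_int(f)
  attr(out, "n_split_failures") <- sum(!ok)
  out
}

#' Write extracted regions as three FASTA files plus a coordinate table
#'
#' @param records Record tibble with regions attached (see
#'   [extract_regions()] / [filter_its_complete()]).
#' @param outdir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, a named character vector of the four paths.
#' @export
write_regions <- function(records, outdir, prefix = "dataset") {
  if (!"its1" %in% names(records))
    stop("records lack extracted regions", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    its1 = file.path(outdir, paste0(prefix, ".ITS1.fasta")),
    s58 = file.path(outdir, paste0(prefix, ".5_8S.fasta")),
    its2 = file.path(outdir, paste0(prefix, ".ITS2.fasta")),
    coords = file.path(outdir, paste0(prefix, ".regions.tsv"))
  )
  for (part in c("its1", "s58", "its2")) {
    set <- Biostrings::BStringSet(
      stats::setNames(as.character(records[[part]]), records$accession))
    Biostrings::writeXStringSet(set, paths[[part]], width = 80L)
  }
  coords <- records[, c("accession", "its1_start", "its1_end", "s58_start",
                        "s58_end", "its2_start", "its2_end")]
  readr::write_tsv(coords, paths[["coords"]], progress = FALSE)
  invisible(paths)
}
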