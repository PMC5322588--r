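# Per-genus uncorrected p-distance matrices.
#
# Default path: every pair aligned independently with a global (end-to-end)
# aligner (match +1, mismatch -1, gap -2 linear; ties resolved diagonal
# first, then up), then the uncorrected p-distance with pairwise deletion of
# gap columns. A prealigned path ingests an externally produced multiple
# alignment instead, for users who prefer to run their own aligner.

MARKERS <- c("ITS", "ITS1", "ITS2")

#' Global pairwise alignment
#'
#' Needleman-Wunsch end-to-end alignment with linear gap penalty. Scoring
#' defaults: match +1, mismatch -1, gap -2. Co-optimal moves resolve
#' deterministically (diagonal preferred, then up, i.e. a gap in `b`).
#'
#' @param a,b Non-empty nucleotide strings over `{A,C,G,T}`.
#' @param match,mismatch,gap Scoring parameters.
#' @return A list with aligned strings `a` and `b` (equal length, `-` gaps)
#'   and the optimal `score`.
#' @examples
#' align_pair("ACGT", "ACT")
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.character(a), length(a) == 1, is.character(b),
            length(b) == 1)
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must contain only A, C, G, T", call. = FALSE)
  nw_align_cpp(a, b, match, mismatch, gap)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching columns among columns where both sequences have
#' a base (pairwise deletion: any column containing a gap in either sequence
#' is excluded). No substitution-model correction is applied.
#'
#' @param aligned_a,aligned_b Equal-length aligned strings (`-` for gaps).
#' @return A real in `[0, 1]`.
#' @examples
#' p_distance("AC-GT", "ACTGT")  # 0: four comparable columns, no mismatch
#' @export
p_distance <- function(aligned_a, aligned_b) {
  stopifnot(is.character(aligned_a), length(aligned_a) == 1,
            is.character(aligned_b), length(aligned_b) == 1)
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences must have equal length", call. = FALSE)
  d <- p_distance_cpp(aligned_a, aligned_b)
  if (is.na(d))
    stop("no comparable columns: distance undefined", call. = FALSE)
  d
}

#' Construct a labelled distance matrix
#'
#' @param values Square numeric matrix of distances in `[0, 1]`.
#' @param accession Character vector of unique sequence ids (row order).
#' @param species Character vector of species labels (same order); at least
#'   two distinct species must be present.
#' @return A `distance_matrix` object: list with `labels` (tibble
#'   `accession`, `species`) and `values` (matrix with accession dimnames).
#' @export
distance_matrix <- function(values, accession, species) {
  values <- as.matrix(values)
  n <- length(accession)
  stopifnot(nrow(values) == n, ncol(values) == n, length(species) == n)
  if (anyDuplicated(accession))
    stop("accessions must be unique", call. = FALSE)
  if (length(unique(species)) < 2)
    stop("a distance matrix requires at least two distinct species",
         call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("distances must lie in [0, 1]", call. = FALSE)
  if (any(abs(values - t(values)) > 1e-12) || any(diag(values) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  dimnames(values) <- list(accession, accession)
  structure(list(labels = tibble::tibble(accession = accession,
                                         species = species),
                 values = values),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", nrow(x$values), " sequences, ",
      length(unique(x$labels$species)), " species\n", sep = "")
  invisible(x)
}

# Marker subsequence of each record.
marker_sequences <- function(records, marker) {
  marker <- match.arg(marker, MARKERS)
  if (marker == "ITS") return(records$sequence)
  col <- tolower(marker)
  if (!col %in% names(records))
    stop("records lack extracted ", marker,
         " regions; run extract_regions() first", call. = FALSE)
  records[[col]]
}

#' Per-genus uncorrected p-distance matrix for one marker
#'
#' In `pairwise` mode (the default) every pair of marker sequences is
#' aligned independently with [align_pair()] and scored with
#' [p_distance()]. In `prealigned` mode a multiple alignment supplied via
#' `alignment` (named character vector of equal-length gapped sequences,
#' names matching the accessions) is used instead; `gap_columns` then
#' chooses between pairwise deletion (per-pair exclusion of gap columns,
#' the default) and complete deletion (columns containing a gap in any
#' sequence dropped once for all pairs).
#'
#' @param records Record tibble from a single genus with at least two
#'   distinct species.
#' @param marker One of `"ITS"`, `"ITS1"`, `"ITS2"`.
#' @param mode `"pairwise"` or `"prealigned"`.
#' @param alignment Named character vector of gapped sequences (prealigned
#'   mode only).
#' @param gap_columns Gap-column policy in prealigned mode.
#' @param match,mismatch,gap Alignment scoring (pairwise mode).
#' @return A [distance_matrix()].
#' @export
genus_distance_matrix <- function(records,
                                  marker = c("ITS", "ITS1", "ITS2"),
                                  mode = c("pairwise", "prealigned"),
                                  alignment = NULL,
                                  gap_columns = c("pairwise", "complete"),
                                  match = 1, mismatch = -1, gap = -2) {
  marker <- match.arg(marker)
  mode <- match.arg(mode)
  gap_columns <- match.arg(gap_columns)
  if (nrow(records) < 2)
    stop("need at least two records", call. = FALSE)
  if (length(unique(records$genus)) != 1)
    stop("records must all belong to one genus", call. = FALSE)
  species <- species_name(records)
  if (length(unique(species)) < 2)
    stop("need at least two distinct species", call. = FALSE)

  if (mode == "pairwise") {
    seqs <- marker_sequences(records, marker)
    if (any(!nzchar(seqs)) || any(grepl("[^ACGT]", seqs)))
      stop("marker sequences must be non-empty and unambiguous (A/C/G/T)",
           call. = FALSE)
    values <- nw_pdist_matrix_cpp(seqs, match, mismatch, gap)
  } else {
    if (is.null(alignment))
      stop("prealigned mode requires `alignment`", call. = FALSE)
    if (!all(records$accession %in% names(alignment)))
      stop("`alignment` is missing some accessions", call. = FALSE)
    aln <- toupper(alignment[records$accession])
    if (length(unique(nchar(aln))) != 1)
      stop("aligned sequences must share one length", call. = FALSE)
    if (gap_columns == "complete") {
      mat <- do.call(rbind, strsplit(aln, ""))
      keep <- colSums(mat == "-") == 0
      if (!any(keep))
        stop("no gap-free columns under complete deletion", call. = FALSE)
      aln <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
    }
    n <- length(aln)
    values <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        values[i, j] <- values[j, i] <- p_distance(aln[i], aln[j])
      }
    }
  }
  distance_matrix(values, records$accession, species)
}

#' Write a distance matrix as TSV (labels in first row and column)
#'
#' @param dm A [distance_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- tibble::as_tibble(dm$values, .name_repair = "minimal")
  names(df) <- dm$labels$accession
  df <- dplyr::bind_cols(tibble::tibble(accession = dm$labels$accession), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
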