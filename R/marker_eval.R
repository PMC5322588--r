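# The two evaluation instruments: probability of correct identification
# (PCI), and boxplot-based barcode-gap classification with Group 1-4
# assignment across the three markers.

GAP_LEVELS <- c("poor", "intermediate", "good")

#' Per-species distance summaries
#'
#' For every species with at least two sequences ("scorable" species):
#' the maximum intraspecific distance (over all within-species pairs) and
#' the minimum interspecific distance (over all pairs to sequences of any
#' other species). Species represented by a single sequence have no
#' intraspecific distance and are excluded from scoring, but their sequences
#' still contribute to the interspecific minima of the other species.
#'
#' @param dm A [distance_matrix()].
#' @return A tibble with columns `species`, `max_intra`, `min_inter`,
#'   `n_intra_pairs`, `n_inter_pairs`.
#' @export
species_summaries <- function(dm) {
  sp <- dm$labels$species
  v <- dm$values
  counts <- table(sp)
  scorable <- names(counts)[counts >= 2]
  if (length(scorable) == 0)
    stop("no species with at least two sequences: PCI undefined",
         call. = FALSE)
  rows <- lapply(scorable, function(s) {
    members <- which(sp == s)
    others <- which(sp != s)
    intra <- v[members, members][upper.tri(diag(length(members)))]
    inter <- v[members, others, drop = FALSE]
    tibble::tibble(
      species = s,
      max_intra = max(intra),
      min_inter = min(inter),
      n_intra_pairs = length(intra),
      n_inter_pairs = length(inter)
    )
  })
  dplyr::bind_rows(rows)
}

#' Is a species successfully identified?
#'
#' Identification succeeds when the minimum interspecific distance involving
#' the species is strictly larger than its maximum intraspecific distance;
#' ties fail.
#'
#' @param summaries A tibble from [species_summaries()] (or any data frame
#'   with `min_inter` and `max_intra`).
#' @return Logical vector, one element per species.
#' @export
species_identified <- function(summaries) {
  summaries$min_inter > summaries$max_intra
}

#' Probability of correct identification for a genus
#'
#' The fraction of scorable species (those with at least two sequences)
#' whose minimum interspecific distance strictly exceeds their maximum
#' intraspecific distance.
#'
#' @param dm A [distance_matrix()].
#' @return A real in `[0, 1]`.
#' @export
genus_pci <- function(dm) {
  mean(species_identified(species_summaries(dm)))
}

#' Pooled intra- and interspecific distances of a genus
#'
#' All within-species pairwise distances pooled across species, and all
#' between-species pairwise distances. These pools feed the boxplot-based
#' barcode-gap classification; note they use every sequence pair, unlike the
#' species-level extrema that define PCI.
#'
#' @param dm A [distance_matrix()].
#' @return A list with numeric vectors `intra` and `inter`.
#' @export
distance_pools <- function(dm) {
  sp <- dm$labels$species
  v <- dm$values
  ut <- upper.tri(v)
  same <- outer(sp, sp, "==")
  list(intra = v[ut & same], inter = v[ut & !same])
}

#' Boxplot statistics
#'
#' Quartiles by linear interpolation (type-7 quantiles, the common default),
#' whiskers at the most extreme data values within 1.5 IQR of the box, and
#' outliers beyond the whiskers.
#'
#' @param values Non-empty numeric vector.
#' @return A `box_stats` list: `q1`, `median`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @examples
#' box_stats(c(1, 2, 3, 4, 5))
#' @export
box_stats <- function(values) {
  if (length(values) == 0 || !is.numeric(values) || anyNA(values))
    stop("`values` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  structure(list(
    q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    outliers = sort(values[values < lo_fence | values > hi_fence]),
    n = length(values)
  ), class = "box_stats")
}

#' Classify the barcode gap of a genus/marker from its box statistics
#'
#' Checked in order of precedence: `poor` if the boxes overlap
#' (`intra$q3 >= inter$q1`) or the intraspecific values sit at or above the
#' interspecific ones (`intra$median >= inter$median`); else `intermediate`
#' if the whiskers overlap (`intra$whisker_high >= inter$whisker_low`); else
#' `good` — overlapping outliers alone do not spoil a `good` call.
#'
#' @param intra,inter [box_stats()] of the pooled intra- and interspecific
#'   distances of one genus and marker.
#' @return An ordered factor with levels `poor < intermediate < good`.
#' @export
classify_gap <- function(intra, inter) {
  stopifnot(inherits(intra, "box_stats"), inherits(inter, "box_stats"))
  cls <- if (intra$q3 >= inter$q1 || intra$median >= inter$median) "poor"
  else if (intra$whisker_high >= inter$whisker_low) "intermediate"
  else "good"
  factor(cls, levels = GAP_LEVELS, ordered = TRUE)
}

#' Assign a genus to a cross-marker group
#'
#' Group 1: all three markers `good`. Group 2: at least one `good` but not
#' all (the `good` markers are the recommended ones). Group 3: no `good`
#' marker, not all `poor`. Group 4: all three `poor`.
#'
#' @param classes Named character vector or list of gap classes, with
#'   exactly the names `ITS`, `ITS1`, `ITS2`.
#' @return A list with integer `group` (1-4) and character `recommended`
#'   (the good markers when `group == 2`, otherwise empty).
#' @export
assign_group <- function(classes) {
  classes <- unlist(lapply(classes, as.character))
  if (!setequal(names(classes), MARKERS) || length(classes) != 3)
    stop("`classes` must be named ITS, ITS1, ITS2", call. = FALSE)
  if (!all(classes %in% GAP_LEVELS))
    stop("classes must be poor/intermediate/good", call. = FALSE)
  classes <- classes[MARKERS]
  n_good <- sum(classes == "good")
  n_poor <- sum(classes == "poor")
  group <- if (n_good == 3) 1L
  else if (n_poor == 3) 4L
  else if (n_good >= 1) 2L
  else 3L
  list(group = group,
       recommended = if (group == 2L) MARKERS[classes == "good"]
       else character(0))
}

#' Evaluate a genus across markers
#'
#' Builds the per-marker distance matrix, computes PCI, the pooled distance
#' boxplot statistics, and the gap class, then assigns the cross-marker
#' group when all three markers are evaluated.
#'
#' @param records Record tibble of a single genus (regions attached when
#'   sub-region markers are requested).
#' @param markers Markers to evaluate.
#' @param ... Passed to [genus_distance_matrix()].
#' @return A tibble with one row per marker (`genus`, `marker`, `pci`,
#'   `gap_class`, `n_seqs`, `n_species`, and list-columns `intra_box`,
#'   `inter_box`, `intra_pool`, `inter_pool`) plus, when all three markers
#'   are present, columns `group` and `recommended`.
#' @export
evaluate_genus <- function(records, markers = MARKERS, ...) {
  rows <- lapply(markers, function(m) {
    dm <- genus_distance_matrix(records, marker = m, ...)
    pools <- distance_pools(dm)
    ib <- box_stats(pools$intra)
    ob <- box_stats(pools$inter)
    tibble::tibble(
      genus = records$genus[1],
      marker = m,
      pci = genus_pci(dm),
      gap_class = classify_gap(ib, ob),
      n_seqs = nrow(dm$values),
      n_species = length(unique(dm$labels$species)),
      intra_box = list(ib), inter_box = list(ob),
      intra_pool = list(pools$intra), inter_pool = list(pools$inter)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (setequal(markers, MARKERS)) {
    grp <- assign_group(stats::setNames(as.character(out$gap_class),
                                        out$marker))
    out$group <- grp$group
    out$recommended <- paste(grp$recommended, collapse = ",")
  }
  out
}

#' Boxplot of pooled intra- vs interspecific distances
#'
#' @param eval_tbl Output of [evaluate_genus()].
#' @return A ggplot object: one panel per marker, intra and inter boxes.
#' @export
plot_gap_boxes <- function(eval_tbl) {
  df <- dplyr::bind_rows(lapply(seq_len(nrow(eval_tbl)), function(k)
    tibble::tibble(
      marker = eval_tbl$marker[k],
      type = rep(c("intraspecific", "interspecific"),
                 c(length(eval_tbl$intra_pool[[k]]),
                   length(eval_tbl$inter_pool[[k]]))),
      distance = c(eval_tbl$intra_pool[[k]], eval_tbl$inter_pool[[k]])
    )))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$distance)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~marker) +
    ggplot2::labs(x = NULL, y = "uncorrected p-distance",
                  title = eval_tbl$genus[1]) +
    ggplot2::theme_minimal()
}
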