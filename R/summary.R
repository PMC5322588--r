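# Cross-genus, cross-marker summary statistics on a genus x marker PCI
# table (percent scale): column means, fraction of genera strictly above
# the mean, pairwise Spearman correlations, and group-wise dot-plot data.

marker_column <- function(table, marker) {
  marker <- match.arg(toupper(marker), MARKERS)
  table[[tolower(marker)]]
}

#' Validate a PCI table
#'
#' @param table Data frame with columns `genus`, `its`, `its1`, `its2`; PCI
#'   values on the 0-100 scale, genus names unique.
#' @return The table as a tibble, invisibly validated.
#' @export
pci_table <- function(table) {
  table <- tibble::as_tibble(table)
  missing <- setdiff(c("genus", "its", "its1", "its2"), names(table))
  if (length(missing) > 0)
    stop("PCI table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(table$genus))
    stop("genus names must be unique", call. = FALSE)
  vals <- unlist(table[, c("its", "its1", "its2")])
  if (anyNA(vals) || any(vals < 0 | vals > 100))
    stop("PCI values must lie in [0, 100]", call. = FALSE)
  table
}

#' Read a PCI table from TSV
#'
#' @param path TSV with columns `genus`, `its`, `its1`, `its2`.
#' @return A validated tibble.
#' @export
read_pci_table <- function(path) {
  pci_table(readr::read_tsv(path, col_types = "ciii", progress = FALSE))
}

#' Read a genus-to-group table from TSV
#'
#' @param path TSV with columns `genus`, `group` (1-4) and optionally
#'   `recommended` (comma-separated markers for Group 2).
#' @return A tibble.
#' @export
read_group_table <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    genus = "c", group = "i", .default = "c"), progress = FALSE)
  if (!all(c("genus", "group") %in% names(g)))
    stop("group table must have columns genus and group", call. = FALSE)
  if (!all(g$group %in% 1:4))
    stop("groups must be 1-4", call. = FALSE)
  if (is.null(g$recommended)) g$recommended <- ""
  g$recommended[is.na(g$recommended)] <- ""
  g
}

#' Mean PCI of a marker column
#'
#' @param table A [pci_table()].
#' @param marker One of `"ITS"`, `"ITS1"`, `"ITS2"`.
#' @return Arithmetic mean on the 0-100 scale.
#' @export
mean_pci <- function(table, marker = c("ITS", "ITS1", "ITS2")) {
  table <- pci_table(table)
  if (nrow(table) == 0) stop("PCI table is empty", call. = FALSE)
  mean(marker_column(table, marker[1]))
}

#' Fraction of genera strictly above the column mean
#'
#' @inheritParams mean_pci
#' @return A real in `[0, 1 - 1/n]` for non-constant columns.
#' @export
fraction_above_mean <- function(table, marker = c("ITS", "ITS1", "ITS2")) {
  table <- pci_table(table)
  if (nrow(table) == 0) stop("PCI table is empty", call. = FALSE)
  v <- marker_column(table, marker[1])
  mean(v > mean(v))
}

#' Spearman rank correlation (tie-corrected)
#'
#' Rank correlation with average ranks for ties, i.e. the Pearson
#' correlation of midranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A real in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("zero rank variance: correlation undefined", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Group-wise dot-plot data
#'
#' Partitions the PCI values by (group, marker), flagging for each value
#' whether it lies strictly above its marker's overall mean.
#'
#' @param table A [pci_table()].
#' @param groups A data frame with columns `genus` and `group` covering
#'   every genus of `table`.
#' @return A long tibble with columns `group`, `marker`, `genus`, `pci`,
#'   `above_mean`.
#' @export
group_dotplot_data <- function(table, groups) {
  table <- pci_table(table)
  idx <- match(table$genus, groups$genus)
  if (anyNA(idx))
    stop("genus without a group assignment: ",
         paste(table$genus[is.na(idx)], collapse = ", "), call. = FALSE)
  long <- tidyr::pivot_longer(table, cols = c("its", "its1", "its2"),
                              names_to = "marker", values_to = "pci")
  long$marker <- toupper(long$marker)
  means <- vapply(MARKERS, function(m) mean_pci(table, m), numeric(1))
  long$above_mean <- unname(long$pci > means[long$marker])
  long$group <- groups$group[match(long$genus, groups$genus)]
  long[order(long$group, long$marker, long$genus),
       c("group", "marker", "genus", "pci", "above_mean")]
}

# Published reference values (printed summary statistics) for the packaged
# genus x marker PCI table and group assignments.
published_reference <- function() {
  tibble::tribble(
    ~quantity, ~published, ~digits, ~tol,
    "n_genera", 113, 0, 0,
    "mean_pci_its", 63, 0, 1,
    "mean_pci_its1", 59, 0, 1,
    "mean_pci_its2", 58, 0, 1,
    "pct_above_mean_its", 53.1, 1, 1,
    "pct_above_mean_its1", 46, 1, 1,
    "pct_above_mean_its2", 48, 1, 1,
    "spearman_its_its1", 0.8825, 4, 0.01,
    "spearman_its_its2", 0.9102, 4, 0.01,
    "spearman_its1_its2", 0.8158, 4, 0.01,
    "n_group4", 11, 0, 0
  )
}

#' Recompute the published cross-marker summaries from the packaged tables
#'
#' Loads the packaged genus x marker PCI table and group table (or
#' user-supplied replacements), recomputes every summary statistic, and
#' compares each against its published value. Because the packaged table
#' holds integer-printed PCI values while the published summaries were
#' computed from unrounded ones, each recomputed value is rounded to the
#' published printing precision before differencing, and a per-quantity
#' tolerance (1 percentage point for means and fractions, 0.01 for Spearman
#' correlations, exact for counts) decides `ok`.
#'
#' @param table1 Optional path to a PCI table TSV (default: packaged).
#' @param table2 Optional path to a group table TSV (default: packaged).
#' @return A tibble with columns `quantity`, `published`, `recomputed`,
#'   `recomputed_rounded`, `delta`, `tol`, `ok`.
#' @export
reproduce_published_summaries <- function(table1 = NULL, table2 = NULL) {
  if (is.null(table1)) table1 <- fixture_path("table1_pci.tsv")
  if (is.null(table2)) table2 <- fixture_path("table2_groups.tsv")
  if (!file.exists(table1) || !file.exists(table2))
    stop("fixture table(s) not found", call. = FALSE)
  t1 <- read_pci_table(table1)
  t2 <- read_group_table(table2)
  recomputed <- c(
    n_genera = nrow(t1),
    mean_pci_its = mean_pci(t1, "ITS"),
    mean_pci_its1 = mean_pci(t1, "ITS1"),
    mean_pci_its2 = mean_pci(t1, "ITS2"),
    pct_above_mean_its = 100 * fraction_above_mean(t1, "ITS"),
    pct_above_mean_its1 = 100 * fraction_above_mean(t1, "ITS1"),
    pct_above_mean_its2 = 100 * fraction_above_mean(t1, "ITS2"),
    spearman_its_its1 = spearman_rho(t1$its, t1$its1),
    spearman_its_its2 = spearman_rho(t1$its, t1$its2),
    spearman_its1_its2 = spearman_rho(t1$its1, t1$its2),
    n_group4 = sum(t2$group == 4)
  )
  report <- published_reference()
  report$recomputed <- unname(recomputed[report$quantity])
  report$recomputed_rounded <- round(report$recomputed, report$digits)
  report$delta <- report$published - report$recomputed_rounded
  report$ok <- abs(report$delta) <= report$tol
  report$digits <- NULL
  report
}
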