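# Packaged reference tables: the printed genus x marker PCI values (113
# genera, percent scale) and the genus-to-group assignments from the
# barcode-gap analysis, both shipped as plain TSV under extdata.

fixture_path <- function(name) {
  system.file("extdata", name, package = "barcodegap", mustWork = FALSE)
}

#' Copy the packaged reference tables to a directory
#'
#' Writes `table1_pci.tsv` (genus, ITS, ITS1, ITS2 integer PCI values) and
#' `table2_groups.tsv` (genus, group 1-4, recommended markers for Group 2)
#' into `outdir`.
#'
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the two paths.
#' @export
write_fixture_tables <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  paths <- c(table1 = file.path(outdir, "table1_pci.tsv"),
             table2 = file.path(outdir, "table2_groups.tsv"))
  ok1 <- file.copy(fixture_path("table1_pci.tsv"), paths[["table1"]],
                   overwrite = TRUE)
  ok2 <- file.copy(fixture_path("table2_groups.tsv"), paths[["table2"]],
                   overwrite = TRUE)
  if (!ok1 || !ok2)
    stop("failed to write fixture tables to ", outdir, call. = FALSE)
  paths
}
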