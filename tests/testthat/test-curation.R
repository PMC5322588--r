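test_that("voucher filter keeps only non-empty vouchers", {
  rec <- make_records(2, voucher = c("K(M)123", ""))
  expect_equal(filter_voucher(rec)$accession, "ACC001")
  all_present <- make_records(3)
  expect_identical(filter_voucher(all_present), all_present)
})

test_that("a single ambiguity code anywhere removes the record", {
  rec <- make_records(3, sequence = c("ACGTN", "ACGTACGT", "ACGTACGR"))
  expect_equal(filter_ambiguous(rec)$accession, "ACC002")
})

test_that("inconclusive name tokens are removed, but only as whole tokens", {
  rec <- make_records(
    6,
    species_epithet = c("sp.", "bisporus", "cf.", "crassifolia",
                        "uncultured", "edulis"),
    name_qualifiers = c("", "", "edulis", "", "", "aff. boletus"))
  kept <- filter_species_names(rec)
  expect_equal(kept$accession, c("ACC002", "ACC004"))
})

test_that("ITS-completeness keeps splittable records and attaches regions", {
  set.seed(5)
  good <- make_its_sequence(150, 150)
  no_anchor <- gsub(substr(its58_core(), 1, 20), "", good, fixed = TRUE)
  empty_its1 <- paste0(its58_core(), random_sequence(150))
  rec <- make_records(3, sequence = c(good, no_anchor, empty_its1))
  kept <- filter_its_complete(rec)
  expect_equal(kept$accession, "ACC001")
  expect_equal(kept$its1, substr(good, 1, 150))
  expect_equal(kept$its2, substr(good, 151 + 158, nchar(good)))
})

test_that("length filter applies inclusive [400, 800] and 100 bp sub-region floors", {
  set.seed(6)
  lens <- list(c(121, 121),   # total 400: kept
               c(120, 121),   # total 399: removed
               c(321, 321),   # total 800: kept
               c(322, 321),   # total 801: removed
               c(99, 193))    # total 450 but ITS1 = 99: removed
  seqs <- vapply(lens, function(l) make_its_sequence(l[1], l[2]),
                 character(1))
  rec <- filter_its_complete(make_records(5, sequence = seqs))
  expect_equal(nrow(rec), 5)  # all splittable
  kept <- filter_lengths(rec)
  expect_equal(kept$accession, c("ACC001", "ACC003"))
  expect_error(filter_lengths(make_records(1)), "regions")
})

test_that("locality filter needs three distinct localities per species", {
  rec <- make_records(6,
                      species_epithet = c("alba", "alba", "alba",
                                          "nigra", "nigra", "nigra"),
                      locality = c("Brazil", "Brazil", "Chile",
                                   "Brazil", "Chile", "Peru"))
  kept <- filter_localities(rec)
  expect_equal(sort(kept$accession), c("ACC004", "ACC005", "ACC006"))
  expect_error(filter_localities(rec, min_localities = 0), "integer")
})

test_that("unlocated records drop out but do not sink their species", {
  rec <- make_records(5, locality = c("", "", "A", "B", "C"))
  kept <- filter_localities(rec)
  expect_equal(sort(kept$accession), c("ACC003", "ACC004", "ACC005"))
})

test_that("genera need at least two distinct surviving species", {
  rec <- dplyr::bind_rows(
    make_records(5, genus = "Solo", species_epithet = "una"),
    make_records(4, accession = sprintf("B%03d", 1:4), genus = "Duo",
                 species_epithet = rep(c("una", "dua"), 2)))
  kept <- filter_min_species_per_genus(rec)
  expect_setequal(unique(kept$genus), "Duo")
  n_sp <- tapply(species_name(kept), kept$genus,
                 function(x) length(unique(x)))
  expect_true(all(n_sp >= 2))
})

test_that("each filter is idempotent on a defect-laden dataset", {
  configs <- lapply(c("Ga", "Gb", "Gc"), function(g)
    genus_sim_config(g, n_species = 3, seqs_per_species = 4,
                     n_localities_pool = 4, seed = 17))
  rec <- generate_dataset(configs,
                          defect_config(p_ambiguous = 0.3, p_no_voucher = 0.3,
                                        p_bad_name = 0.3, p_bad_length = 0.3,
                                        p_no_locality = 0.3, seed = 8))
  filters <- list(filter_voucher, filter_ambiguous, filter_species_names,
                  function(r) filter_localities(r),
                  function(r) filter_min_species_per_genus(r))
  for (f in filters) {
    once <- f(rec)
    expect_identical(f(once), once)
  }
  extracted <- filter_its_complete(rec)
  expect_identical(filter_its_complete(extracted), extracted)
  expect_identical(filter_lengths(filter_lengths(extracted)),
                   filter_lengths(extracted))
})

test_that("per-record filters commute with one another", {
  rec <- generate_dataset(
    list(genus_sim_config("Gx", n_species = 3, seqs_per_species = 4,
                          seed = 19)),
    defect_config(p_ambiguous = 0.4, p_no_voucher = 0.4, p_bad_name = 0.4,
                  seed = 2))
  fs <- list(filter_voucher, filter_ambiguous, filter_species_names)
  for (i in 1:2) for (j in (i + 1):3)
    expect_identical(fs[[i]](fs[[j]](rec)), fs[[j]](fs[[i]](rec)))
})

test_that("adding records can rescue a species at the locality stage", {
  base <- make_records(2, locality = c("Brazil", "Chile"))
  expect_equal(nrow(filter_localities(base)), 0)
  more <- dplyr::bind_rows(base, make_records(1, accession = "ACC999",
                                              locality = "Peru"))
  expect_equal(nrow(filter_localities(more)), 3)
})

test_that("the cascade is the identity on clean data and reports consistently", {
  rec <- generate_dataset(lapply(c("Ga", "Gb"), function(g)
    genus_sim_config(g, n_species = 3, seqs_per_species = 3, seed = 23)))
  out <- run_curation(rec)
  expect_equal(out$report$n_in, rep(nrow(rec), 7))
  expect_equal(out$report$n_out, rep(nrow(rec), 7))
  expect_equal(nrow(out$records), nrow(rec))
  # stage chaining on a lossy run
  lossy <- run_curation(inject_defects(rec, defect_config(
    p_ambiguous = 0.5, p_no_voucher = 0.5, seed = 3)))
  expect_equal(lossy$report$n_in[-1],
               lossy$report$n_out[-nrow(lossy$report)])
  expect_equal(lengths(lossy$report$removed),
               lossy$report$n_in - lossy$report$n_out)
})

test_that("an absorbing defect stage leaves nothing for later stages", {
  rec <- generate_dataset(list(genus_sim_config("Gz", seed = 29)),
                          defect_config(p_no_voucher = 1, seed = 1))
  out <- run_curation(rec)
  expect_equal(out$report$n_out[1], 0)
  expect_true(all(out$report$n_in[-1] == 0))
})

test_that("curation reports serialize to JSON", {
  rec <- generate_dataset(list(genus_sim_config("Gj", seed = 31)),
                          defect_config(p_no_voucher = 0.5, seed = 6))
  out <- run_curation(rec)
  path <- file.path(tempdir(), "report.json")
  write_curation_report(out$report, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 7)
  expect_equal(parsed[[1]]$stage, "voucher")
  expect_equal(parsed[[1]]$n_in, nrow(rec))
})
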