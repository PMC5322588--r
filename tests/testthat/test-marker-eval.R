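test_that("species summaries report per-species extrema", {
  v <- matrix(0.2, 4, 4)
  v[1, 2] <- v[2, 1] <- 0
  v[3, 4] <- v[4, 3] <- 0
  diag(v) <- 0
  dm <- distance_matrix(v, paste0("A", 1:4), c("x", "x", "y", "y"))
  s <- species_summaries(dm)
  expect_equal(s$max_intra, c(0, 0))
  expect_equal(s$min_inter, c(0.2, 0.2))
  expect_equal(s$n_intra_pairs, c(1, 1))
  expect_equal(s$n_inter_pairs, c(4, 4))
})

test_that("singleton species are unscored but still donate interspecific distances", {
  # species z has one member whose distance to x is the smallest
  v <- matrix(0, 5, 5)
  v[1, 2] <- 0.01; v[3, 4] <- 0.02                 # intra x, intra y
  v[1, 3] <- 0.30; v[1, 4] <- 0.30; v[2, 3] <- 0.30; v[2, 4] <- 0.30
  v[1, 5] <- 0.05; v[2, 5] <- 0.40; v[3, 5] <- 0.40; v[4, 5] <- 0.40
  v <- v + t(v)
  dm <- distance_matrix(v, paste0("A", 1:5), c("x", "x", "y", "y", "z"))
  s <- species_summaries(dm)
  expect_setequal(s$species, c("x", "y"))
  expect_equal(s$min_inter[s$species == "x"], 0.05)  # via the singleton
  expect_equal(oracle_species_summaries(dm)$min_inter[1], 0.05)
})

test_that("identification requires a strictly larger interspecific minimum", {
  s <- tibble::tibble(max_intra = c(0.02, 0.05, 0.05),
                      min_inter = c(0.05, 0.05, 0.02))
  expect_equal(species_identified(s), c(TRUE, FALSE, FALSE))
})

test_that("PCI spans its documented extremes", {
  clean <- matrix(0.2, 4, 4); diag(clean) <- 0
  clean[1, 2] <- clean[2, 1] <- 0.01
  clean[3, 4] <- clean[4, 3] <- 0.01
  dm <- distance_matrix(clean, paste0("A", 1:4), c("x", "x", "y", "y"))
  expect_equal(genus_pci(dm), 1)

  half <- clean
  half[3, 4] <- half[4, 3] <- 0.5   # species y fails (intra > inter)
  dm2 <- distance_matrix(half, paste0("A", 1:4), c("x", "x", "y", "y"))
  expect_equal(genus_pci(dm2), 0.5)

  none <- matrix(0.01, 4, 4); diag(none) <- 0
  none[1, 2] <- none[2, 1] <- 0.5
  none[3, 4] <- none[4, 3] <- 0.5
  dm3 <- distance_matrix(none, paste0("A", 1:4), c("x", "x", "y", "y"))
  expect_equal(genus_pci(dm3), 0)
})

test_that("PCI and summaries match the brute-force oracle on random matrices", {
  set.seed(51)
  for (i in 1:25) {
    dm <- random_distance_matrix()
    expect_equal(genus_pci(dm), oracle_pci(dm))
    s <- species_summaries(dm)
    o <- oracle_species_summaries(dm)
    expect_equal(as.data.frame(s), o, ignore_attr = TRUE)
  }
})

test_that("box statistics follow type-7 quartiles and 1.5 IQR whiskers", {
  b <- box_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$q1, 2); expect_equal(b$median, 3); expect_equal(b$q3, 4)
  expect_equal(b$whisker_low, 1); expect_equal(b$whisker_high, 5)
  expect_length(b$outliers, 0)

  const <- box_stats(rep(0.3, 6))
  expect_equal(const$q1, 0.3); expect_equal(const$whisker_high, 0.3)
  expect_length(const$outliers, 0)

  out <- box_stats(c(0, 0, 0, 0, 10))
  expect_equal(out$q3, 0)
  expect_equal(out$whisker_high, 0)
  expect_equal(out$outliers, 10)

  expect_error(box_stats(numeric(0)), "non-empty")
})

test_that("gap classification obeys the declared precedence", {
  good <- classify_gap(box_stats(c(0.01, 0.02, 0.02, 0.03)),
                       box_stats(c(0.20, 0.22, 0.25, 0.30)))
  expect_equal(as.character(good), "good")

  inter <- classify_gap(box_stats(c(0.02, 0.04, 0.06, 0.08)),
                        box_stats(c(0.07, 0.12, 0.14, 0.18)))
  expect_equal(as.character(inter), "intermediate")

  poor <- classify_gap(box_stats(c(0.05, 0.10, 0.15, 0.20)),
                       box_stats(c(0.10, 0.18, 0.22, 0.30)))
  expect_equal(as.character(poor), "poor")

  inverted <- classify_gap(box_stats(c(0.5, 0.6, 0.7)),
                           box_stats(c(0.10, 0.12, 0.15)))
  expect_equal(as.character(inverted), "poor")

  # overlapping outliers alone do not spoil a good call
  outlier_overlap <- classify_gap(box_stats(c(0.01, 0.02, 0.02, 0.03, 0.25)),
                                  box_stats(c(0.20, 0.22, 0.25, 0.30)))
  expect_equal(as.character(outlier_overlap), "good")
})

test_that("group assignment is total over all 27 class combinations", {
  lv <- c("poor", "intermediate", "good")
  combos <- expand.grid(ITS = lv, ITS1 = lv, ITS2 = lv,
                        stringsAsFactors = FALSE)
  groups <- integer(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    cls <- c(ITS = combos$ITS[k], ITS1 = combos$ITS1[k],
             ITS2 = combos$ITS2[k])
    res <- assign_group(cls)
    groups[k] <- res$group
    n_good <- sum(cls == "good")
    expected <- if (n_good == 3) 1L
    else if (all(cls == "poor")) 4L
    else if (n_good >= 1) 2L
    else 3L
    expect_equal(res$group, expected)
    if (res$group == 2) expect_setequal(res$recommended,
                                        names(cls)[cls == "good"])
    else expect_length(res$recommended, 0)
  }
  expect_true(all(groups %in% 1:4))
  expect_equal(sum(groups == 1), 1)
  expect_equal(sum(groups == 4), 1)
  expect_equal(sum(groups == 2), 18)  # >= 1 good but not all three
  expect_equal(sum(groups == 3), 7)   # no good, not all poor
  expect_error(assign_group(c(ITS = "good", ITS1 = "good")), "named")
})

test_that("scaling all distances leaves PCI and gap class unchanged", {
  set.seed(52)
  for (i in 1:10) {
    dm <- random_distance_matrix(scale = 0.5)
    pools <- distance_pools(dm)
    base_cls <- classify_gap(box_stats(pools$intra), box_stats(pools$inter))
    base_pci <- genus_pci(dm)
    for (lambda in c(0.2, 0.9)) {
      dm2 <- distance_matrix(dm$values * lambda, dm$labels$accession,
                             dm$labels$species)
      pools2 <- distance_pools(dm2)
      expect_equal(genus_pci(dm2), base_pci)
      expect_equal(classify_gap(box_stats(pools2$intra),
                                box_stats(pools2$inter)), base_cls)
    }
  }
})

test_that("inflating interspecific distances never degrades PCI or class", {
  set.seed(53)
  for (i in 1:10) {
    dm <- random_distance_matrix(scale = 0.3)
    sp <- dm$labels$species
    pools <- distance_pools(dm)
    base_cls <- classify_gap(box_stats(pools$intra), box_stats(pools$inter))
    base_pci <- genus_pci(dm)
    for (lambda in c(1.5, 3)) {
      v <- dm$values
      diffsp <- outer(sp, sp, "!=")
      v[diffsp] <- pmin(v[diffsp] * lambda, 1)
      dm2 <- distance_matrix(v, dm$labels$accession, sp)
      pools2 <- distance_pools(dm2)
      expect_gte(genus_pci(dm2), base_pci)
      expect_gte(as.integer(classify_gap(box_stats(pools2$intra),
                                         box_stats(pools2$inter))),
                 as.integer(base_cls))
    }
  }
})

test_that("evaluate_genus assembles per-marker results and the group", {
  rec <- filter_its_complete(generate_genus(
    genus_sim_config("Gm", n_species = 3, seqs_per_species = 3,
                     intra_div = 0.01, inter_div = 0.2, seed = 61)))
  ev <- evaluate_genus(rec)
  expect_equal(ev$marker, c("ITS", "ITS1", "ITS2"))
  expect_true(all(ev$pci == 1))
  expect_true(all(ev$gap_class == "good"))
  expect_equal(unique(ev$group), 1L)
  expect_s3_class(plot_gap_boxes(ev), "ggplot")
})
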