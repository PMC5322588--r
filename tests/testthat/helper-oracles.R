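# Independent oracles and small fixture builders used across the suite.

# Best global-alignment score by exhaustive recursion (tiny inputs only).
oracle_best_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (substr(a, i, i) == substr(b, j, j)) match
                  else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Score of a given alignment column by column.
score_alignment <- function(aa, bb, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(aa, "")[[1]]
  cb <- strsplit(bb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ifelse(ca == "-" | cb == "-", gap, ifelse(ca == cb, match, mismatch)))
}

# Literal nested-loop recomputation of per-species distance extrema.
oracle_species_summaries <- function(dm) {
  sp <- dm$labels$species
  v <- dm$values
  n <- length(sp)
  out <- list()
  for (s in unique(sp)) {
    members <- which(sp == s)
    if (length(members) < 2) next
    max_intra <- -Inf
    n_intra <- 0L
    for (i in members) for (j in members) if (i < j) {
      max_intra <- max(max_intra, v[i, j]); n_intra <- n_intra + 1L
    }
    min_inter <- Inf
    n_inter <- 0L
    for (i in members) for (j in seq_len(n)) if (sp[j] != s) {
      min_inter <- min(min_inter, v[i, j]); n_inter <- n_inter + 1L
    }
    out[[s]] <- data.frame(species = s, max_intra = max_intra,
                           min_inter = min_inter, n_intra_pairs = n_intra,
                           n_inter_pairs = n_inter)
  }
  do.call(rbind, out)
}

oracle_pci <- function(dm) {
  s <- oracle_species_summaries(dm)
  mean(s$min_inter > s$max_intra)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random single-genus record set: 2-4 species, <= 12 sequences, unrelated
# random marker sequences of varying length.
random_genus_records <- function(max_seqs = 12) {
  n_species <- sample(2:4, 1)
  sizes <- pmax(1, stats::rmultinom(1, sample(n_species:max_seqs, 1),
                                    rep(1, n_species))[, 1])
  rows <- list()
  k <- 0
  for (s in seq_len(n_species)) {
    for (i in seq_len(sizes[s])) {
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        accession = sprintf("ACC%03d", k),
        genus = "Genusia",
        species_epithet = paste0("species", s),
        name_qualifiers = "",
        voucher = "V1", locality = "Brazil",
        sequence = random_sequence(sample(30:60, 1))
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Random labelled distance matrix with given species sizes; at least one
# species always has two members so PCI is defined.
random_distance_matrix <- function(max_seqs = 12, scale = 1) {
  n_species <- sample(2:4, 1)
  sizes <- pmax(1, stats::rmultinom(1, sample(n_species:max_seqs, 1),
                                    rep(1, n_species))[, 1])
  if (max(sizes) < 2) sizes[1] <- 2L
  n <- sum(sizes)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- stats::runif(n * (n - 1) / 2) * scale
  v <- v + t(v)
  distance_matrix(v, sprintf("ACC%03d", seq_len(n)),
                  rep(paste0("sp", seq_along(sizes)), sizes))
}

# Minimal record tibble for curation tests.
make_records <- function(n = 1, accession = sprintf("ACC%03d", seq_len(n)),
                         genus = "Genusia", species_epithet = "alba",
                         name_qualifiers = "", voucher = "V1",
                         locality = "Brazil", sequence = "ACGTACGT") {
  tibble::tibble(accession = accession, genus = genus,
                 species_epithet = species_epithet,
                 name_qualifiers = name_qualifiers, voucher = voucher,
                 locality = locality, sequence = sequence)
}

# A well-formed complete-ITS sequence around the packaged 5.8S core.
make_its_sequence <- function(its1_len = 150, its2_len = 150, s58 = NULL) {
  if (is.null(s58)) s58 <- its58_core()
  paste0(random_sequence(its1_len), s58, random_sequence(its2_len))
}
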