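# Synthetic ITS datasets with known ground truth.
#
# The generator emulates the structure a genus-level barcode-gap analysis
# cares about -- controllable intraspecific vs interspecific divergence, a
# conserved 5.8S core between two variable spacers, multi-locality sampling --
# plus the defect channels that the curation cascade filters out. It makes no
# attempt at phylogenetic realism (no rate heterogeneity, no indels, no
# coalescent); the i.i.d. per-site substitution model keeps the expected
# p-distances analytic.

# Fixed synthetic 158-bp "canonical-like" 5.8S core. This is NOT a database
# sequence; it is a package constant so that anchor-based region extraction
# is exact on clean simulated data.
S58_CORE <- paste0(
  "AACTTTCAGCAACGGATCTCTTGGCTCTCGCATCGATGAAGAACGCAGCG",
  "AAATGCGATAAGTAATGTGAATTGCAGAATTCAGTGAATCATCGAATCTT",
  "TGAACGCACATTGCGCCCCTTGGTATTCCGAGGGGCATGCCTGTTCGAGC",
  "GTCATTTA"
)

# Country pool for locality assignment (country-level granularity).
COUNTRY_POOL <- c(
  "Brazil", "Chile", "Peru", "Argentina", "Mexico", "Canada", "Sweden",
  "Norway", "Finland", "Estonia", "Germany", "France", "Spain", "Italy",
  "Portugal", "Austria", "Czechia", "Poland", "Slovakia", "Hungary",
  "Japan", "China", "India", "Thailand", "Malaysia", "Indonesia",
  "Australia", "New Zealand", "South Africa", "Kenya", "Tanzania",
  "Morocco", "Turkey", "Iran", "Russia", "Ukraine", "Colombia",
  "Ecuador", "Panama", "Costa Rica"
)

#' The packaged synthetic 5.8S core sequence
#'
#' A fixed 158-bp synthetic nucleotide constant used as the conserved core
#' between the simulated ITS1 and ITS2 spacers. Its first and last 20 bases
#' are the default anchor motifs for [split_its()].
#'
#' @return A single 158-character string over `{A,C,G,T}`.
#' @examples
#' nchar(its58_core())
#' @export
its58_core <- function() S58_CORE

#' Configuration for one simulated genus
#'
#' Divergence is parameterized as expected tip divergence: `intra_div` is the
#' per-site substitution probability between an individual and its species
#' consensus, and `inter_div` the per-site substitution probability between a
#' species tip and the shared genus ancestor. Internally the species branch
#' is mutated at `max(inter_div - intra_div, 0)` and each individual at
#' `intra_div`, so that expected tip-to-tip intraspecific divergence is about
#' `2 * intra_div` and interspecific about `2 * inter_div`. Setting
#' `inter_div = intra_div` therefore draws intra- and interspecific distances
#' from the same process (no barcode gap), while `inter_div >> intra_div`
#' produces a clear gap.
#'
#' @param genus_name Genus name (unique within a dataset).
#' @param n_species Number of species (>= 1).
#' @param seqs_per_species Sequences per species (>= 3, so the three-locality
#'   rule can hold on clean data).
#' @param its1_len,its2_len Spacer lengths in bp.
#' @param s58_len 5.8S core length in bp (>= 41; default 158, the packaged
#'   core). Other lengths keep the 20-bp anchors and recycle the core middle.
#' @param inter_div,intra_div Substitution probabilities per site in `[0, 1]`
#'   (see Details above).
#' @param s58_div Per-site substitution probability applied to the 5.8S core
#'   on individual branches; default 0 keeps extraction anchors exact.
#' @param n_localities_pool Number of distinct localities to round-robin
#'   species members across (>= 3).
#' @param seed Integer seed; identical (config, seed) pairs give
#'   byte-identical output.
#' @return A `genus_sim_config` list.
#' @examples
#' cfg <- genus_sim_config("Agaricus", n_species = 2, seqs_per_species = 3,
#'                         intra_div = 0, inter_div = 0.2, seed = 1)
#' @export
genus_sim_config <- function(genus_name,
                             n_species = 5,
                             seqs_per_species = 4,
                             its1_len = 250,
                             s58_len = 158,
                             its2_len = 250,
                             inter_div = 0.1,
                             intra_div = 0.01,
                             s58_div = 0,
                             n_localities_pool = 6,
                             seed = 1) {
  stopifnot(is.character(genus_name), length(genus_name) == 1,
            nzchar(genus_name))
  cfg <- list(
    genus_name = genus_name,
    n_species = check_count(n_species, "n_species"),
    seqs_per_species = check_count(seqs_per_species, "seqs_per_species",
                                   min = 3),
    its1_len = check_count(its1_len, "its1_len"),
    s58_len = check_count(s58_len, "s58_len", min = 41),
    its2_len = check_count(its2_len, "its2_len"),
    inter_div = check_probability(inter_div, "inter_div"),
    intra_div = check_probability(intra_div, "intra_div"),
    s58_div = check_probability(s58_div, "s58_div"),
    n_localities_pool = check_count(n_localities_pool, "n_localities_pool",
                                    min = 3),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$n_localities_pool > length(COUNTRY_POOL))
    stop("`n_localities_pool` must be <= ", length(COUNTRY_POOL),
         call. = FALSE)
  class(cfg) <- "genus_sim_config"
  cfg
}

#' Defect-channel configuration
#'
#' One independent Bernoulli channel per curation filter. Each record is
#' corrupted independently with the channel's probability; channels draw from
#' separate seeded substreams, so changing one probability does not perturb
#' the draws of another channel.
#'
#' @param p_ambiguous Probability of replacing one base with an IUPAC
#'   ambiguity code.
#' @param p_no_voucher Probability of blanking the voucher field.
#' @param p_bad_name Probability of corrupting the species name with one of
#'   `sp.`, `aff.`, `cf.`, `uncultured`.
#' @param p_bad_length Probability of truncating the sequence below 400 bp or
#'   padding it above 800 bp (each mode with probability 1/2).
#' @param p_no_locality Probability of blanking the locality field.
#' @param seed Integer seed for the channel substreams.
#' @return A `defect_config` list.
#' @export
defect_config <- function(p_ambiguous = 0, p_no_voucher = 0, p_bad_name = 0,
                          p_bad_length = 0, p_no_locality = 0, seed = 1) {
  cfg <- list(
    p_ambiguous = check_probability(p_ambiguous, "p_ambiguous"),
    p_no_voucher = check_probability(p_no_voucher, "p_no_voucher"),
    p_bad_name = check_probability(p_bad_name, "p_bad_name"),
    p_bad_length = check_probability(p_bad_length, "p_bad_length"),
    p_no_locality = check_probability(p_no_locality, "p_no_locality"),
    seed = check_count(seed, "seed", min = 0)
  )
  class(cfg) <- "defect_config"
  cfg
}

# Mutate a character vector of bases: each site substituted with probability
# `rate` to a uniformly random *different* base. Consumes the current RNG
# stream.
mutate_bases <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  k <- sum(hit)
  if (k == 0) return(chars)
  off <- sample.int(3L, k, replace = TRUE)
  idx <- match(chars[hit], DNA_BASES)
  chars[hit] <- DNA_BASES[((idx - 1L + off) %% 4L) + 1L]
  chars
}

# Deterministic Latin-flavoured epithet for species index i.
make_epithet <- function(i) {
  stems <- c("alb", "brun", "cin", "dulc", "erub", "fulv", "gris", "hirt",
             "lute", "mont", "nigr", "ochr", "pall", "rubr", "sulph", "tenu",
             "umbr", "virid", "xanth", "zonat")
  sufs <- c("ida", "osa", "ella", "ata", "ensis", "icola", "oides", "ula")
  stem <- stems[((i - 1L) %% length(stems)) + 1L]
  suf <- sufs[(((i - 1L) %/% length(stems)) %% length(sufs)) + 1L]
  extra <- (i - 1L) %/% (length(stems) * length(sufs))
  paste0(stem, suf, if (extra > 0) extra else "")
}

# Build the 5.8S core at the requested length, keeping the 20-bp anchors.
build_s58 <- function(s58_len) {
  if (s58_len == nchar(S58_CORE)) return(S58_CORE)
  mid_src <- substr(S58_CORE, 21, nchar(S58_CORE) - 20)
  mid_len <- s58_len - 40L
  mid_chars <- rep(strsplit(mid_src, "")[[1]], length.out = mid_len)
  paste0(substr(S58_CORE, 1, 20), paste(mid_chars, collapse = ""),
         substr(S58_CORE, nchar(S58_CORE) - 19, nchar(S58_CORE)))
}

#' Generate one synthetic genus
#'
#' Builds `n_species * seqs_per_species` specimen records. A random genus
#' ancestor is drawn for ITS1 and ITS2; each species consensus mutates the
#' ancestor at rate `max(inter_div - intra_div, 0)` per site, and each
#' individual mutates its species consensus at `intra_div`. The 5.8S core is
#' the packaged constant, mutated at `s58_div` on individual branches (0 by
#' default). Localities are assigned round-robin over the pool so every
#' species spans at least three localities on clean data. All randomness is
#' governed by `config$seed`; the caller's RNG state is untouched.
#'
#' @param config A [genus_sim_config()].
#' @return A tibble of specimen records with columns `accession`, `genus`,
#'   `species_epithet`, `name_qualifiers`, `voucher`, `locality`, `sequence`.
#' @examples
#' rec <- generate_genus(genus_sim_config("Agaricus", seed = 1))
#' nrow(rec)
#' @export
generate_genus <- function(config) {
  if (!inherits(config, "genus_sim_config"))
    stop("`config` must be a genus_sim_config", call. = FALSE)
  with_preserved_seed(derive_seed(config$seed,
                                  paste0("genus:", config$genus_name)), {
    s58 <- strsplit(build_s58(config$s58_len), "")[[1]]
    anc1 <- sample(DNA_BASES, config$its1_len, replace = TRUE)
    anc2 <- sample(DNA_BASES, config$its2_len, replace = TRUE)
    branch <- max(config$inter_div - config$intra_div, 0)
    pool <- COUNTRY_POOL[seq_len(config$n_localities_pool)]
    rows <- vector("list", config$n_species * config$seqs_per_species)
    counter <- 0L
    acc_stub <- gsub("[^A-Za-z0-9]", "", config$genus_name)
    for (s in seq_len(config$n_species)) {
      sp1 <- mutate_bases(anc1, branch)
      sp2 <- mutate_bases(anc2, branch)
      epithet <- make_epithet(s)
      for (j in seq_len(config$seqs_per_species)) {
        counter <- counter + 1L
        seq_chars <- c(mutate_bases(sp1, config$intra_div),
                       mutate_bases(s58, config$s58_div),
                       mutate_bases(sp2, config$intra_div))
        rows[[counter]] <- tibble::tibble(
          accession = sprintf("%s_%03d", acc_stub, counter),
          genus = config$genus_name,
          species_epithet = epithet,
          name_qualifiers = "",
          voucher = sprintf("FH:%s:%04d", toupper(substr(acc_stub, 1, 3)),
                            counter),
          locality = pool[((j - 1L) %% length(pool)) + 1L],
          sequence = paste(seq_chars, collapse = "")
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a multi-genus dataset
#'
#' @param configs List of [genus_sim_config()] objects (genus names must be
#'   unique).
#' @param defects Optional [defect_config()] applied to the pooled records.
#' @return A specimen-record tibble.
#' @export
generate_dataset <- function(configs, defects = NULL) {
  nm <- vapply(configs, function(x) x$genus_name, character(1))
  if (anyDuplicated(nm))
    stop("genus names must be unique within a dataset", call. = FALSE)
  records <- purrr::map_dfr(configs, generate_genus)
  if (!is.null(defects)) records <- inject_defects(records, defects)
  records
}

#' Inject repository-style defects into specimen records
#'
#' Each channel corrupts each record independently with its probability,
#' drawing from a dedicated seeded substream (`derive_seed(seed, channel)`).
#' The length channel is applied before the ambiguity channel so an injected
#' ambiguity code is never truncated away. The input is not modified; the
#' returned tibble carries logical ground-truth tag columns
#' (`defect_ambiguous`, `defect_no_voucher`, `defect_bad_name`,
#' `defect_bad_length`, `defect_no_locality`) plus `bad_length_mode`
#' (`"truncate"`, `"pad"`, or `NA`), so tests can replay the curation cascade
#' against known truth.
#'
#' @param records Specimen-record tibble.
#' @param defects A [defect_config()].
#' @return A corrupted copy of `records` with tag columns appended.
#' @export
inject_defects <- function(records, defects) {
  if (!inherits(defects, "defect_config"))
    stop("`defects` must be a defect_config", call. = FALSE)
  if (nrow(records) == 0)
    stop("`records` must be non-empty", call. = FALSE)
  n <- nrow(records)
  out <- records

  draw <- function(channel, p) {
    with_preserved_seed(derive_seed(defects$seed, channel),
                        stats::runif(n) < p)
  }

  # length first (see above), then ambiguity, then metadata channels
  len_hit <- draw("bad_length", defects$p_bad_length)
  mode <- rep(NA_character_, n)
  if (any(len_hit)) {
    with_preserved_seed(derive_seed(defects$seed, "bad_length:detail"), {
      for (i in which(len_hit)) {
        L <- nchar(out$sequence[i])
        if (stats::runif(1) < 0.5) {
          mode[i] <- "truncate"
          newlen <- sample(100:399, 1)
          out$sequence[i] <- substr(out$sequence[i], 1, min(newlen, L))
        } else {
          mode[i] <- "pad"
          target <- sample(801:1200, 1)
          extra <- max(target - L, 1L)
          out$sequence[i] <- paste0(
            out$sequence[i],
            paste(sample(DNA_BASES, extra, replace = TRUE), collapse = ""))
        }
      }
    })
  }

  amb_hit <- draw("ambiguous", defects$p_ambiguous)
  if (any(amb_hit)) {
    with_preserved_seed(derive_seed(defects$seed, "ambiguous:detail"), {
      for (i in which(amb_hit)) {
        pos <- sample.int(nchar(out$sequence[i]), 1)
        code <- sample(IUPAC_AMBIGUOUS, 1)
        substr(out$sequence[i], pos, pos) <- code
      }
    })
  }

  name_hit <- draw("bad_name", defects$p_bad_name)
  if (any(name_hit)) {
    with_preserved_seed(derive_seed(defects$seed, "bad_name:detail"), {
      for (i in which(name_hit)) {
        style <- sample(c("sp.", "aff.", "cf.", "uncultured"), 1)
        if (style %in% c("aff.", "cf.")) {
          out$name_qualifiers[i] <- out$species_epithet[i]
          out$species_epithet[i] <- style
        } else {
          out$species_epithet[i] <- style
          out$name_qualifiers[i] <- ""
        }
      }
    })
  }

  vou_hit <- draw("no_voucher", defects$p_no_voucher)
  out$voucher[vou_hit] <- ""

  loc_hit <- draw("no_locality", defects$p_no_locality)
  out$locality[loc_hit] <- ""

  out$defect_bad_length <- len_hit
  out$bad_length_mode <- mode
  out$defect_ambiguous <- amb_hit
  out$defect_bad_name <- name_hit
  out$defect_no_voucher <- vou_hit
  out$defect_no_locality <- loc_hit
  out
}
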