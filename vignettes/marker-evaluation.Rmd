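---
title: "Evaluating ITS, ITS1 and ITS2 as genus-level barcode markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ITS, ITS1 and ITS2 as genus-level barcode markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA barcoding identifies a specimen by comparing a short standardized
genomic region against a reference library. For Fungi that region is the
nuclear ribosomal internal transcribed spacer (ITS), composed of two
variable spacers (ITS1, ITS2) flanking the conserved 5.8S gene; the
sub-regions on their own are popular metabarcoding markers for short-read
platforms. Whether a marker works for a given genus depends on whether
within-species (intraspecific) genetic distances stay below between-species
(interspecific) distances — the "barcode gap". `barcodegap` packages the two
standard instruments for asking that question at genus level:

* **PCI (probability of correct identification).** A species is counted as
  successfully identified when the minimum uncorrected interspecific
  p-distance involving that species is *strictly larger* than its maximum
  intraspecific distance; the genus PCI is the fraction of species so
  identified. Ties count as failures. Species represented by a single
  sequence have no intraspecific distance and are excluded from scoring,
  but their sequences still serve as interspecific partners for the others.
* **Barcode-gap classification.** Pooled intraspecific and interspecific
  distances of a genus are summarized as boxplots and the marker is called
  `good`, `intermediate` or `poor` depending on how the two boxes relate
  (details below). Combining the three markers' classes assigns each genus
  to one of four groups: all good (Group 1), some good (Group 2, the good
  markers being the recommended ones), none good but not all poor
  (Group 3), all poor (Group 4).

The pipeline around these instruments — metadata curation, region
extraction, per-genus distance matrices, cross-genus summaries — mirrors
how barcode-gap surveys of public repositories are actually conducted, and
every stage is exercised end-to-end on synthetic data with known ground
truth.

## The curation cascade

Sequences from public repositories vary widely in reliability, so the
pipeline starts from a FASTA file plus a metadata table (accession, genus,
species, voucher, country) and applies, in a fixed order, filters that keep
only records suitable for distance-based identification:

1. **voucher** — a record must cite a preserved specimen in a permanent
   collection; only non-emptiness of the field is checked, since voucher id
   formats are not standardized.
2. **ambiguity** — a single IUPAC ambiguity code (anything outside
   `{A,C,G,T}`) removes the record: ambiguous calls would bias p-distances.
3. **species names** — organism names containing `sp.`, `aff.`, `cf.` or
   `uncultured` are not identified to species level and are removed. Tokens
   are matched whole (split on whitespace, trailing periods stripped,
   case-insensitive), so an epithet that merely contains the letters `cf`
   is not a false hit.
4. **ITS completeness** — the record must contain a complete, splittable
   ITS1/5.8S/ITS2 partition (next section); failures are removals, not
   errors.
5. **lengths** — the full ITS must lie in the inclusive window
   [400, 800] bp and each spacer must be at least 100 bp. The window is
   read as inclusive at both ends: the intent is to exclude the tails
   *outside* the interval that covers the overwhelming majority of
   complete fungal ITS sequences, and the sub-100-bp spacer floor removes
   fragments that would destabilize alignments.
6. **localities** — records without a country of origin are dropped, and a
   species is retained only when its remaining records span at least three
   distinct localities (exact string match after trimming and
   case-folding). This guards against estimating intraspecific variation
   from near-clonal resampling of one population. The distinct-locality
   count is taken *after* dropping unlocated records — a declared choice,
   since located and unlocated records cannot be distinguished once the
   unlocated ones are gone.
7. **minimum species per genus** — contrasting intra- against
   interspecific distances requires at least two species, so genera
   reduced below that are removed entirely.

Each filter is a pure function; `run_curation()` chains them and reports
per-stage in/out counts and removed accessions. Per-record filters (1-3)
are idempotent and commute; the group filters (6-7) depend on surviving
group membership, which is why the cascade order is fixed.

An optional enrichment join (`enrich_metadata()`) fills *empty* metadata
fields from a second curated table keyed by accession; populated fields are
never overwritten. This models the common practice of supplementing
repository metadata from a curated community database, without committing
to any particular source's field mapping.

## Region extraction

Profile-HMM annotators locate the 5.8S by probabilistic matching against
curated models. For curated complete-ITS inputs a much simpler device
suffices and is exactly testable: `split_its()` finds a start motif and an
end motif (defaults: the first and last 20 bp of the packaged 5.8S core)
by sliding-window Hamming matching with a mismatch budget
(`max_mismatches`, default 1). The best hit wins, ties broken by fewest
mismatches then leftmost position; two equally good non-overlapping hits
make the split *ambiguous* and the record fails extraction. ITS1 is the
prefix before the start motif, 5.8S runs through the end of the end motif,
ITS2 is the suffix; all three parts must be non-empty. Coordinates are
0-based and half-open throughout the package.

The packaged 158-bp 5.8S core is a fixed synthetic constant — not a
database sequence — chosen so that anchor-based extraction is exact on
clean simulated data. Users processing real sequences should supply their
own anchors via `anchor_config()` or pre-extract regions with a dedicated
annotator and use the prealigned ingestion path.

## Distances

Distance matrices use the **uncorrected p-distance**: the proportion of
mismatching columns among columns where both sequences have a base, with
no substitution-model correction. Gap columns are excluded per pair
(pairwise deletion) by default; complete deletion (dropping every column
that has a gap in any sequence) is available for the prealigned path, and
the choice is a configuration switch because conventions differ between
tools.

Rather than re-implementing a published multiple aligner, the default path
aligns every pair independently with a global (end-to-end)
Needleman-Wunsch aligner. The scoring scheme is declared rather than
inherited from an external tool's defaults: match +1, mismatch −1, gap −2
(linear). Co-optimal alignments are resolved deterministically — diagonal
move preferred, then the move consuming the first sequence — so results
are reproducible to the byte. Each unordered pair is aligned exactly once.
Pairwise alignment was preferred over a multiple alignment because
per-genus MSA quality is not what is being evaluated here, pairwise
p-distances are deterministic and checkable against a literal
brute-force oracle, and users who prefer an external multiple aligner can
feed its output through the `prealigned` mode of
`genus_distance_matrix()`.

## Boxplot conventions and classification thresholds

Published gap classifications are typically made by visual inspection of
boxplots; this package operationalizes them so they are computable:

* Quartiles use linear interpolation (type-7 quantiles, the common
  default); whiskers extend to the most extreme data values within
  1.5 × IQR of the box; points beyond are outliers.
* `poor`: the boxes overlap (`intra q3 >= inter q1`) *or* the
  intraspecific values sit at or above the interspecific ones
  (`median(intra) >= median(inter)` — medians being the boxplot-native
  location statistic). The overlap test is one-sided because intraspecific
  distances are expected below interspecific ones.
* `intermediate`: boxes separated but whiskers overlap
  (`intra whisker_high >= inter whisker_low`).
* `good`: whiskers separated; overlapping *outliers* alone do not spoil a
  good call.
* Checks run in that order, so `poor` takes precedence over
  `intermediate` over `good`.

The Group 2 / Group 3 boundary is formalized as presence/absence of at
least one `good` marker. These thresholds are declared choices: a visual
classification has no unique algorithmic form, and exact reproduction of
any particular published genus-by-genus assignment is not claimed. The
boxplot pools use *all* sequence pairs, while PCI uses species-level
extrema; the two views are kept explicitly separate in the per-genus
results.

## The synthetic-data generator

The generator produces per-genus record sets with controllable divergence
structure plus repository-style defects, so that every downstream stage
can be tested against known truth without downloading anything.

**Mutation model.** Sequences evolve by i.i.d. per-site substitution to a
uniformly random different base; no indels, no rate heterogeneity, no
coalescent. This keeps expected p-distances analytic (a copy with exactly
*k* substituted sites at length *L* has p-distance *k/L*) at the cost of
realism — which is acceptable because the analyses being validated need
divergence *control*, not evolutionary fidelity.

**Divergence parameterization.** `intra_div` is the per-site substitution
probability between an individual and its species consensus; `inter_div`
is the per-site substitution probability between a species tip and the
genus ancestor. Internally the species branch is mutated at
`max(inter_div − intra_div, 0)` and each individual at `intra_div`, so
expected tip-to-tip intraspecific divergence is about `2·intra_div` and
interspecific about `2·inter_div`. This tip-divergence convention was
chosen deliberately: it makes `inter_div = intra_div` draw intra- and
interspecific distances from literally the same process (no barcode gap,
the `poor` reference condition) and makes the expected inter/intra
divergence ratio equal to `inter_div/intra_div` exactly. Had the species
branch been mutated at `inter_div` directly, interspecific pairs would
carry two extra branches and equal rates would still produce a clear —
and misleading — gap.

**Structure and metadata.** Each sequence is ITS1 + 5.8S core + ITS2 with
configurable lengths (defaults 250/158/250 bp, total 658, inside the
curation window). The 5.8S core embeds the extraction anchors exactly
(`s58_div` defaults to 0). Localities are assigned round-robin over a
country pool so every species spans at least three localities on clean
data; accessions, vouchers and Latin-flavoured epithets are deterministic.

**Defects.** `inject_defects()` corrupts records through five independent
Bernoulli channels matching the five metadata/sequence filters: an IUPAC
code at a random position; a blanked voucher; a name corrupted with `sp.`,
`aff.`, `cf.` or `uncultured`; a truncation below 400 bp or padding above
800 bp; a blanked locality. Channels draw from separate seeded substreams
(`derive_seed(seed, channel)`), so changing one probability never perturbs
another channel's draws, and the returned records carry ground-truth tag
columns that let tests replay the cascade symbolically. The length channel
is applied before the ambiguity channel so an injected code is never
truncated away.

**Seeding.** All randomness flows from integer seeds through a stable
31-bit polynomial hash (`derive_seed()`), giving per-genus and per-channel
substreams: identical (config, seed) pairs produce byte-identical FASTA
and TSV output, and adding a genus to a dataset does not change any other
genus. Generation never disturbs the caller's RNG state.

**What passing tests do and do not show.** The generator emulates the
*structure* the instruments respond to — gap present, borderline, absent —
and the defect classes the curation stage must catch. It does not emulate
indels and alignment ambiguity, rate variation across lineages or sites,
chimeras, sequencing error models, or the skewed species-abundance
distributions of real repositories. Recovery of ground truth on synthetic
genera therefore validates the implementation, not the biological adequacy
of ITS markers for any particular taxon.

## Packaged reference tables and comparison policy

The package ships two plain-text reference tables: a genus × marker PCI
table (113 genera, integer percent values) and a genus-to-group table
(groups 1-4 with recommended markers for Group 2).
`reproduce_published_summaries()` recomputes from them the column means,
the fractions of genera strictly above each mean, the three tie-corrected
Spearman correlations, and the genus and Group-4 counts, and compares each
against its published value. Because the table stores integer-printed PCI
values while the published summaries were computed from unrounded ones,
each recomputed value is rounded to the published printing precision
(integers for means, one decimal for percentages, four decimals for
correlations) before differencing; tolerances are 1 percentage point for
means and fractions, 0.01 for correlations, and exact for counts. Worth
noting: the means recomputed from the printed integers are 64.5 (ITS),
60.2 (ITS1) and 59.0 (ITS2), each about one point above the published
63/59/58 — a gap larger than integer rounding of the per-genus values
alone can explain (that bounds the drift at 0.5), which is why comparison
at printed precision with a 1-point tolerance is the package's declared
policy rather than exact equality. "Above the mean" is strict, consistent
with the published 60/113 = 53.1% for ITS.

## Validation problem sizes

The automated checks run at desk scale, chosen to exercise every code path
with comfortable statistical margins: ground-truth recovery uses 50
genera per condition (4 species × 3 sequences, 658-bp ITS) with
`inter_div = 10 × intra_div` (expect PCI 1 and class `good`) and
`inter_div = intra_div` (expect `poor`); oracle equivalence uses 100
random labelled matrices (up to 12 sequences, 2-4 species) plus
nested-loop recomputation of alignment-based matrices; curation
bookkeeping is verified record-exactly on a 1,000-record seeded defect
dataset replayed symbolically from the ground-truth tags.

## Known limitations

* The anchor-motif splitter is not a general rDNA annotator: it assumes a
  complete ITS with a recognizable 5.8S and no large rearrangements; there
  is no SSU/LSU flank detection.
* Pairwise alignment can place co-optimal gaps differently than an MSA
  would; for strongly diverged genera (p-distances above roughly 0.3)
  p-distances from either route carry alignment uncertainty that no
  deterministic tie-break removes.
* The gap classification operationalizes a visual convention; other
  reasonable thresholds (for example notch-based overlap) would shift
  borderline genera between classes.
* PCI treats species as given: cryptic species inflate intraspecific
  distances and deflate PCI, and no attempt is made to re-delimit species.
* No model-corrected distances (K2P and relatives) are provided — the
  uncorrected p-distance is the deliberate, assumption-free choice.
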