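---
title: "Analysing a direct-cloned viral metagenome shotgun library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a direct-cloned viral metagenome shotgun library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromelib)
```

## The problem this package addresses

Marine virus assemblages can be purified from seawater by filtration,
ultrafiltration and CsCl buoyant-density banding, their DNA extracted and
shotgun-cloned directly (with no prior amplification), and a few hundred
to a few thousand clones end-sequenced by the Sanger method. Analysing
such a library involves a chain of small, well-defined computations:

1. **Read processing** — trim reads to a quality window, assemble them
   under strict overlap criteria, and account for how many independent
   sequences remain.
2. **Hit annotation** — parse tabular similarity-search output (one row
   per query–subject match with an E-value), pick top hits, flag
   candidate viral hits by keyword, and tally source categories.
3. **Threshold sensitivity** — examine how the apparent taxonomic
   composition of the library changes with the significance threshold,
   and locate the E-value beyond which hit quality degrades sharply.
4. **Library comparison** — compare libraries by reciprocal
   cross-search, normalising for read length, and summarise each pair by
   a reciprocal distance.
5. **Particle accounting** — convert gradient-fraction measurements,
   particle counts and DNA yields into per-virus DNA content, an implied
   genome size, a recovery estimate, and the expected number of
   appearances of a single-copy viral gene in the sequenced library.

`viromelib` implements this chain as composable functions, together with
a synthetic-data generator that produces every input the pipeline
consumes, with planted truth, so each step can be validated end to end.

## Read processing

### Trimming

`trim_reads()` truncates reads longer than `max_len` (default 500 bp) at
the 3' end — Sanger base quality decays toward the 3' end, and with no
per-base quality model a fixed-window truncation is the reproducible
choice — and discards reads shorter than `min_len` (default 100 bp),
keeping the boundary read. The operation is idempotent and preserves
input order.

### Greedy overlap assembly

`assemble_greedy()` merges reads and contigs iteratively, always taking
the pair with the *longest* suffix–prefix overlap of at least
`min_overlap` bases (default 21) at ungapped identity of at least
`min_identity` (default 0.98), on either strand, until no qualifying
merge remains. Choices worth stating explicitly:

* **Identity is ungapped**: matches divided by overlap length. An
  overlap criterion phrased as a bare percentage admits several
  readings; the ungapped one is the simplest that is exactly testable,
  and it is the default here. Gapped alignment is deliberately out of
  scope.
* **Determinism**: ties on overlap length are broken by the
  lexicographically smallest member read ids, then by a fixed preference
  order over the four strand configurations. Two runs on the same input
  are byte-identical.
* **Consensus**: at a merge only two sequences cover the overlap, so
  "majority base with ties to the earlier member" reduces to keeping the
  earlier-assembled item's bases across the overlap.
* **The k-mer prescreen is exact**: candidate pairs are restricted to
  those sharing an exact k-mer, with k chosen from the identity bound —
  an overlap of length L with m mismatches contains an exact run of at
  least ceiling((L−m)/(m+1)) bases, and k is the minimum of that bound
  over all admissible L. The screen therefore cannot discard a
  qualifying merge; the test suite also checks the assembler against a
  brute-force all-pairs oracle with no prescreen.

### Contig classification

Clone ids follow the grammar `<lib>_P<plate>_<row><col>.<F|R>`.
`classify_contigs()` marks a contig `same_clone` when all members share
library, plate and well (the forward and reverse read of one clone);
`adjacent_well_suspect` when members share a plate and sit in wells at
Manhattan distance 1 (the signature of well-to-well carry-over — the
narrowest reading of "adjacent", so diagonal neighbours do *not*
qualify); and `independent` otherwise. `post_assembly_count()` and
`interclone_read_fraction()` provide the bookkeeping: n reads collapsing
into c contigs of m total members leave n − m + c sequences, and the
reads in non-same-clone contigs are reported as a percentage of all
reads at one decimal.

## Hit annotation

Hit tables are TSVs with one row per query–subject match
(`query_id, subject_id, percent_identity, evalue, bit_score, database,
subject_description, source_category`). Source categorisation is carried
as a column — populated by the generator, or by the user's own curation
when real search output is supplied — because faithful automated
taxonomy assignment is a separate problem this package does not attempt.

* Significance is **inclusive**: `filter_significant()` keeps
  E ≤ threshold (default 10^-3).
* `top_hit_per_query()` minimises the E-value, breaking ties by larger
  bit score, then lexicographic subject id.
* `keyword_virus_flag()` performs case-insensitive plain substring
  matching against the eight virus keywords ("phage", "virus", "capsid",
  "tail", "integrase", "base plate", "baseplate", "portal"). Substring
  semantics are intentional — "prophage" matches, but so does
  "cocktail" — so flagged hits are *candidates*; the confirmed category
  lives in `source_category`, mirroring the manual verification step
  such screens require.
* `any_viral_hit_summary()` counts queries with *any* significant viral
  hit, not only viral top hits, de-duplicating queries hit in several
  databases; queries whose only viral evidence is a match to another
  viral metagenome are counted separately from known-virus matches.
  Percentages are reported over known-virus queries, rounded half-up to
  integers.

## Threshold sensitivity

`sweep_thresholds()` recomputes the broad-group composition (virus,
prokaryote, eukaryote, other) of significant top hits at each threshold
of a descending E-value grid (default decades 10^-10 … 10^-1), along
with the cumulative fraction of queries significant at each threshold.
`bin_by_decade()` gives the per-decade view; bins are half-open,
lower-inclusive `[10^k, 10^(k+1))`, so an E-value of exactly 10^-3 falls
in the `[10^-3, 10^-2)` bin — the same convention as the inclusive
significance boundary. By default mobile genetic elements are *not*
folded into the virus group (range breakdowns report them separately);
the collapse map is an argument.

`detect_breakpoint()` operationalises the "sharp decline" in hit
quality: over decades ordered stringent to loose it returns the adjacent
pair with the maximal decrease in the summed virus + prokaryote
proportion, ties going to the most stringent pair and a series with no
decrease returning nothing. A cumulative sweep is first differenced back
into per-interval composition, which makes the sweep-based and bin-based
answers agree exactly when the sweep thresholds are the decade edges.
This max-drop rule is our operationalisation of an informally described
feature, and reports should label it as such.

## Library comparison

For a reference library R and query library Q, `compare_pair()` computes
the three pairwise parameters from reciprocal cross-search hit tables:

* hits into R as a percentage of R's sequences,
* hits into Q as a percentage of Q's sequences,
* hits into R per 100 (optionally length-normalised) query sequences,
  whose reciprocal is the **distance** between the libraries.

A "hit" is a *sequence* with at least one match at E ≤ 10^-5
(inclusive), not a match row: the quantity of interest is the proportion
of a library's sequences with a counterpart, which per-HSP counting
would inflate. Read-length normalisation
(`length_normalized_size()`) scales Q's sequence count by the ratio of
its mean read length to R's, compensating for the higher per-sequence
hit rate of longer reads; with equal mean lengths it is exactly the
identity. Zero hits yield an explicit infinite-distance sentinel, which
`rank_libraries()` sorts last but never drops. Both directions of a
comparison are reported separately rather than averaged, since the
underlying searches are asymmetric.

`naive_cross_search()` is a desk-scale stand-in for a translated
similarity search: a query read hits a target read when they share an
exact word of `word_size` (default 20) bases on either strand, with a
pseudo-E-value of 10^-5 at exactly `word_size` matched bases shrinking
fourfold per extra matched base. It is labelled a stand-in deliberately:
real search output in the same TSV dialect drops in wherever it is used.

## Particle accounting

The accounting functions are exact arithmetic with stated rounding:
density = mass / volume; total particles = Σ concentration × volume over
the harvested fractions; DNA per particle in attograms (10^-18 g),
rounded half-up to an integer; implied genome size = mass × Avogadro /
660 Da per bp (the standard dsDNA constant; it is an argument, and 650
would shift a ~38 kb genome to ~39 kb); recovery bracketed by a
historical abundance range with the bounds crossed (low abundance gives
the high recovery estimate); and expected single-copy gene appearances =
total sequenced bases / genome size. All reported roundings are
round-half-up at the printed precision (integers for attograms, kb and
percent; one decimal for ratios), implemented in `round_half_up()`
because R's default banker's rounding would turn 2.25 into 2.2.

## The synthetic-data generator

`genome_model()` draws genome lengths from a four-class mixture
(30–45 kb, 60–80 kb, ~125 kb, >146 kb by default, the size classes seen
on pulsed-field gels of marine virus concentrates). The class weights
are not documented anywhere we know of, so the defaults (0.40, 0.30,
0.15, 0.15) put most mass on the smaller, tailed-phage-like classes;
they are ordinary arguments. Genome composition is i.i.d. uniform at the
stated GC fraction — no repeats, no codon structure — which suffices for
exercising overlap detection and assembly. Uniform selection across
genomes when cloning is likewise an assumption of convenience, not a
claim about any real community's abundance structure.

`clone_model()` / `shear_and_clone()` emulate nebulised, size-selected
(1.4–4 kb by default), blunt-cloned inserts end-sequenced from one or
both ends; `duplicate_clone_rate` re-emits inserts under fresh well ids,
planting the "legitimate" inter-clone contigs an assembler should
recover. `simulate_hit_table()` gives each query a hit with probability
`hit_rate`, draws source categories from a stated composition and
E-values log10-uniformly within per-category decade ranges — enough
structure to exercise threshold sweeps across decades without modelling
alignment score statistics. `simulate_gradient()` produces fractions
with monotonically increasing density and particles banding in stated
peak fractions (1.44–1.47 g/ml by default).
`generate_library_pair()` builds two libraries over genome pools sharing
a stated fraction, then cross-searches them both ways.
`generate_planted_library()` constructs a read set whose assembly
outcome is known exactly: paired reads across short inserts (same-clone
contigs), duplicated inserts in adjacent wells (different-name contigs),
and singletons drawn from disjoint genome windows so no other qualifying
overlap exists by construction.

Every generator takes one integer seed; a global seed expands to
per-operation sub-seeds by fixed offsets, so the same seed re-runs any
stage independently and byte-identically.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: sequencing error and chromatogram quality,
chimeric clones, cloning bias, repeat structure within genomes, real
alignment score statistics, and real database composition. Results that
depend on searching real databases (the fraction of a real library with
significant matches, real inter-library distances) are out of reach of
synthetic data by construction and are not claimed.

## Problem sizes and numerical choices

The shipped test-suite and acceptance-script sizes were chosen so each
property has clear statistical headroom while the whole suite stays
quick on a single CPU: assembly bookkeeping on a 907-read planted
library; assembler-versus-oracle equivalence on 50 seeded instances of
up to 20 reads; read-count conservation on 100 random instances;
planted-composition recovery at n = 5000 (binomial 99% CIs and a
chi-square goodness-of-fit at α = 0.01); planted-cliff break-point
detection on 50 seeded tables; comparison monotonicity across shared
fractions {0, 0.25, 0.5, 0.75, 1} with 5 seeds each on 100-read
libraries; and an end-to-end run on ~1,000 reads. Degenerate inputs
follow the contracts stated in the function documentation: empty inputs
return empty results where that is meaningful (trimming, filtering),
and raise informative errors where a quantity is undefined (densities
of non-positive mass, ratios with zero denominators, empty fraction
selections, zero-read interclone fractions).

## Known limitations

* The assembler is greedy; it makes no attempt at optimal multi-read
  layout, mirroring the step it replaces rather than improving on it.
* Ungapped overlap identity slightly under-merges relative to a gapped
  criterion when indels are present; with error-free synthetic reads the
  two coincide.
* Keyword flagging is a recall-oriented screen with known false
  positives by design; precision comes from the curated category column.
* The pseudo-E-value of the naive cross search is a calibrated monotone
  score, not an extreme-value statistic; distances computed from it are
  comparable to each other, not to distances from a real search.
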