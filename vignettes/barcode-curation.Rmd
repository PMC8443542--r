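---
title: "Curating DNA barcode reference datasets with barcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating DNA barcode reference datasets with barcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcurate)
```

## The problem

Reference datasets for DNA barcoding — typically the COI-5P fragment for
animals — are scattered across repositories with different record shapes
(BOLD process records, GenBank nucleotide entries), inconsistent marker
naming ("COI-5P", "cytochrome c oxidase subunit I", typo variants), and a
non-trivial fraction of problematic records: missing sequences or taxonomy,
open nomenclature ("Neotamias sp. 3"), mislabeled or contaminant sequences,
ambiguity-ridden reads, and pseudogene-like sequences that do not translate
cleanly. Assembling a project-specific reference set by hand is slow and,
worse, unreproducible. `barcurate` turns the whole procedure into four
deterministic, parameterised stages so the exact dataset can be rebuilt from
a genus list and a handful of published arguments.

## The four stages

### 1. Acquisition and harmonization

Records from BOLD-style and GenBank-style sources are fetched through an
*injectable transport* (a small list of functions). Live HTTP transports are
provided, but any stage of the pipeline can be run offline by replaying
stored responses — which is also how the entire test suite runs. The default
GenBank query per genus is

```
(genus[ORGN]) NOT (shotgun[ALL] OR genome[ALL] OR assembled[ALL] OR microsatellite[ALL])
```

which excludes genome-scale and microsatellite records that are useless for
barcode work. Each raw record is harmonized into one row of a *total table*:
the organism string is split into genus (first term) and species (the
remainder, verbatim), the marker name is kept both raw and normalized, and
six quality flags are computed:

| flag | meaning |
|---|---|
| `no_marker` | marker name empty |
| `no_taxa` | genus or species missing (a binomial is required downstream) |
| `no_seq` | empty sequence |
| `name_issue` | more than two terms in "genus species" |
| `taxa_digits` | digits in the name |
| `taxa_punct` | punctuation in the name (any non-letter/digit/space, including hyphens) |

Records identical in accession across sources are collapsed to the first
occurrence. Inclusion is *conjunctive*: a record enters downstream FASTA
assembly only if every flag it carries has been explicitly permitted, so the
default (all toggles off) keeps only unflagged records.

### 2. Genus-by-marker FASTA assembly

Marker names are normalized (uppercase, whitespace removed, only letters,
digits and hyphen kept) and matched **exactly** against a user-supplied
synonym table: one column per genus-by-marker group, the genus in row one
and the synonym list below. We deliberately do no fuzzy matching: the
synonym table is the user's explicit, publishable statement of which naming
variants belong to which marker, and the output file
(`<genus>_<first synonym>.fas`) is named after the first synonym. FASTA
headers carry `uid|accession|genus|species|marker` so taxonomy survives into
the alignment and cleaning stages.

### 3. Reference-guided alignment and trimming

Each group FASTA is aligned with MAFFT against a single reference sequence
for the target region. The gap-opening penalty is exposed (`op`, default 10;
MAFFT's own default is 1.53) because barcode regions are highly conserved
and length variation is almost always artefactual — stiff gap penalties
suppress spurious gaps. After alignment:

1. columns outside the reference's first/last non-gap column are cropped and
   the reference row is dropped;
2. records with leading or trailing gaps inside that window (incomplete
   coverage of the reference extent, any run length) are removed;
3. rare internal insertions are resolved by the `pigl` rule: a column whose
   gap fraction strictly exceeds `pigl` (default 0.95) is an insertion
   private to a small minority, and the records holding residues there are
   removed; `pigl = 0` disables the rule.

Two numerical choices deserve a note. *Strictness*: "more than the
proportion" is read as a strict `>`, so a column gapped in exactly 19 of 20
rows (0.95) does not trigger at the default threshold. *Iteration*: removing
one insertion's carriers can push a second, near-threshold column over the
limit; the rule therefore iterates to a fixpoint rather than making a single
pass. The fixpoint is deterministic, makes the operation idempotent (running
it twice never changes the result — a property the test suite checks on
random gapped alignments), and removal counts remain monotone as `pigl`
decreases. Reported trigger columns stay in the input alignment's 1-based
coordinates because columns are only deleted after the iteration ends.

### 4. Cleaning

Cleaning assigns **exactly one flag per record**, in a fixed precedence
order (`non_AGCT` → `Stop_Codon` → `Genus_Outlier` → `Species_Outlier`),
so the output data table partitions the input:

1. **Residue screen** (`agct_only`, default on): any non-AGCT residue flags
   the record. Alignment gaps are ignored — they are artifacts of the
   alignment, not residues.
2. **Translation screen** (`aa_code`, default `"invert"`): the degapped
   sequence is translated in all three forward frames under the chosen
   genetic code (standard, vertebrate-mitochondrial or
   invertebrate-mitochondrial; tables from Biostrings' NCBI translation
   tables 1, 2 and 5). The record passes if any frame with at least one
   complete codon is stop-free. The any-frame rule exists because the
   reading frame of a trimmed fragment is not guaranteed; reverse frames
   are not read because orientation is fixed by the alignment stage.
   Codons containing ambiguous bases are skipped rather than counted as
   stops.
3. **Distance outliers**: a pairwise p-distance matrix is computed over the
   screen survivors with pairwise deletion — per pair, only positions where
   both sequences hold an unambiguous base are compared; pairs with no
   comparable sites get a missing distance. Outliers are flagged first at
   the genus level, then (among the remainder) at the species level.
4. **Barcode gap**: for the retained records, each species' maximum
   intraspecific distance is compared with its minimum distance to any
   other species; a gap is present when the latter strictly exceeds the
   former.

### The outlier rule

The outlier criterion is the one place where the procedure is a genuine
design choice rather than a mechanical rule, so it is worth stating
precisely. Within each group (genus, then species) of at least
`min_group_size` members (default 4 — quartiles on two or three points are
meaningless), we compute an upper Tukey fence over the group's **pairwise
distances**:

$$\mathrm{fence} = Q_3 + k \times (Q_3 - Q_1), \qquad k = 1.5$$

with quartiles by linear interpolation (R's type-7 quantiles). A record is
an outlier when its **median** distance to the other group members strictly
exceeds the fence. Records that share no comparable site with any group
member cannot be placed and are likewise flagged (at the genus stage).

Two alternatives were considered and rejected on measured grounds:

* computing the fence over the per-record *mean* distances makes the fence
  collapse onto the spread of the means themselves; on simulated
  ten-record genera this false-flags a clean record in roughly a third of
  datasets — unusable;
* keeping the fence on pairwise distances but summarising each record by
  its *mean* distance fails differently: one genuine outlier inflates every
  other record's mean by `d/(n-1)`, dragging clean records over the fence
  exactly when an outlier is present.

The median summary is immune to single-outlier contamination, achieves 100%
recovery of planted outliers at 30% divergence and a measured false-flag
rate indistinguishable from zero under the synthetic study conditions below.
The summary statistic remains switchable (`statistic = "mean"`) and the
multiplier configurable for users who want the classical behaviour.
Species-level evaluation runs *after* genus-level outliers are removed
(sequentially), since a genus-level contaminant would otherwise poison its
species' quartiles too.

## The synthetic study conditions

The fixture generator is first-class, tested code; its defaults define the
conditions under which the pipeline's operating characteristics are
measured:

| parameter | default | why |
|---|---|---|
| `seq_len` | 658 | canonical COI-5P amplicon length |
| `background_divergence` | 0.01 | conspecific-scale per-site variation |
| `n_clean` | 10, as two species of 5 | small but quartile-stable groups; two species keep the barcode-gap report non-degenerate |
| `outlier_divergence` | 0.30 | far beyond congeneric distances (~15x the expected clean pairwise distance of `2p(1-p)` ≈ 0.0198) |
| `n_ambig`, `n_stop` | 1 each | one planted `N` record, one record with stops in all three frames |
| `n_insertion` | 0 (3 bases when used) | insertion fixtures use 24 clean rows so one insertion column exceeds `pigl = 0.95` (24/25 = 0.96) |

The ancestor is drawn codon-wise from non-stop codons (frame 1), and point
mutations that would create a stop in frame 1 are repaired, so "clean"
records are coding-like by construction; the stop-codon record plants
`TAA` at three offsets covering all frames, so it fails translation under
every supported code regardless of frame.

What the generator deliberately does **not** emulate: interspecific
divergence (both "species" diverge from one ancestor at the same rate, so
barcode gaps are genuinely absent in the fixtures and the gap report's
negative results there are correct, not a bug), transition/transversion
bias, rate heterogeneity along the sequence, phylogenetic structure,
sequencing-error tails, heteroplasmy and chimeras. Passing tests on these
fixtures therefore demonstrate the *mechanics* of screening, outlier
detection and trimming under controlled truth — not field performance on
real GenBank/BOLD downloads, where error modes are richer.

## Degenerate inputs and tie-breaks

* Identical sequences throughout a group: all summary distances equal the
  fence; the strict `>` means nobody is flagged.
* Fewer than two records after the screens: distance, outlier and gap
  stages are skipped with a warning; outputs are still written.
* Equal `min_inter` and `max_intra`: no barcode gap (strict `>`).
* A species with one member has no `max_intra`; its gap status is missing,
  not false.
* Empty marker names are an error at normalization time, but records with
  empty markers simply carry the `no_marker` flag.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
twenty seeded fixtures of 13 records x 658 bp for truth recovery, a
25-row insertion fixture for the trimming invariants, 1000 random
alignments against brute-force oracles, and one 7-sequence MAFFT round
trip. These sizes were chosen as the smallest at which every rule
(quartile fences, the 0.95 column threshold, frame screening) is exercised
away from its degenerate regime.

## Known limitations

* Live transports fetch only summary fields from the GenBank docsum
  endpoint; a production deployment would swap in a transport backed by a
  full E-utilities client. The transport interface exists precisely so this
  is a drop-in replacement.
* Reverse-complemented records are not detected or reoriented; sequences
  are assumed oriented before alignment (MAFFT is not run with
  `--adjustdirection`).
* No model-corrected distances (K2P etc.), haplotype collapsing, or OTU
  clustering — p-distances are the deliberate, simple standard here.
* Dereplication is by accession identity only; near-duplicate records from
  the same specimen under different accessions are kept.
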