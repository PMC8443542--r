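# barcurate

Assembly, alignment trimming and cleaning of DNA barcode reference
datasets in R.

Building a project-specific barcode reference set (classically the COI-5P
mitochondrial fragment) means pulling records from BOLD- and GenBank-style
sources, reconciling inconsistent marker names, aligning everything against
a reference, and weeding out records that are mislabeled, ambiguous or
pseudogene-like. Done by hand this is slow and unreproducible. `barcurate`
implements the workflow as four deterministic stages — **download →
group → align/trim → clean** — each driven by a small set of publishable
parameters, so the exact dataset can be rebuilt from a genus list.

## The core rules

* **Record flags** gate inclusion: `no_marker`, `no_taxa`, `no_seq`,
  `name_issue` (>2 name terms), `taxa_digits`, `taxa_punct`; a record
  passes only if every flag it carries is explicitly permitted.
* **Reference-guided trimming**: the alignment is cropped to the
  reference's non-gap extent; records not fully covering that window are
  dropped; a column whose gap fraction exceeds `pigl` (default 0.95) marks
  a private insertion and its carrier records are removed (iterated to a
  fixpoint).
* **Cleaning** assigns one flag per record, in order `non_AGCT` →
  `Stop_Codon` → `Genus_Outlier` → `Species_Outlier` → `-`:
  pairwise p-distances with pairwise deletion
  (d = mismatches / sites where both rows hold A/C/G/T), stop-codon
  screening in all three forward frames under the standard, vertebrate- or
  invertebrate-mitochondrial code (default `invert`), and a group Tukey
  fence Q3 + 1.5 × IQR over the group's pairwise distances — a record is an
  outlier when its median within-group distance exceeds the fence.
* **Barcode gap** per species: gap present iff the minimum distance to any
  other species strictly exceeds the maximum intraspecific distance.

## Worked example

The package ships a deterministic fixture generator with known ground
truth, which doubles as a demonstration dataset: ten clean records (two
species of five), one divergent outlier (30% divergence), one
ambiguity-bearing record and one record with planted stop codons, all 658
bp.

```r
library(barcurate)

fx  <- generate_fixture(fixture_spec(seed = 1))
res <- clean_dataset(fx$aligned, verbose = FALSE)
res
#> <clean_result>
#>   non_AGCT         1
#>   Stop_Codon       1
#>   Genus_Outlier    1
#>   Species_Outlier  0
#>   -                10
res$barcode_gap
#>              species n  max_intra  min_inter gap_present
#> 1 Simulomys speciesa 5 0.03343465 0.01367781       FALSE
#> 2 Simulomys speciesb 5 0.02431611 0.01367781       FALSE
```

The three planted anomalies are flagged for exactly the right reasons and
all ten clean records are retained. The barcode gap is genuinely absent
here — both fixture "species" diverge from one ancestor at the same rate,
so the maximum intraspecific distance (≈0.03) exceeds the minimum
interspecific distance (≈0.014); real sister species with diverged
barcodes would show the opposite sign.

The marker-synonym parameter table for stage 2 looks like this (one column
per output FASTA; see `inst/extdata/marker_synonyms_example.tsv`):

```r
specs <- parse_parameter_file(system.file("extdata",
                              "marker_synonyms_example.tsv",
                              package = "barcurate"))
vapply(specs, `[[`, "", "output_name")
#> [1] "Neotamias_CYTB"            "Neotamias_COI-5P"
#> [3] "Neotamias_18SRIBOSOMALRNA"
```

A shell entry point mirrors the stages (`exec/barcurate` after
installation, or `run_cli()` in-process):

```
barcurate download    --input genus_list.txt --output DIR
barcurate make-fastas --data A_Total_Table.dat --params params.tsv --output DIR
barcurate align-trim  --data DIR --ref ref.fas [--pigl 0.95] [--op 10]
barcurate clean       --data DIR [--aa-code invert] [--multiplier 1.5]
```

Every run writes a JSON manifest (arguments, version, input digests) next
to its outputs.

## Documentation

The methods vignette (`vignettes/barcode-curation.Rmd`) describes the
model and rules in detail: the outlier fence and why the median summary
statistic is used, the `pigl` fixpoint iteration, the genetic-code tables,
what the synthetic fixtures do and do not emulate, and the package's known
limitations.
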