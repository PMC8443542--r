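#' Specification of a synthetic barcode fixture
#'
#' Describes a deterministic synthetic genus dataset with known ground
#' truth for every pipeline stage: clean records mutated from a shared
#' ancestor at a background per-site divergence, planted divergent
#' outliers, ambiguity-bearing records, records carrying an in-frame stop
#' codon in all three forward frames, and records with a short internal
#' insertion.
#'
#' Defaults emulate a small single-genus COI-5P dataset: 658 bp (the
#' canonical animal barcode amplicon), 1% background per-site divergence
#' (conspecific-scale variation), one planted outlier at 30% divergence
#' (far beyond any congeneric distance), one ambiguity record, one
#' stop-codon record, no insertions, and ten clean records split across
#' two species of five.
#'
#' @param seed Integer seed; the same spec and seed reproduce the fixture
#'   byte for byte.
#' @param n_clean Number of clean records.
#' @param seq_len Ancestor length (bases).
#' @param background_divergence Per-site mutation probability of clean
#'   records relative to the ancestor.
#' @param n_outliers,outlier_divergence Planted divergent records and
#'   their per-site divergence (must exceed the background).
#' @param n_ambig Records carrying an `N`.
#' @param n_stop Records carrying stop codons in all three forward frames
#'   (under the invertebrate mitochondrial code, whose stops TAA/TAG are
#'   stops in all three screening codes).
#' @param n_insertion,insertion_len Records carrying an internal insertion
#'   of `insertion_len` bases.
#' @param species_partition Integer vector of clean-record species-group
#'   sizes; must sum to `n_clean`. `NULL` puts all clean records in one
#'   species.
#' @param genus Genus name used in record headers (synthetic).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_clean = 10L, seq_len = 658L,
                         background_divergence = 0.01, n_outliers = 1L,
                         outlier_divergence = 0.30, n_ambig = 1L,
                         n_stop = 1L, n_insertion = 0L, insertion_len = 3L,
                         species_partition = NULL, genus = "Simulomys") {
  if (is.null(species_partition)) {
    species_partition <- if (n_clean == 10L) c(5L, 5L) else n_clean
  }
  if (n_clean > 0L && sum(species_partition) != n_clean)
    stopf("species_partition must sum to n_clean (%d != %d)",
          sum(species_partition), n_clean)
  counts <- c(n_clean, n_outliers, n_ambig, n_stop, n_insertion,
              insertion_len, seq_len)
  if (any(counts < 0L)) stopf("all counts must be non-negative")
  if (n_outliers > 0L && outlier_divergence <= background_divergence)
    stopf("outlier_divergence must exceed background_divergence")
  if (n_stop > 0L && seq_len < 12L)
    stopf("seq_len %d is too short to plant stop codons in all three frames",
          seq_len)
  if (n_insertion > 0L && seq_len < insertion_len + 2L)
    stopf("seq_len too short for internal insertions of length %d",
          insertion_len)
  structure(list(seed = as.integer(seed), n_clean = as.integer(n_clean),
                 seq_len = as.integer(seq_len),
                 background_divergence = background_divergence,
                 n_outliers = as.integer(n_outliers),
                 outlier_divergence = outlier_divergence,
                 n_ambig = as.integer(n_ambig), n_stop = as.integer(n_stop),
                 n_insertion = as.integer(n_insertion),
                 insertion_len = as.integer(insertion_len),
                 species_partition = as.integer(species_partition),
                 genus = genus),
            class = "fixture_spec")
}

# stop codons visible in every forward frame: TAA at offsets 0, 4 and 8
# covers all residues mod 3
STOP_PLANT <- "TAAATAAATAA"

# union of stop codons across the three screening codes (std/vert/invert)
ANY_STOP <- c("TAA", "TAG", "TGA", "AGA", "AGG")

# random coding-like sequence: frame-1 codons drawn from non-stop codons,
# so clean records have a stop-free forward frame by construction
random_coding_ancestor <- function(len) {
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  codons <- sample(setdiff(all_codons, ANY_STOP), ceiling(len / 3),
                   replace = TRUE)
  strsplit(paste(codons, collapse = ""), "")[[1L]][seq_len(len)]
}

# point mutations occasionally create a frame-1 stop; repair by setting the
# middle base to C (TAA->TCA, TAG->TCG, TGA->TCA, AGA->ACA, AGG->ACG)
repair_frame1_stops <- function(chars) {
  starts <- seq(1L, length(chars) - 2L, by = 3L)
  for (k in starts) {
    if (paste(chars[k:(k + 2L)], collapse = "") %in% ANY_STOP)
      chars[k + 1L] <- "C"
  }
  chars
}

mutate_sites <- function(ancestor, rate) {
  hit <- which(stats::runif(length(ancestor)) < rate)
  if (length(hit))
    ancestor[hit] <- vapply(ancestor[hit], function(b)
      sample(setdiff(BASES, b), 1L), character(1L))
  repair_frame1_stops(ancestor)
}

#' Generate a synthetic fixture with known truth
#'
#' Derives an ancestor sequence from the seed and produces the records
#' described by the spec, together with the reference sequence (the
#' ancestor), a pre-gapped aligned variant (insertion columns padded with
#' `-`, so trimming logic is testable without running an aligner) and the
#' truth table of expected cleaning flags. Record headers follow the
#' pipeline convention `uid|accession|genus|species|marker`.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fixture` with elements `records` (unaligned,
#'   insertions inline), `aligned` ([msa] over all records), `reference`
#'   (named character of length 1), `truth` (data frame `id`,
#'   `expected_flag`), `removed_by_trim` (ids the alignment stage is
#'   expected to drop under the default `pigl`), `trimmed_len`, and
#'   `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  len <- spec$seq_len
  ancestor <- random_coding_ancestor(len)

  species_of_clean <- if (length(spec$species_partition) == 0L) character() else
    rep(paste0("species", letters[seq_along(spec$species_partition)]),
        spec$species_partition)
  sp1 <- if (length(species_of_clean)) species_of_clean[[1L]] else "speciesa"
  ids <- character()
  seqs <- list()
  truth_flag <- character()
  species <- character()
  add <- function(id, seq_chars, flag, sp) {
    ids <<- c(ids, id)
    seqs[[length(seqs) + 1L]] <<- seq_chars
    truth_flag <<- c(truth_flag, flag)
    species <<- c(species, sp)
  }
  for (i in seq_len(spec$n_clean))
    add(sprintf("clean_%02d", i),
        mutate_sites(ancestor, spec$background_divergence), "-",
        species_of_clean[[i]])
  for (i in seq_len(spec$n_outliers))
    add(sprintf("outlier_%02d", i),
        mutate_sites(ancestor, spec$outlier_divergence), "Genus_Outlier",
        sp1)
  for (i in seq_len(spec$n_ambig)) {
    s <- mutate_sites(ancestor, spec$background_divergence)
    s[sample(len, 1L)] <- "N"
    add(sprintf("ambig_%02d", i), s, "non_AGCT", sp1)
  }
  for (i in seq_len(spec$n_stop)) {
    s <- mutate_sites(ancestor, spec$background_divergence)
    pos <- sample(len - nchar(STOP_PLANT), 1L)
    s[pos:(pos + nchar(STOP_PLANT) - 1L)] <- strsplit(STOP_PLANT, "")[[1L]]
    add(sprintf("stop_%02d", i), s, "Stop_Codon", sp1)
  }
  insertion_at <- if (spec$n_insertion > 0L)
    sample(seq(2L, len - 1L), 1L) else NA_integer_
  for (i in seq_len(spec$n_insertion)) {
    s <- mutate_sites(ancestor, spec$background_divergence)
    ins <- sample(BASES, spec$insertion_len, replace = TRUE)
    add(sprintf("insert_%02d", i),
        repair_frame1_stops(append(s, ins, after = insertion_at)), "-",
        sp1)
  }

  headers <- sprintf("%s|%s|%s|%s|COI-5P", ids, toupper(ids), spec$genus,
                     species)
  records <- setNames(vapply(seqs, paste, character(1L), collapse = ""),
                      headers)

  # pre-gapped variant: non-insertion rows get insertion_len gaps at the
  # insertion point so all rows share one coordinate system
  if (spec$n_insertion > 0L) {
    gap <- strrep("-", spec$insertion_len)
    aligned <- vapply(seq_along(seqs), function(k) {
      s <- seqs[[k]]
      if (startsWith(ids[[k]], "insert_")) paste(s, collapse = "") else
        paste0(paste(s[seq_len(insertion_at)], collapse = ""), gap,
               paste(s[(insertion_at + 1L):len], collapse = ""))
    }, character(1L))
    names(aligned) <- headers
  } else {
    aligned <- records
  }

  n_rows <- length(records)
  gap_frac <- if (n_rows > 0L) (n_rows - spec$n_insertion) / n_rows else 0
  removed_by_trim <- if (spec$n_insertion > 0L && gap_frac > 0.95)
    headers[startsWith(ids, "insert_")] else character()

  structure(list(
    records = records,
    aligned = msa(aligned),
    reference = setNames(paste(ancestor, collapse = ""), "reference|REF|ref|ref|COI-5P"),
    truth = data.frame(id = headers, expected_flag = truth_flag,
                       stringsAsFactors = FALSE),
    removed_by_trim = removed_by_trim,
    trimmed_len = len,
    spec = spec), class = "fixture")
}

#' Serialize a fixture as source-shaped inputs
#'
#' Emits the same fixture records in both source shapes consumed by the
#' acquisition stage — a BOLD-style TSV and a list of GenBank-style record
#' maps — plus, optionally, extra records each deliberately violating one
#' record-flag rule, with the expected flags recorded in the returned
#' truth table.
#'
#' @param spec A [fixture_spec()].
#' @param violations Named integer vector (subset of names: `no_marker`,
#'   `no_taxa`, `no_seq`, `name_issue`, `taxa_digits`, `taxa_punct`)
#'   giving how many violating records to append for each rule.
#' @return A list with `bold_tsv` (character lines), `genbank_records`
#'   (list of record maps) and `truth` (data frame: accession, expected
#'   flags string).
#' @export
make_source_fixtures <- function(spec, violations = integer()) {
  fx <- generate_fixture(spec)
  parts <- strsplit(names(fx$records), "|", fixed = TRUE)
  acc <- vapply(parts, `[[`, character(1L), 2L)
  organism <- vapply(parts, function(p) paste(spec$genus, p[[4L]]),
                     character(1L))
  seqsv <- unname(fx$records)
  marker <- rep("COI-5P", length(acc))

  bad <- setdiff(names(violations), RECORD_FLAGS)
  if (length(bad)) stopf("unknown violation rule(s): %s", paste(bad, collapse = ", "))
  vrows <- list()
  for (rule in names(violations)) {
    for (k in seq_len(violations[[rule]])) {
      base <- list(accession = sprintf("VIOL_%s_%02d", toupper(rule), k),
                   organism = paste(spec$genus, "typica"),
                   marker = "COI-5P", sequence = "ACGTACGT")
      v <- switch(rule,
        no_marker   = { base$marker <- ""; base },
        no_taxa     = { base$organism <- spec$genus; base },
        no_seq      = { base$sequence <- ""; base },
        name_issue  = { base$organism <- paste(spec$genus, "typica minor"); base },
        taxa_digits = { base$organism <- paste(spec$genus, "typica2"); base },
        taxa_punct  = { base$organism <- paste(spec$genus, "typica-minor"); base })
      vrows[[length(vrows) + 1L]] <- v
    }
  }
  acc <- c(acc, vapply(vrows, `[[`, character(1L), "accession"))
  organism <- c(organism, vapply(vrows, `[[`, character(1L), "organism"))
  marker <- c(marker, vapply(vrows, `[[`, character(1L), "marker"))
  seqsv <- c(seqsv, vapply(vrows, `[[`, character(1L), "sequence"))

  bold_tsv <- c("processid\tspecies_name\tmarkercode\tnucleotides",
                paste(acc, organism, marker, seqsv, sep = "\t"))
  genbank_records <- lapply(seq_along(acc), function(i)
    list(accession = acc[[i]], organism = organism[[i]], gene = marker[[i]],
         product = "", definition = "", sequence = seqsv[[i]]))
  truth <- data.frame(
    accession = acc,
    flags = vapply(seq_along(acc), function(i) {
      terms <- strsplit(trimws(organism[[i]]), "[[:space:]]+")[[1L]]
      sp <- if (length(terms) >= 2L) paste(terms[-1L], collapse = " ") else ""
      flags_to_string(flag_record(terms[[1L]], sp, marker[[i]], seqsv[[i]]))
    }, character(1L)), stringsAsFactors = FALSE)
  list(bold_tsv = bold_tsv, genbank_records = genbank_records, truth = truth)
}

#' Write a fixture to disk
#'
#' Emits the unaligned records FASTA, the pre-aligned FASTA, the reference
#' FASTA, the BOLD-style TSV and a JSON truth file under `out_dir`.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the named character vector of written paths.
#' @export
write_fixture_files <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- generate_fixture(spec)
  src <- make_source_fixtures(spec)
  paths <- c(
    records = file.path(out_dir, "records.fas"),
    aligned = file.path(out_dir, "aligned.fas"),
    reference = file.path(out_dir, "reference.fas"),
    bold = file.path(out_dir, "bold.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_fasta(fx$records, paths[["records"]])
  write_fasta(fx$aligned, paths[["aligned"]])
  write_fasta(fx$reference, paths[["reference"]])
  writeLines(src$bold_tsv, paths[["bold"]], useBytes = TRUE)
  jsonlite::write_json(
    list(truth = fx$truth, removed_by_trim = fx$removed_by_trim,
         trimmed_len = fx$trimmed_len),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
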