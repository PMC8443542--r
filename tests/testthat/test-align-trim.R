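test_that("trimming crops to the reference window and drops partial coverage", {
  aln <- msa(c(ref = "--ACGT--", s1 = "TTACGTAA", s2 = "--AC--TT"),
             ref_id = "ref")
  out <- trim_to_reference(aln)
  expect_equal(unclass(out)[["s1"]], "ACGT", ignore_attr = TRUE)
  expect_false("ref" %in% names(out))
  expect_false("s2" %in% names(out))
  expect_equal(attr(out, "removed")$id, "s2")
  expect_equal(attr(out, "removed")$reason, "trailing_gap")

  # ungapped reference spanning everything: targets unchanged
  aln2 <- msa(c(ref = "ACGT", a = "AGGT", b = "ACGA"), ref_id = "ref")
  out2 <- trim_to_reference(aln2)
  expect_equal(unclass(out2), c(a = "AGGT", b = "ACGA"), ignore_attr = TRUE)

  # all targets partial -> empty alignment, all removals reported
  aln3 <- msa(c(ref = "ACGT", a = "-CGT", b = "ACG-"), ref_id = "ref")
  out3 <- trim_to_reference(aln3)
  expect_length(out3, 0)
  expect_setequal(attr(out3, "removed")$id, c("a", "b"))

  expect_error(trim_to_reference(msa(c(ref = "----", a = "ACGT"),
                                     ref_id = "ref")),
               "entirely of gaps")
  expect_error(trim_to_reference(msa(c(a = "ACGT"))), "ref_id")
})

gappy_msa <- function(n_rows, carrier_rows = 1L, len = 10L, gap_col = 5L) {
  base <- strrep("A", len)
  rows <- vapply(seq_len(n_rows), function(i) {
    if (i <= carrier_rows) base else {
      s <- strsplit(base, "")[[1]]
      s[gap_col] <- "-"
      paste(s, collapse = "")
    }
  }, character(1))
  names(rows) <- sprintf("s%02d", seq_len(n_rows))
  msa(rows)
}

test_that("the internal-gap rule removes insertion carriers above the threshold", {
  # pigl = 0 disables internal-gap handling entirely
  aln <- gappy_msa(25)
  expect_equal(unclass(resolve_internal_gaps(aln, pigl = 0)), unclass(aln),
               ignore_attr = TRUE)

  # 19/20 gapped: fraction 0.95 is NOT > 0.95 -> unchanged
  out20 <- resolve_internal_gaps(gappy_msa(20), pigl = 0.95)
  expect_length(out20, 20)
  expect_equal(msa_width(out20), 10)

  # 24/25 gapped: 0.96 > 0.95 -> carrier removed, column deleted
  out25 <- resolve_internal_gaps(gappy_msa(25), pigl = 0.95)
  expect_length(out25, 24)
  expect_equal(msa_width(out25), 9)
  expect_equal(attr(out25, "removed"), "s01")
  expect_equal(attr(out25, "trigger_columns"), 5L)
})

test_that("lowering pigl never removes fewer records (monotonicity)", {
  set.seed(42)
  for (k in 1:25) {
    aln <- random_gapped_msa(n = sample(5:15, 1), len = sample(8:20, 1),
                             gap_prob = runif(1, 0.3, 0.8))
    removed <- vapply(c(0.9, 0.7, 0.5, 0.3),
                      function(p) length(attr(resolve_internal_gaps(aln, p),
                                              "removed")),
                      numeric(1))
    expect_true(all(diff(removed) >= 0),
                info = paste("case", k, ":", paste(removed, collapse = ",")))
  }
})

test_that("a second pass of the internal-gap rule changes nothing", {
  set.seed(43)
  for (k in 1:25) {
    aln <- random_gapped_msa(n = sample(5:15, 1), len = sample(8:20, 1),
                             gap_prob = runif(1, 0.3, 0.8))
    for (p in c(0.5, 0.8, 0.95)) {
      once <- resolve_internal_gaps(aln, p)
      if (length(once) == 0) next
      twice <- resolve_internal_gaps(once, p)
      expect_equal(unclass(twice), unclass(once), ignore_attr = TRUE,
                   info = paste("case", k, "pigl", p))
    }
  }
})

test_that("trimmed width equals reference length once insertions resolve", {
  spec <- fixture_spec(seed = 5, n_clean = 24, n_outliers = 0, n_ambig = 0,
                       n_stop = 0, n_insertion = 1, insertion_len = 3,
                       species_partition = 24)
  fx <- generate_fixture(spec)
  stopifnot(msa_width(fx$aligned) == spec$seq_len + 3)
  # the reference has no insertion, so use a gap-padded row as the guide
  ref_row <- unclass(fx$aligned)[[which(!grepl("insert",
                                               names(fx$aligned)))[1]]]
  trimmed <- trim_to_reference(msa(c(structure(setNames(ref_row, "REF")),
                                     unclass(fx$aligned)), ref_id = "REF"))
  expect_equal(nrow(attr(trimmed, "removed")), 0)
  resolved <- resolve_internal_gaps(trimmed, pigl = 0.95)
  expect_equal(attr(resolved, "removed"), fx$removed_by_trim)
  expect_equal(msa_width(resolved), spec$seq_len)
  expect_length(resolved, 24)
})

test_that("MAFFT alignment plus trimming reproduces ungapped inputs", {
  mafft <- Sys.which("mafft")
  fx <- generate_fixture(fixture_spec(seed = 3, n_clean = 6, seq_len = 120,
                                      n_outliers = 0, n_ambig = 0, n_stop = 0,
                                      species_partition = 6))
  dir <- withr::local_tempdir()
  write_fasta(fx$records, file.path(dir, "Simulomys_COI-5P.fas"))
  ref_path <- file.path(dir, "ref.fas")
  write_fasta(fx$reference, ref_path)

  aln <- invoke_aligner(file.path(dir, "Simulomys_COI-5P.fas"), ref_path,
                        op = 10, mafft = mafft)
  expect_s3_class(aln, "msa")
  expect_length(aln, 7)  # reference + 6 targets
  # point mutations only: nothing should need gaps
  expect_equal(msa_width(aln), 120)

  report <- align_and_trim_folder(dir, ref_path, mafft = mafft,
                                  verbose = FALSE)
  expect_equal(report$status, "ok")
  expect_true(file.exists(file.path(dir, "MAFFT",
                                    "Simulomys_COI-5P_MAFFT.fas")))
  trimmed <- read_fasta_msa(file.path(dir, "MAFFT_trimmed",
                                      "Simulomys_COI-5P_MAFFT_trimmed.fas"))
  expect_equal(msa_width(trimmed), 120)
  expect_length(trimmed, 6)
  expect_true(file.exists(file.path(dir, "MAFFT_log.txt")))
})

test_that("aligner precondition failures are reported", {
  dir <- withr::local_tempdir()
  write_fasta(c(a = "ACGT"), file.path(dir, "t.fas"))
  write_fasta(c(r1 = "ACGT", r2 = "ACGT"), file.path(dir, "ref2.fas"))
  expect_error(invoke_aligner(file.path(dir, "t.fas"),
                              file.path(dir, "ref2.fas")),
               "exactly one sequence")
  write_fasta(c(r1 = "ACGT"), file.path(dir, "ref1.fas"))
  expect_error(invoke_aligner(file.path(dir, "t.fas"),
                              file.path(dir, "ref1.fas"),
                              mafft = "/nonexistent/mafft"),
               "MAFFT executable not found")
  expect_error(align_and_trim_folder(withr::local_tempdir(),
                                     file.path(dir, "ref1.fas")),
               "no FASTA files found")
})
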