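test_that("p-distances use pairwise deletion over unambiguous bases", {
  dm <- p_distance_matrix(msa(c(a = "AAAA", b = "AAAA")))
  expect_equal(dm$d["a", "b"], 0)
  expect_equal(dm$n_sites["a", "b"], 4L)

  dm2 <- p_distance_matrix(msa(c(a = "AAAA", b = "AAAT")))
  expect_equal(dm2$d["a", "b"], 0.25)

  dm3 <- p_distance_matrix(msa(c(a = "AA-A", b = "AATA")))
  expect_equal(dm3$d["a", "b"], 0)
  expect_equal(dm3$n_sites["a", "b"], 3L)

  # no comparable sites -> missing distance
  dm4 <- p_distance_matrix(msa(c(a = "NN--", b = "--NN")))
  expect_true(is.na(dm4$d["a", "b"]))
  expect_equal(dm4$n_sites["a", "b"], 0L)

  expect_error(p_distance_matrix(msa(c(a = "ACGT"))), "at least 2")
})

test_that("p-distances match the brute-force oracle on random pairs", {
  set.seed(101)
  for (k in 1:300) {
    len <- sample(10:120, 1)
    aln <- random_gapped_msa(2, len, gap_prob = runif(1, 0, 0.3),
                             ambig_prob = runif(1, 0, 0.2))
    dm <- p_distance_matrix(aln)
    o <- oracle_p_distance(aln[[1]], aln[[2]])
    expect_equal(dm$d[1, 2], o$d, info = paste("case", k))
    expect_equal(dm$n_sites[1, 2], o$n, info = paste("case", k))
  }
})

test_that("p-distances agree with ape's raw pairwise-deletion distances", {
  set.seed(7)
  fx <- generate_fixture(fixture_spec(seed = 7, n_ambig = 0, n_stop = 0))
  dm <- p_distance_matrix(fx$aligned)
  bin <- ape::as.DNAbin(do.call(rbind,
                                strsplit(tolower(unclass(fx$aligned)), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm$d[rownames(ref), colnames(ref)]), unname(ref),
               tolerance = 1e-12)
})

test_that("distance outliers are flagged against the group Tukey fence", {
  # 9 tight sequences and one divergent member
  set.seed(21)
  fx <- generate_fixture(fixture_spec(seed = 21, n_clean = 9, n_outliers = 1,
                                      n_ambig = 0, n_stop = 0,
                                      species_partition = 9))
  dm <- p_distance_matrix(fx$aligned)
  groups <- setNames(rep("g", length(fx$aligned)), names(fx$aligned))
  out <- flag_distance_outliers(dm, groups)
  expect_equal(out, grep("outlier", names(fx$aligned), value = TRUE))
  expect_equal(out, oracle_outliers(dm$d, names(fx$aligned)))

  # all sequences identical: fence 0, strict > never fires
  ident <- msa(setNames(rep("ACGTACGTAC", 6), paste0("s", 1:6)))
  expect_length(flag_distance_outliers(p_distance_matrix(ident),
                                       setNames(rep("g", 6), paste0("s", 1:6))),
                0)

  # groups below min_group_size contribute no outliers
  two <- msa(c(x = "AAAAAAAAAA", y = "TTTTTTTTTT"))
  expect_length(flag_distance_outliers(p_distance_matrix(two),
                                       c(x = "g", y = "g")), 0)
})

test_that("outlier calls match an independent quartile oracle on random groups", {
  set.seed(99)
  for (k in 1:40) {
    n <- sample(5:12, 1)
    aln <- random_gapped_msa(n, 60, gap_prob = 0.05, ambig_prob = 0.05)
    dm <- p_distance_matrix(aln)
    got <- sort(flag_distance_outliers(dm, setNames(rep("g", n), names(aln)),
                                       min_group_size = 4))
    want <- sort(oracle_outliers(dm$d, names(aln)) %||% character())
    expect_equal(got, want, info = paste("case", k))
  }
})

test_that("the genetic code tables carry the expected stop codons", {
  std <- genetic_code("std")
  vert <- genetic_code("vert")
  inv <- genetic_code("invert")
  for (code in list(std, vert, inv)) expect_length(code, 64)
  expect_setequal(names(std)[std == "*"], c("TAA", "TAG", "TGA"))
  expect_setequal(names(vert)[vert == "*"], c("TAA", "TAG", "AGA", "AGG"))
  expect_setequal(names(inv)[inv == "*"], c("TAA", "TAG"))
  expect_equal(unname(vert[["TGA"]]), "W")
  expect_equal(unname(inv[["AGA"]]), "S")
})

test_that("translation passes when any forward frame is stop-free", {
  expect_true(translation_check("ATGGCCATT", genetic_code("invert")))
  # frame 1 hits AGA (vertebrate stop) but frame 2 reads TGA as Trp
  expect_true(translation_check("ATGAGAAAA", genetic_code("vert")))
  # frame 1 is all stops under the standard code; frame 2 is stop-free
  expect_true(translation_check("TAATAGTGA", genetic_code("std")))
  # stops planted in all three frames fail every code
  planted <- "TAAATAAATAA"
  for (code in c("std", "vert", "invert"))
    expect_false(translation_check(planted, genetic_code(code)))
  # gaps are ignored before framing
  expect_true(translation_check("AT-GGC--CATT", genetic_code("invert")))
  # shorter than one codon after degapping fails
  expect_false(translation_check("AC-", genetic_code("invert")))
})

test_that("the AGCT screen ignores gaps but rejects ambiguity codes", {
  expect_true(agct_check("ACGT"))
  expect_true(agct_check("acgt"))
  expect_true(agct_check("AC-GT"))
  expect_false(agct_check("ACGTN"))
  expect_false(agct_check("ACGRT"))
})

test_that("barcode-gap rows match the all-pairs oracle", {
  aln <- msa(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAT",
               s3 = "TTTTTAAAAA"))
  dm <- p_distance_matrix(aln)
  species <- c(s1 = "A", s2 = "A", s3 = "B")
  rep <- barcode_gap_report(dm, species)
  a <- rep[rep$species == "A", ]
  expect_equal(a$max_intra, 0.1)
  expect_equal(a$min_inter, 0.5)  # d(s1,s3): 5 of 10 sites differ
  expect_true(a$gap_present)
  b <- rep[rep$species == "B", ]
  expect_true(is.na(b$max_intra))
  expect_equal(b$min_inter, 0.5)
  expect_true(is.na(b$gap_present))

  # identical sequences across two species: gap strictly absent
  same <- msa(c(x1 = "ACGT", x2 = "ACGT", y1 = "ACGT", y2 = "ACGT"))
  r2 <- barcode_gap_report(p_distance_matrix(same),
                           c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_false(any(r2$gap_present))

  # single species: no heterospecific pair
  r3 <- barcode_gap_report(p_distance_matrix(msa(c(a = "ACGT", b = "ACGA"))),
                           c(a = "S", b = "S"))
  expect_true(is.na(r3$min_inter))

  # random instances against the brute-force oracle
  set.seed(31)
  for (k in 1:30) {
    n <- sample(4:10, 1)
    aln <- random_gapped_msa(n, 40)
    dm <- p_distance_matrix(aln)
    sp <- setNames(sample(c("A", "B", "C"), n, replace = TRUE), names(aln))
    got <- barcode_gap_report(dm, sp)
    want <- oracle_barcode_gap(dm$d, sp)
    for (s in got$species) {
      expect_equal(got$max_intra[got$species == s], want[[s]]$max_intra,
                   info = paste("case", k, s))
      expect_equal(got$min_inter[got$species == s], want[[s]]$min_inter,
                   info = paste("case", k, s))
    }
  }
})

test_that("clean_dataset assigns one flag per record with fixed precedence", {
  fx <- generate_fixture(fixture_spec(seed = 2))
  res <- clean_dataset(fx$aligned, verbose = FALSE)
  truth <- setNames(fx$truth$expected_flag, fx$truth$id)
  expect_equal(res$flags[names(truth)], truth)
  counts <- table(res$flags)
  expect_equal(unname(counts[["-"]]), 10)
  expect_length(res$retained, 10)
  # partition invariant: every id appears exactly once
  expect_setequal(names(res$flags), names(fx$aligned))
  expect_equal(length(res$retained) + sum(res$flags != "-"),
               length(fx$aligned))
  # distance matrix excludes the residue/translation failures
  expect_false(any(grepl("ambig|stop", res$dist$ids)))

  # all-clean input passes through unchanged
  clean_only <- fx$aligned[grepl("clean", names(fx$aligned))]
  res2 <- clean_dataset(msa(clean_only), verbose = FALSE)
  expect_true(all(res2$flags == "-"))
  expect_equal(unclass(res2$retained), clean_only, ignore_attr = TRUE)

  # with both screens off only distance-based flags remain possible
  res3 <- clean_dataset(fx$aligned,
                        config = clean_config(aa_code = "off",
                                              agct_only = FALSE),
                        verbose = FALSE)
  expect_true(all(res3$flags %in%
                    c("-", "Genus_Outlier", "Species_Outlier")))
  expect_equal(sum(res3$flags == "Genus_Outlier"), 1)
})

test_that("clean_dataset degrades gracefully below two survivors", {
  aln <- msa(c("a|A|G|s|M" = "NNNN", "b|B|G|s|M" = "ACGT"))
  expect_warning(res <- clean_dataset(aln, verbose = FALSE),
                 "fewer than 2")
  expect_null(res$dist)
  expect_equal(unname(res$flags), c("non_AGCT", "-"))
})

test_that("clean_folder writes the three outputs per input FASTA", {
  fx <- generate_fixture(fixture_spec(seed = 4))
  dir <- withr::local_tempdir()
  write_fasta(fx$aligned, file.path(dir, "Simulomys_COI-5P.fas"))
  res <- clean_folder(dir, log_name = "A_Clean_File_test.txt",
                      verbose = FALSE)
  base <- "Simulomys_COI-5P"
  expect_true(file.exists(file.path(dir, paste0(base, "_dist_table.dat"))))
  expect_true(file.exists(file.path(dir, paste0(base, "_data_table.dat"))))
  expect_true(file.exists(file.path(dir, paste0(base, "_no_outlier.fas"))))
  expect_true(file.exists(file.path(dir, "A_Clean_File_test.txt")))
  no_out <- read_fasta(file.path(dir, paste0(base, "_no_outlier.fas")))
  expect_length(no_out, 10)
  tab <- utils::read.delim(file.path(dir, paste0(base, "_data_table.dat")))
  expect_equal(sort(unique(tab$flag)),
               sort(c("-", "Genus_Outlier", "Stop_Codon", "non_AGCT")))
  # distance table is square over the records entering the distance stage
  dist_lines <- readLines(file.path(dir, paste0(base, "_dist_table.dat")))
  expect_length(dist_lines, 12)  # header + 11 survivors
})
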