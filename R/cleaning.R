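CLEAN_FLAGS <- c("non_AGCT", "Stop_Codon", "Genus_Outlier", "Species_Outlier", "-")

#' Cleaning configuration
#'
#' @param aa_code Genetic code for stop-codon screening: `"invert"`
#'   (invertebrate mitochondrial, the default), `"vert"` (vertebrate
#'   mitochondrial), `"std"` (standard), or `"off"` to skip translation
#'   screening.
#' @param agct_only Keep only sequences whose residues are exclusively
#'   A/G/C/T (alignment gaps ignored); other IUPAC characters flag the
#'   record. Default `TRUE`.
#' @param outlier_multiplier Tukey-fence multiplier for distance-outlier
#'   detection (default 1.5).
#' @param min_group_size Smallest genus/species group evaluated for
#'   outliers (default 4).
#' @param statistic Per-record summary distance compared against the
#'   fence; see [flag_distance_outliers()].
#' @return A list of class `clean_config`.
#' @export
clean_config <- function(aa_code = c("invert", "vert", "std", "off"),
                         agct_only = TRUE, outlier_multiplier = 1.5,
                         min_group_size = 4L,
                         statistic = c("median", "mean")) {
  aa_code <- match.arg(aa_code)
  statistic <- match.arg(statistic)
  if (!is.numeric(outlier_multiplier) || outlier_multiplier <= 0)
    stopf("outlier_multiplier must be positive")
  if (!is.numeric(min_group_size) || min_group_size < 2)
    stopf("min_group_size must be an integer >= 2")
  structure(list(aa_code = aa_code, agct_only = isTRUE(agct_only),
                 outlier_multiplier = outlier_multiplier,
                 min_group_size = as.integer(min_group_size),
                 statistic = statistic),
            class = "clean_config")
}

#' AGCT-only residue check
#'
#' `TRUE` iff every non-gap character of the sequence is one of A, C, G, T
#' (case-insensitive). Alignment gaps (`-`) are ignored: the check targets
#' residue content, not alignment artifacts.
#'
#' @param sequence Nucleotide string (possibly gapped).
#' @return Logical scalar.
#' @examples
#' agct_check("AC-GT")   # TRUE
#' agct_check("ACGTN")   # FALSE
#' @export
agct_check <- function(sequence) {
  !grepl("[^ACGT-]", toupper(sequence))
}

#' Stop-codon translation check
#'
#' Degaps the sequence and translates all three forward reading frames
#' under the given genetic code, skipping codons containing non-AGCT
#' characters. The check passes iff at least one frame holding at least
#' one complete codon is free of stop codons. The reading frame after
#' trimming is not guaranteed, hence the any-frame rule; reverse frames
#' are not read because orientation is fixed by the alignment stage.
#' Sequences shorter than one codon after degapping fail.
#'
#' @param sequence Nucleotide string (possibly gapped).
#' @param code A [genetic_code()] table.
#' @return Logical scalar: `TRUE` when a stop-free frame exists.
#' @export
translation_check <- function(sequence, code = genetic_code("invert")) {
  s <- toupper(gsub("-", "", sequence, fixed = TRUE))
  n <- nchar(s)
  if (n < 3L) return(FALSE)
  for (offset in 0:2) {
    n_codons <- (n - offset) %/% 3L
    if (n_codons < 1L) next
    starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, starts, starts + 2L)
    codons <- codons[grepl("^[ACGT]{3}$", codons)]
    if (!any(code[codons] == "*")) return(TRUE)
  }
  FALSE
}

#' Clean a trimmed barcode alignment
#'
#' Runs the cleaning pipeline on one genus-by-marker alignment, in fixed
#' order, with one flag per record (first failure wins):
#'
#' 1. residue screen — non-AGCT residues flag `non_AGCT` (when
#'    `agct_only`);
#' 2. translation screen — no stop-free forward frame flags `Stop_Codon`
#'    (when `aa_code != "off"`);
#' 3. a pairwise p-distance matrix is computed over the survivors;
#' 4. genus-level distance outliers flag `Genus_Outlier` (this also
#'    catches records with no comparable sites anywhere);
#' 5. species-level outliers among the remaining records flag
#'    `Species_Outlier` (sequential: genus outliers are already out);
#' 6. a barcode-gap report is computed over the retained (`"-"`) records.
#'
#' With fewer than two survivors after steps 1-2 the distance, outlier and
#' gap stages are skipped with a warning.
#'
#' @param aln An [msa] (a trimmed alignment).
#' @param taxonomy Data frame with columns `id`, `genus`, `species`
#'   covering all alignment ids (`species` is the specific epithet; the
#'   binomial used for grouping is `genus species`). If `NULL`, taxonomy
#'   is recovered from `uid|accession|genus|species|marker` headers.
#' @param config A [clean_config()].
#' @param verbose Emit messages.
#' @return A list of class `clean_result`: `flags` (named vector over
#'   `non_AGCT`, `Stop_Codon`, `Genus_Outlier`, `Species_Outlier`, `-`),
#'   `retained` (the [msa] of `-` records), `dist` (the
#'   [p_distance_matrix()] over step-1/2 survivors, or `NULL`),
#'   `barcode_gap` (data frame, or `NULL`), `taxonomy`, `config`.
#' @export
clean_dataset <- function(aln, taxonomy = NULL, config = clean_config(),
                          verbose = TRUE) {
  ids <- names(aln)
  if (is.null(taxonomy)) taxonomy <- header_taxonomy(ids)
  missing <- setdiff(ids, taxonomy$id)
  if (length(missing))
    stopf("taxonomy does not cover: %s", paste(missing, collapse = ", "))
  taxonomy <- taxonomy[match(ids, taxonomy$id), , drop = FALSE]
  flags <- setNames(rep("-", length(ids)), ids)

  if (config$agct_only) {
    bad <- !vapply(aln, agct_check, logical(1L))
    flags[bad] <- "non_AGCT"
  }
  if (config$aa_code != "off") {
    code <- genetic_code(config$aa_code)
    cand <- flags == "-"
    bad <- !vapply(aln[cand], translation_check, logical(1L), code = code)
    flags[names(which(cand))[bad]] <- "Stop_Codon"
  }

  survivors <- ids[flags == "-"]
  dm <- NULL
  gap <- NULL
  if (length(survivors) < 2L) {
    warning("fewer than 2 records survive the residue/translation screens; distance, outlier and barcode-gap stages skipped",
            call. = FALSE)
  } else {
    dm <- p_distance_matrix(aln[survivors])
    genus_of <- setNames(taxonomy$genus, taxonomy$id)[survivors]
    g_out <- flag_distance_outliers(dm, genus_of,
                                    multiplier = config$outlier_multiplier,
                                    min_group_size = config$min_group_size,
                                    statistic = config$statistic)
    flags[g_out] <- "Genus_Outlier"

    remaining <- ids[flags == "-"]
    if (length(remaining) >= 2L) {
      binomial <- setNames(paste(taxonomy$genus, taxonomy$species),
                           taxonomy$id)
      sub <- subset_p_dist(dm, remaining)
      s_out <- flag_distance_outliers(sub, binomial[remaining],
                                      multiplier = config$outlier_multiplier,
                                      min_group_size = config$min_group_size,
                                      statistic = config$statistic)
      flags[s_out] <- "Species_Outlier"
    }

    retained_ids <- ids[flags == "-"]
    if (length(retained_ids) >= 2L) {
      binomial <- setNames(paste(taxonomy$genus, taxonomy$species),
                           taxonomy$id)
      gap <- barcode_gap_report(subset_p_dist(dm, retained_ids),
                                binomial[retained_ids])
    }
  }
  counts <- table(factor(flags, levels = CLEAN_FLAGS))
  bc_log(sprintf("[clean] %s", paste(names(counts), counts, sep = "=",
                                     collapse = " ")), verbose = verbose)
  structure(list(flags = flags,
                 retained = msa(unclass(aln)[flags == "-"]),
                 dist = dm, barcode_gap = gap, taxonomy = taxonomy,
                 config = config),
            class = "clean_result")
}

subset_p_dist <- function(dm, ids) {
  structure(list(ids = ids, d = dm$d[ids, ids, drop = FALSE],
                 n_sites = dm$n_sites[ids, ids, drop = FALSE]),
            class = "p_dist")
}

#' @export
print.clean_result <- function(x, ...) {
  counts <- table(factor(x$flags, levels = CLEAN_FLAGS))
  cat("<clean_result>\n")
  for (f in CLEAN_FLAGS) cat(sprintf("  %-16s %d\n", f, counts[[f]]))
  invisible(x)
}

#' Clean every alignment FASTA in a folder
#'
#' Applies [clean_dataset()] to each FASTA in `data_folder` and writes,
#' per input `<name>.fas`: `<name>_dist_table.dat` (TSV square p-distance
#' matrix over the records entering the distance stage),
#' `<name>_data_table.dat` (TSV: id, genus, species, flag) and
#' `<name>_no_outlier.fas` (the retained records). One run log
#' (`A_Clean_File_<timestamp>.txt` by default) accumulates per-file flag
#' counts and the barcode-gap rows.
#'
#' @param data_folder Folder with trimmed alignment FASTAs.
#' @param config A [clean_config()].
#' @param output Output folder; defaults to `data_folder`.
#' @param log_name Run-log file name; pass a fixed name for byte-stable
#'   reruns.
#' @param verbose Emit messages.
#' @return Invisibly, a named list of [clean_dataset()] results.
#' @export
clean_folder <- function(data_folder, config = clean_config(), output = NULL,
                         log_name = NULL, verbose = TRUE) {
  files <- list.files(data_folder, pattern = "\\.(fas|fasta|fa)$",
                      full.names = TRUE)
  files <- files[!grepl("_no_outlier\\.fas$", files)]
  if (length(files) == 0L) stopf("no FASTA files found in %s", data_folder)
  output <- output %||% data_folder
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  log_name <- log_name %||%
    format(Sys.time(), "A_Clean_File_%Y-%m-%d_%H%M%S.txt")
  log_path <- file.path(output, log_name)
  results <- list()
  for (f in files) {
    base <- sub("\\.(fas|fasta|fa)$", "", basename(f))
    aln <- read_fasta_msa(f)
    res <- clean_dataset(aln, taxonomy = NULL, config = config,
                         verbose = verbose)
    if (!is.null(res$dist)) {
      d <- res$dist$d
      write_square_table(d, file.path(output, paste0(base, "_dist_table.dat")))
    } else {
      writeLines(character(), file.path(output, paste0(base, "_dist_table.dat")))
    }
    data_tab <- data.frame(id = names(res$flags),
                           genus = res$taxonomy$genus,
                           species = res$taxonomy$species,
                           flag = unname(res$flags), stringsAsFactors = FALSE)
    utils::write.table(data_tab,
                       file.path(output, paste0(base, "_data_table.dat")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(res$retained,
                file.path(output, paste0(base, "_no_outlier.fas")))
    counts <- table(factor(res$flags, levels = CLEAN_FLAGS))
    cat(sprintf("%s\t%s\n", basename(f),
                paste(names(counts), counts, sep = "=", collapse = "\t")),
        file = log_path, append = TRUE)
    if (!is.null(res$barcode_gap)) {
      gap_lines <- apply(res$barcode_gap, 1L, function(r)
        paste(c(basename(f), r), collapse = "\t"))
      cat(paste0(gap_lines, "\n", collapse = ""), file = log_path,
          append = TRUE)
    }
    results[[basename(f)]] <- res
  }
  invisible(results)
}

write_square_table <- function(d, path) {
  lines <- c(paste(c("", colnames(d)), collapse = "\t"),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(rownames(d)[i],
                       formatC(d[i, ], format = "g", digits = 10)),
                     collapse = "\t"), character(1L)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
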