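#' Alignment/trimming configuration
#'
#' @param pigl Proportion-internal-gap threshold in `[0, 1]`. A column
#'   whose gap fraction strictly exceeds `pigl` triggers removal of the
#'   records holding residues there (see [resolve_internal_gaps()]);
#'   `pigl = 0` disables internal-gap removal entirely. Default `0.95`.
#' @param op MAFFT gap-opening penalty (positive). MAFFT's own default is
#'   1.53; for highly conserved barcode regions such as COI-5P, where no
#'   gaps are expected, a much stiffer penalty is appropriate and 10 is
#'   the default here.
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(pigl = 0.95, op = 10) {
  if (!is.numeric(pigl) || length(pigl) != 1L || pigl < 0 || pigl > 1)
    stopf("pigl must be a single number in [0, 1]")
  if (!is.numeric(op) || length(op) != 1L || op <= 0)
    stopf("op (gap opening penalty) must be a single positive number")
  structure(list(pigl = pigl, op = op), class = "trim_config")
}

#' Align target sequences against a single reference with MAFFT
#'
#' Concatenates the reference (first) and target sequences, runs the MAFFT
#' executable with the given gap-opening penalty and returns the resulting
#' alignment as an [msa] with `ref_id` set to the reference's identifier.
#'
#' @param target_fasta Path to the FASTA of unaligned target sequences.
#' @param ref_fasta Path to a FASTA containing exactly one reference
#'   sequence.
#' @param op Gap-opening penalty passed to MAFFT (`--op`).
#' @param mafft Path to the MAFFT executable; defaults to `mafft` on the
#'   search path.
#' @param out_path Optional path at which the raw aligned FASTA is
#'   persisted (conventionally `<name>_MAFFT.fas`).
#' @return An [msa] including the reference row.
#' @export
invoke_aligner <- function(target_fasta, ref_fasta, op = 10,
                           mafft = Sys.which("mafft"), out_path = NULL) {
  mafft <- as.character(mafft)
  if (!nzchar(mafft) || !file.exists(mafft))
    stopf(paste0("MAFFT executable not found (looked at '%s'); install MAFFT ",
                 "(https://mafft.cbrc.jp/alignment/software/) or pass its ",
                 "location via 'mafft'"), mafft)
  ref <- read_fasta(ref_fasta)
  if (length(ref) != 1L)
    stopf("reference FASTA must contain exactly one sequence, found %d",
          length(ref))
  targets <- read_fasta(target_fasta)
  tmp_in <- tempfile(fileext = ".fas")
  tmp_out <- tempfile(fileext = ".fas")
  tmp_err <- tempfile(fileext = ".log")
  on.exit(unlink(c(tmp_in, tmp_out, tmp_err)), add = TRUE)
  write_fasta(c(ref, targets), tmp_in)
  status <- suppressWarnings(
    system2(mafft, args = c("--op", format(op), "--quiet", shQuote(tmp_in)),
            stdout = tmp_out, stderr = tmp_err))
  if (!identical(status, 0L))
    stopf("MAFFT exited with status %s: %s", status,
          paste(readLines(tmp_err, warn = FALSE), collapse = " "))
  aln <- read_fasta_msa(tmp_out, ref_id = names(ref))
  if (!is.null(out_path)) write_fasta(aln, out_path)
  aln
}

#' Trim an alignment to the reference extent
#'
#' Columns outside the first/last non-gap column of the reference row are
#' removed, the reference row itself is dropped, and any record whose
#' trimmed row starts or ends with one or more gaps — i.e. does not fully
#' cover the reference window — is removed. Removed identifiers are
#' attached as the `removed` attribute (a data frame with a
#' leading/trailing reason) of the result.
#'
#' @param aln An [msa] with `ref_id` set.
#' @return The trimmed [msa] (reference excluded) with attribute
#'   `removed`.
#' @export
trim_to_reference <- function(aln) {
  ref_id <- attr(aln, "ref_id")
  if (is.null(ref_id)) stopf("trim_to_reference requires an msa with ref_id set")
  m <- as.matrix(aln)
  ref <- m[ref_id, ]
  span <- which(ref != "-")
  if (length(span) == 0L) stopf("reference row consists entirely of gaps")
  window <- seq(min(span), max(span))
  m <- m[setdiff(rownames(m), ref_id), window, drop = FALSE]
  rows <- apply(m, 1L, paste, collapse = "")
  leading <- grepl("^-", rows)
  trailing <- grepl("-$", rows)
  removed <- data.frame(
    id = rownames(m)[leading | trailing],
    reason = ifelse(leading[leading | trailing], "leading_gap", "trailing_gap"),
    stringsAsFactors = FALSE)
  out <- msa_from_matrix(m[!(leading | trailing), , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Remove records causing rare internal insertions
#'
#' For each alignment column the gap fraction (share of rows holding `-`)
#' is computed. Columns whose gap fraction strictly exceeds `pigl`
#' represent insertions private to a small minority: every record with a
#' residue (non-gap) in such a column is removed, in a single pass over
#' the union of offending columns; columns left entirely gapped are then
#' deleted. With `pigl = 0` the alignment is returned unchanged (internal
#' gaps are not removed).
#'
#' @param aln An [msa] (typically the output of [trim_to_reference()]).
#' @param pigl Gap-fraction threshold in `[0, 1]`; see [trim_config()].
#' @return The filtered [msa] with attributes `removed` (character ids)
#'   and `trigger_columns` (1-based offending column indices).
#' @export
resolve_internal_gaps <- function(aln, pigl = 0.95) {
  if (!is.numeric(pigl) || pigl < 0 || pigl > 1)
    stopf("pigl must be in [0, 1]")
  if (pigl == 0) {
    attr(aln, "removed") <- character()
    attr(aln, "trigger_columns") <- integer()
    return(aln)
  }
  if (length(aln) == 0L) stopf("empty alignment")
  m <- as.matrix(aln)
  carriers <- character()
  bad_cols <- integer()
  # removing one insertion's carriers can push other columns over the
  # threshold, so iterate to the fixpoint; column indices stay in input
  # coordinates because columns are only deleted at the end
  repeat {
    if (nrow(m) == 0L) break
    gap_frac <- colMeans(m == "-")
    bad <- which(gap_frac > pigl)
    bad <- setdiff(bad, bad_cols)
    hit <- if (length(bad))
      rownames(m)[rowSums(m[, bad, drop = FALSE] != "-") > 0L]
    else character()
    bad_cols <- sort(union(bad_cols, bad))
    if (length(hit) == 0L) break
    carriers <- c(carriers, hit)
    m <- m[setdiff(rownames(m), hit), , drop = FALSE]
  }
  if (nrow(m) > 0L) {
    all_gap <- colSums(m != "-") == 0L
    m <- m[, !all_gap, drop = FALSE]
  }
  out <- msa_from_matrix(m)
  attr(out, "removed") <- carriers
  attr(out, "trigger_columns") <- as.integer(bad_cols)
  out
}

#' Align and trim every FASTA in a folder
#'
#' Applies the full alignment stage to each FASTA file found in `folder`:
#' MAFFT alignment against the single reference sequence (raw alignment
#' written to `MAFFT/<name>_MAFFT.fas`), trimming to the reference extent
#' with removal of records lacking full coverage, and internal-gap
#' resolution at the configured `pigl` (result written to
#' `MAFFT_trimmed/<name>_MAFFT_trimmed.fas`). Per-file removal counts are
#' appended to `MAFFT_log.txt`. A failure on one file is logged and does
#' not abort the batch.
#'
#' @param folder Directory containing the FASTA files (`.fas`, `.fasta`,
#'   `.fa`).
#' @param ref_fasta Single-sequence reference FASTA.
#' @param config A [trim_config()].
#' @param mafft Path to the MAFFT executable.
#' @param output Output root; defaults to `folder`.
#' @param verbose Emit per-file messages.
#' @return Invisibly, a data frame report: file, sequences in, removed by
#'   coverage, removed by the gap rule, final width, status.
#' @export
align_and_trim_folder <- function(folder, ref_fasta, config = trim_config(),
                                  mafft = Sys.which("mafft"), output = NULL,
                                  verbose = TRUE) {
  files <- list.files(folder, pattern = "\\.(fas|fasta|fa)$",
                      full.names = TRUE)
  files <- files[normalizePath(files) !=
                   normalizePath(ref_fasta, mustWork = FALSE)]
  if (length(files) == 0L) stopf("no FASTA files found in %s", folder)
  output <- output %||% folder
  dir_raw <- file.path(output, "MAFFT")
  dir_trim <- file.path(output, "MAFFT_trimmed")
  dir.create(dir_raw, recursive = TRUE, showWarnings = FALSE)
  dir.create(dir_trim, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output, "MAFFT_log.txt")
  report <- list()
  for (f in files) {
    base <- sub("\\.(fas|fasta|fa)$", "", basename(f))
    res <- tryCatch({
      aln <- invoke_aligner(f, ref_fasta, op = config$op, mafft = mafft,
                            out_path = file.path(dir_raw,
                                                 paste0(base, "_MAFFT.fas")))
      n_in <- length(aln) - 1L  # reference excluded
      trimmed <- trim_to_reference(aln)
      cov_removed <- attr(trimmed, "removed")
      final <- resolve_internal_gaps(trimmed, pigl = config$pigl)
      gap_removed <- attr(final, "removed")
      write_fasta(final, file.path(dir_trim, paste0(base, "_MAFFT_trimmed.fas")))
      line <- sprintf(
        "%s\tin=%d\tremoved_coverage=%d\tremoved_gap_rule=%d\ttrigger_columns=%s\twidth=%d",
        basename(f), n_in, nrow(cov_removed), length(gap_removed),
        if (length(attr(final, "trigger_columns")))
          paste(attr(final, "trigger_columns"), collapse = ",") else "-",
        msa_width(final))
      cat(line, "\n", sep = "", file = log_path, append = TRUE)
      bc_log(paste0("[align-trim] ", line), verbose = verbose)
      data.frame(file = basename(f), n_in = n_in,
                 removed_coverage = nrow(cov_removed),
                 removed_gap_rule = length(gap_removed),
                 width = msa_width(final), status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      cat(sprintf("%s\tFAILED\t%s\n", basename(f), conditionMessage(e)),
          file = log_path, append = TRUE)
      bc_log(sprintf("[align-trim] %s failed: %s", basename(f),
                     conditionMessage(e)), verbose = verbose)
      data.frame(file = basename(f), n_in = NA_integer_,
                 removed_coverage = NA_integer_,
                 removed_gap_rule = NA_integer_, width = NA_integer_,
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
    report[[length(report) + 1L]] <- res
  }
  invisible(do.call(rbind, report))
}
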