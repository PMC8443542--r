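GENBANK_QUERY_TEMPLATE <- paste0(
  "(%s[ORGN]) NOT (shotgun[ALL] OR genome[ALL] OR assembled[ALL] ",
  "OR microsatellite[ALL])")

#' Build the GenBank nucleotide search query for a genus
#'
#' With `custom = NULL` the default template is used:
#' `(genus[ORGN]) NOT (shotgun[ALL] OR genome[ALL] OR assembled[ALL] OR
#' microsatellite[ALL])`, which excludes genome-scale and microsatellite
#' records. A custom search string is returned verbatim and is only valid
#' when a single genus is queued.
#'
#' @param genus Genus name (required when `custom` is `NULL`).
#' @param custom Optional full query string overriding the template.
#' @param n_queued Number of genera queued in the surrounding run; a custom
#'   string with more than one genus is an error.
#' @return The query string.
#' @examples
#' build_genbank_query("Neotamias")
#' @export
build_genbank_query <- function(genus, custom = NULL, n_queued = 1L) {
  if (!is.null(custom)) {
    if (n_queued > 1L)
      stopf("custom search string: only a single genus at a time can be searched")
    return(custom)
  }
  if (is.null(genus) || is_blank(genus))
    stopf("genus must be non-empty when no custom search string is given")
  sprintf(GENBANK_QUERY_TEMPLATE, genus)
}

with_retries <- function(fn, what, retries = 3L, retry_delay = 0.5) {
  for (attempt in seq_len(retries)) {
    res <- tryCatch(list(ok = TRUE, value = fn()),
                    error = function(e) list(ok = FALSE, error = e))
    if (res$ok) return(res$value)
    if (attempt < retries) Sys.sleep(retry_delay * 2^(attempt - 1L))
  }
  stopf("%s failed after %d attempts: %s", what, retries,
        conditionMessage(res$error))
}

#' Fetch GenBank-style records for a genus
#'
#' Runs `query` through the supplied transport (live HTTP or fixture
#' replay), paginating until exhaustion, and returns the raw record maps.
#' The transport is a list with two functions: `search(query, retstart,
#' retmax)` returning a character vector of record identifiers, and
#' `fetch(ids)` returning a list of named-list record maps (fields
#' `accession`, `organism`, `gene`/`product`/`definition`, `sequence`).
#'
#' @param genus Genus name (carried into error messages).
#' @param query Search string, see [build_genbank_query()].
#' @param transport Transport list, e.g. [fixture_genbank_transport()].
#' @param page_size Records per pagination step.
#' @param retries Attempts per transport call before giving up.
#' @param retry_delay Base delay (seconds) for exponential backoff.
#' @return List of record maps (possibly empty).
#' @export
fetch_genbank <- function(genus, query, transport, page_size = 100L,
                          retries = 3L, retry_delay = 0.5) {
  ids <- character()
  offset <- 0L
  repeat {
    page <- with_retries(
      function() transport$search(query, retstart = offset, retmax = page_size),
      what = sprintf("GenBank search for genus '%s' (query: %s)", genus, query),
      retries = retries, retry_delay = retry_delay)
    ids <- c(ids, page)
    if (length(page) < page_size) break
    offset <- offset + length(page)
  }
  if (length(ids) == 0L) return(list())
  out <- list()
  for (start in seq(1L, length(ids), by = page_size)) {
    chunk <- ids[start:min(start + page_size - 1L, length(ids))]
    recs <- with_retries(
      function() transport$fetch(chunk),
      what = sprintf("GenBank fetch for genus '%s'", genus),
      retries = retries, retry_delay = retry_delay)
    out <- c(out, recs)
  }
  out
}

#' Fetch BOLD-style records for a genus
#'
#' Retrieves the genus' specimen+sequence TSV through the transport (a list
#' with a single function `specimens(genus)` returning the TSV text),
#' parses it into record maps and keeps the verbatim TSV so callers can
#' persist the raw download. Expected columns include `processid`,
#' `species_name` (or `organism`), `markercode` (or `marker`) and
#' `nucleotides` (or `seq`).
#'
#' @inheritParams fetch_genbank
#' @param transport Transport list, e.g. [fixture_bold_transport()].
#' @return List with elements `records` (list of record maps) and `raw`
#'   (the TSV text, one element per line).
#' @export
fetch_bold <- function(genus, transport, retries = 3L, retry_delay = 0.5) {
  tsv <- with_retries(function() transport$specimens(genus),
                      what = sprintf("BOLD download for genus '%s'", genus),
                      retries = retries, retry_delay = retry_delay)
  lines <- if (length(tsv) == 1L) strsplit(tsv, "\n", fixed = TRUE)[[1L]] else tsv
  lines <- sub("\r$", "", lines)
  lines <- lines[!(seq_along(lines) == length(lines) & !nzchar(lines))]
  if (length(lines) == 0L)
    return(list(records = list(), raw = character()))
  header <- split_tsv_line(lines[[1L]])
  rows <- lapply(lines[-1L], split_tsv_line)
  n_fields <- lengths(rows)
  bad <- which(n_fields != length(header))
  if (length(bad))
    stopf("BOLD TSV for genus '%s': row %d has %d fields (expected %d)",
          genus, bad[[1L]], n_fields[bad[[1L]]], length(header))
  records <- lapply(rows, function(r) as.list(setNames(r, header)))
  list(records = records, raw = lines)
}

#' Summarize a download run per genus
#'
#' Tallies, for each genus in the table, the unique species seen (sorted),
#' the record counts per normalized marker name and the record counts per
#' source database. Counts always sum to the number of records in the
#' table.
#'
#' @param table A [total_table()].
#' @return A named list (class `download_summary`), one element per genus,
#'   each with `species`, `markers` and `sources`.
#' @export
summarize_download <- function(table) {
  genera <- unique(table$genus)
  out <- lapply(genera, function(g) {
    sub <- table[table$genus == g, , drop = FALSE]
    sp <- sort(unique(sub$species[nzchar(sub$species)]))
    markers <- table(factor(ifelse(nzchar(sub$marker_norm),
                                   sub$marker_norm, "(no marker)")))
    sources <- table(factor(sub$source_db))
    list(species = sp,
         markers = setNames(as.integer(markers), names(markers)),
         sources = setNames(as.integer(sources), names(sources)),
         n_records = nrow(sub))
  })
  structure(setNames(out, genera), class = "download_summary")
}

#' @rdname summarize_download
#' @param summary A `download_summary`.
#' @param path Output file.
#' @export
write_download_summary <- function(summary, path) {
  lines <- character()
  for (g in names(summary)) {
    s <- summary[[g]]
    lines <- c(lines,
               sprintf("Genus: %s (%d records)", g, s$n_records),
               sprintf("  Species (%d): %s", length(s$species),
                       paste(s$species, collapse = ", ")),
               "  Markers:",
               sprintf("    %s\t%d", names(s$markers), s$markers),
               "  Sources:",
               sprintf("    %s\t%d", names(s$sources), s$sources),
               "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a genus list file
#'
#' One genus per line; blank lines (including the conventional trailing
#' empty line) are dropped and surrounding whitespace trimmed.
#'
#' @param path File path.
#' @return Character vector of genus names.
#' @export
read_genus_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Download and accumulate records for a list of genera
#'
#' Orchestrates the acquisition stage: for each genus, fetches records from
#' BOLD and/or GenBank through the supplied transports, persists the raw
#' per-genus downloads under `BOLD/` and `NCBI/`, harmonizes and
#' dereplicates all records (duplicate accessions collapse to their first
#' occurrence) and writes `Total_tables/A_Summary.txt` and
#' `Total_tables/A_Total_Table.dat` inside the run folder.
#'
#' @param genera Character vector of genus names (see [read_genus_list()]).
#' @param output_dir Directory under which the run folder is created.
#' @param bold,ncbi Include the respective source (at least one must be
#'   `TRUE`).
#' @param search_str Optional custom GenBank search string; only valid with
#'   a single genus.
#' @param bold_transport,genbank_transport Transports (fixture or live);
#'   see [fixture_bold_transport()], [fixture_genbank_transport()],
#'   [live_bold_transport()], [live_genbank_transport()].
#' @param run_name Name of the run folder; defaults to the timestamped
#'   `Seq_auto_dl_<HHMMSS_Mon_dd>` pattern (pass a fixed name for
#'   reproducible layouts).
#' @param retries,retry_delay,page_size Transport politeness settings.
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with `table` (the [total_table()]), `summary`
#'   and `run_dir`.
#' @export
download_sequences <- function(genera, output_dir,
                               bold = TRUE, ncbi = TRUE, search_str = NULL,
                               bold_transport = live_bold_transport(),
                               genbank_transport = live_genbank_transport(),
                               run_name = NULL, retries = 3L,
                               retry_delay = 0.5, page_size = 100L,
                               verbose = TRUE) {
  if (!bold && !ncbi)
    stopf("at least one of bold/ncbi must be TRUE")
  if (!is.null(search_str) && length(genera) > 1L)
    stopf("custom search string: only a single genus at a time can be searched")
  if (length(genera) == 0L) stopf("empty genus list")
  run_name <- run_name %||%
    format(Sys.time(), "Seq_auto_dl_%H%M%S_%b_%d")
  run_dir <- file.path(output_dir, run_name)
  for (d in c("BOLD", "NCBI", "Total_tables"))
    dir.create(file.path(run_dir, d), recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (genus in genera) {
    if (bold) {
      bc_log(sprintf("[download] BOLD: %s", genus), verbose = verbose)
      res <- fetch_bold(genus, bold_transport, retries = retries,
                        retry_delay = retry_delay)
      writeLines(res$raw, file.path(run_dir, "BOLD", paste0(genus, ".tsv")),
                 useBytes = TRUE)
      rows <- c(rows, lapply(res$records, harmonize_record, source = "BOLD"))
    }
    if (ncbi) {
      query <- build_genbank_query(genus, custom = search_str,
                                   n_queued = length(genera))
      bc_log(sprintf("[download] GenBank: %s", genus), verbose = verbose)
      recs <- fetch_genbank(genus, query, genbank_transport,
                            page_size = page_size, retries = retries,
                            retry_delay = retry_delay)
      con <- file.path(run_dir, "NCBI", paste0(genus, ".tsv"))
      writeLines(vapply(recs, function(r)
        paste(r$accession %||% "", r$organism %||% "", r$gene %||% "",
              r$product %||% "", r$definition %||% "", r$sequence %||% "",
              sep = "\t"), character(1L)), con, useBytes = TRUE)
      rows <- c(rows, lapply(recs, harmonize_record, source = "NCBI"))
    }
  }
  table <- total_table(if (length(rows)) do.call(rbind, rows) else NULL,
                       provenance = list(
                         genera = genera,
                         genbank_query = if (ncbi) vapply(
                           genera, build_genbank_query, character(1L),
                           custom = search_str,
                           n_queued = length(genera)) else NULL))
  table <- dereplicate_records(table)
  summary <- summarize_download(table)
  write_total_table(table, file.path(run_dir, "Total_tables",
                                     "A_Total_Table.dat"))
  write_download_summary(summary, file.path(run_dir, "Total_tables",
                                            "A_Summary.txt"))
  invisible(list(table = table, summary = summary, run_dir = run_dir))
}
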