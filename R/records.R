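RECORD_FLAGS <- c("no_marker", "no_taxa", "no_seq",
                  "name_issue", "taxa_digits", "taxa_punct")

TOTAL_TABLE_COLUMNS <- c("uid", "accession", "source_db", "genus", "species",
                         "marker_raw", "marker_norm", "sequence", "flags")

#' Quality flags for a harmonized record
#'
#' Computes the set of quality flags gating a record's inclusion in FASTA
#' assembly. The six flags mirror the inclusion toggles of
#' [assemble_fasta_groups()]:
#'
#' * `no_marker` — marker name empty after trimming whitespace;
#' * `no_taxa` — genus or species empty (a binomial is required downstream);
#' * `no_seq` — empty sequence;
#' * `name_issue` — the combined name "genus species" has more than two
#'   whitespace-separated terms (e.g. "Neotamias sp. 3");
#' * `taxa_digits` — genus or species contains a decimal digit;
#' * `taxa_punct` — genus or species contains punctuation, i.e. any
#'   character that is not a letter, digit or whitespace (hyphens count).
#'
#' @param genus,species,marker_raw,sequence Character scalars (may be empty).
#' @return Character vector of flags carried (possibly empty), in canonical
#'   order.
#' @examples
#' flag_record("Neotamias", "minimus", "COI-5P", "ACGT")   # none
#' flag_record("Neotamias", "sp. 3", "COI-5P", "ACGT")
#' @export
flag_record <- function(genus, species, marker_raw, sequence) {
  genus <- trimws(genus %||% "")
  species <- trimws(species %||% "")
  taxa <- paste(genus, species)
  n_terms <- length(strsplit(trimws(taxa), "[[:space:]]+")[[1L]])
  flags <- c(
    no_marker   = is_blank(marker_raw %||% ""),
    no_taxa     = !nzchar(genus) || !nzchar(species),
    no_seq      = is_blank(sequence %||% ""),
    name_issue  = n_terms > 2L,
    taxa_digits = grepl("[0-9]", taxa),
    taxa_punct  = grepl("[^[:alnum:][:space:]]", taxa)
  )
  RECORD_FLAGS[flags[RECORD_FLAGS]]
}

flags_to_string <- function(flags) {
  if (length(flags) == 0L) "-" else paste(flags, collapse = ";")
}

flags_from_string <- function(s) {
  if (identical(s, "-") || !nzchar(s)) character() else
    strsplit(s, ";", fixed = TRUE)[[1L]]
}

#' Harmonize a source-specific record into the unified row shape
#'
#' Converts one raw record map from a BOLD- or GenBank-style source into the
#' unified record used by the total table. The organism string is split on
#' whitespace: first term becomes the genus, the remainder (verbatim) the
#' species; a one-term organism yields an empty species (and hence the
#' `no_taxa` flag). The marker name is copied verbatim into `marker_raw`
#' and normalized into `marker_norm` (see [normalize_marker_name()]); flags
#' are computed with [flag_record()].
#'
#' @param raw Named list with the source's fields. BOLD-style sources use
#'   `processid`, `organism` (or `species_name`), `marker` (or
#'   `markercode`), `seq` (or `nucleotides`). GenBank-style sources use
#'   `accession`, `organism`, one of the marker fields (see
#'   `marker_preference`) and `sequence` (or `seq`).
#' @param source `"BOLD"` or `"NCBI"`.
#' @param marker_preference For GenBank-style records, the order in which
#'   the `gene`, `product` and `definition` fields are consulted for the
#'   marker name (first non-empty wins).
#' @return One-row data frame with the total-table columns.
#' @export
harmonize_record <- function(raw, source = c("BOLD", "NCBI"),
                             marker_preference = c("gene", "product", "definition")) {
  source <- match.arg(source)
  get <- function(...) {
    for (f in c(...)) {
      v <- raw[[f]]
      if (!is.null(v) && !is.na(v)) return(as.character(v))
    }
    ""
  }
  if (source == "BOLD") {
    id_field <- "processid"
    accession <- get("processid")
    organism <- get("organism", "species_name")
    marker <- get("marker", "markercode")
    sequence <- get("seq", "nucleotides", "sequence")
  } else {
    id_field <- "accession"
    accession <- get("accession")
    organism <- get("organism")
    marker <- ""
    for (f in marker_preference) {
      marker <- get(f)
      if (nzchar(trimws(marker))) break
    }
    sequence <- get("sequence", "seq")
  }
  if (!nzchar(accession))
    stopf("malformed record: missing identifier field '%s'", id_field)
  terms <- strsplit(trimws(organism), "[[:space:]]+")[[1L]]
  genus <- if (length(terms) >= 1L) terms[[1L]] else ""
  species <- if (length(terms) >= 2L)
    paste(terms[-1L], collapse = " ") else ""
  unified_row(uid = paste(source, accession, sep = ":"),
              accession = accession, source_db = source, genus = genus,
              species = species, marker_raw = marker, sequence = sequence)
}

unified_row <- function(uid, accession, source_db, genus, species,
                        marker_raw, sequence) {
  marker_raw <- trimws(marker_raw)
  data.frame(
    uid = uid, accession = accession, source_db = source_db,
    genus = genus, species = species, marker_raw = marker_raw,
    marker_norm = if (is_blank(marker_raw)) "" else
      normalize_marker_name(marker_raw),
    sequence = gsub("[[:space:]]", "", sequence),
    flags = flags_to_string(flag_record(genus, species, marker_raw, sequence)),
    stringsAsFactors = FALSE
  )
}

#' Total table of harmonized records
#'
#' Binds harmonized record rows into the "total table": the single table
#' accumulating every record downloaded for all genera searched. The
#' constructor recomputes `marker_norm` and `flags` from the other fields,
#' so those two columns are always consistent with the normalization and
#' flagging rules, and checks `uid` uniqueness.
#'
#' @param records Data frame with at least the columns `uid`, `accession`,
#'   `source_db`, `genus`, `species`, `marker_raw`, `sequence` (e.g. rows
#'   from [harmonize_record()]).
#' @param provenance Named list of per-source fetch metadata (query string,
#'   timestamp); carried as an attribute.
#' @return A data frame of class `total_table`.
#' @export
total_table <- function(records = NULL, provenance = list()) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(
      setNames(rep(list(character()), length(TOTAL_TABLE_COLUMNS)),
               TOTAL_TABLE_COLUMNS), stringsAsFactors = FALSE)
  } else {
    records <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
      unified_row(uid = records$uid[i], accession = records$accession[i],
                  source_db = records$source_db[i], genus = records$genus[i],
                  species = records$species[i],
                  marker_raw = records$marker_raw[i],
                  sequence = records$sequence[i])))
  }
  if (anyDuplicated(records$uid))
    stopf("duplicate uid in total table: %s",
          paste(unique(records$uid[duplicated(records$uid)]), collapse = ", "))
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("total_table", "data.frame"))
}

#' Collapse duplicate records across sources
#'
#' Records identical in `accession` are collapsed to the first occurrence
#' (table order, i.e. the first source fetched wins); all other records are
#' kept.
#'
#' @param table A [total_table()].
#' @return A [total_table()] without duplicated accessions.
#' @export
dereplicate_records <- function(table) {
  keep <- !duplicated(table$accession)
  total_table(table[keep, , drop = FALSE],
              provenance = attr(table, "provenance"))
}

#' Filter records by their quality flags
#'
#' A record is returned iff every flag it carries is permitted (`TRUE`) in
#' `include`; unflagged records always pass. This matches the per-flag
#' inclusion toggles: with all toggles `FALSE` (the default) only unflagged
#' records survive.
#'
#' @param table A [total_table()].
#' @param include Named logical vector with one entry per flag
#'   (`no_marker`, `no_taxa`, `no_seq`, `name_issue`, `taxa_digits`,
#'   `taxa_punct`). See [default_include()].
#' @return The subset of rows passing the filter.
#' @export
filter_records <- function(table, include = default_include()) {
  missing <- setdiff(RECORD_FLAGS, names(include))
  if (length(missing))
    stopf("include is missing entries for: %s", paste(missing, collapse = ", "))
  pass <- vapply(table$flags, function(s) {
    fl <- flags_from_string(s)
    length(fl) == 0L || all(include[fl])
  }, logical(1L), USE.NAMES = FALSE)
  table[pass, , drop = FALSE]
}

#' @rdname filter_records
#' @param ... Per-flag overrides, e.g. `default_include(no_seq = TRUE)`.
#' @export
default_include <- function(...) {
  inc <- setNames(rep(FALSE, length(RECORD_FLAGS)), RECORD_FLAGS)
  dots <- list(...)
  bad <- setdiff(names(dots), RECORD_FLAGS)
  if (length(bad)) stopf("unknown flag(s): %s", paste(bad, collapse = ", "))
  for (nm in names(dots)) inc[[nm]] <- isTRUE(dots[[nm]])
  inc
}

#' Read and write the total table
#'
#' The on-disk representation is UTF-8 tab-separated text with a fixed
#' header (`uid`, `accession`, `source_db`, `genus`, `species`,
#' `marker_raw`, `marker_norm`, `sequence`, `flags`); flags are
#' semicolon-joined with `-` for the empty set. The `.dat` extension used
#' by the pipeline outputs is plain TSV. `read_total_table()` validates the
#' header and rejects ragged rows with the offending (1-based, header
#' included) line number.
#'
#' @param table A [total_table()].
#' @param path File path.
#' @return `write_total_table()`: the path, invisibly.
#'   `read_total_table()`: a [total_table()].
#' @export
write_total_table <- function(table, path) {
  lines <- c(paste(TOTAL_TABLE_COLUMNS, collapse = "\t"),
             if (nrow(table) > 0L)
               do.call(paste, c(unname(as.list(table[TOTAL_TABLE_COLUMNS])),
                                list(sep = "\t"))))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_total_table
#' @export
read_total_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stopf("empty total table file: %s", path)
  header <- split_tsv_line(lines[[1L]])
  if (!identical(header, TOTAL_TABLE_COLUMNS))
    stopf("malformed header in %s: expected '%s'", path,
          paste(TOTAL_TABLE_COLUMNS, collapse = "\t"))
  body <- lines[-1L]
  body <- body[!(seq_along(body) == length(body) & !nzchar(body))]
  rows <- lapply(body, split_tsv_line)
  n_fields <- lengths(rows)
  bad <- which(n_fields != length(TOTAL_TABLE_COLUMNS))
  if (length(bad))
    stopf("parse error in %s: line %d has %d fields (expected %d)",
          path, bad[[1L]] + 1L, n_fields[bad[[1L]]], length(TOTAL_TABLE_COLUMNS))
  df <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(total_table())
  names(df) <- TOTAL_TABLE_COLUMNS
  total_table(df)
}
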