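#' Normalize a marker name
#'
#' Database marker names are inconsistent ("COI-5P", "cytochrome c oxidase
#' subunit I", "CytochromeOxidaseSubunit1", ...). Normalization uppercases,
#' removes all whitespace and drops every character except letters, digits
#' and hyphen, so that synonym matching is exact on a canonical form. The
#' operation is idempotent.
#'
#' @param name Marker name (non-empty after trimming).
#' @return Normalized name, e.g. `"CYTOCHROMECOXIDASESUBUNITI"`.
#' @examples
#' normalize_marker_name("Cytochrome c oxidase subunit I")
#' normalize_marker_name("COI-5P")  # fixed point
#' @export
normalize_marker_name <- function(name) {
  if (is_blank(name)) stopf("marker name is empty")
  out <- toupper(name)
  out <- gsub("[[:space:]]", "", out)
  out <- gsub("[^A-Z0-9-]", "", out)
  if (!nzchar(out))
    stopf("marker name '%s' is empty after normalization", name)
  out
}

#' Parse a genus/marker-synonym parameter file
#'
#' The parameter file is tab-separated: row one holds the target genus of
#' each column; the cells below hold that column's marker-name synonyms
#' (empty cells are skipped). Each column defines one output FASTA group:
#' the genus plus the ordered, normalized synonym set, named after the
#' first synonym.
#'
#' @param path Parameter file path.
#' @return List of marker group specs, each a list with `genus`,
#'   `synonyms` (normalized, unique, ordered) and `output_name`
#'   (`<genus>_<first synonym>`).
#' @export
parse_parameter_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) == length(lines) & !nzchar(lines))]
  if (length(lines) == 0L) stopf("empty parameter file: %s", path)
  cells <- lapply(lines, split_tsv_line)
  ncol <- max(lengths(cells))
  grid <- vapply(cells, function(r) c(r, rep("", ncol - length(r))),
                 character(ncol))
  grid <- matrix(grid, nrow = ncol)  # columns of the file are rows here
  specs <- list()
  for (j in seq_len(ncol)) {
    genus <- trimws(grid[j, 1L])
    syn_cells <- trimws(grid[j, -1L])
    syn_cells <- syn_cells[nzchar(syn_cells)]
    if (!nzchar(genus)) {
      if (length(syn_cells))
        stopf("parameter file column %d has marker names but no genus", j)
      next
    }
    if (length(syn_cells) == 0L)
      stopf("parameter file column %d (%s) has a genus but no marker names",
            j, genus)
    syn <- vapply(syn_cells, normalize_marker_name, character(1L),
                  USE.NAMES = FALSE)
    if (anyDuplicated(syn)) {
      warning(sprintf("column %d (%s): duplicate synonyms after normalization",
                      j, genus), call. = FALSE)
      syn <- unique(syn)
    }
    specs[[length(specs) + 1L]] <- list(
      genus = genus, synonyms = syn,
      output_name = paste(genus, syn[[1L]], sep = "_"))
  }
  if (length(specs) == 0L) stopf("parameter file has no usable columns: %s", path)
  specs
}

#' Assemble genus-by-marker FASTA files
#'
#' For each marker group spec, records passing the flag filter whose genus
#' matches and whose normalized marker name is one of the spec's synonyms
#' are written to `<genus>_<first synonym>.fas`. FASTA headers carry
#' `uid|accession|genus|species|marker_norm` so taxonomy stays recoverable
#' downstream. Specs matching zero records produce no file (a message is
#' emitted); specs of the same genus sharing a synonym cause a warning
#' because their records are duplicated across files.
#'
#' @param table A [total_table()].
#' @param specs Marker group specs from [parse_parameter_file()].
#' @param include Flag-inclusion map, see [default_include()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit per-spec messages.
#' @return Invisibly, the character vector of written file paths.
#' @export
assemble_fasta_groups <- function(table, specs, include = default_include(),
                                  out_dir = ".", verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  kept <- filter_records(table, include)
  # warn when two specs for one genus share a synonym (records land in both)
  key <- split(specs, vapply(specs, `[[`, character(1L), "genus"))
  for (g in names(key)) {
    syns <- unlist(lapply(key[[g]], `[[`, "synonyms"))
    dup <- unique(syns[duplicated(syns)])
    if (length(dup))
      warning(sprintf("genus %s: synonym(s) %s appear in more than one column; matching records will be written to multiple files",
                      g, paste(dup, collapse = ", ")), call. = FALSE)
  }
  written <- character()
  for (spec in specs) {
    sel <- kept[kept$genus == spec$genus &
                  kept$marker_norm %in% spec$synonyms, , drop = FALSE]
    if (nrow(sel) == 0L) {
      bc_log(sprintf("[make-fastas] %s: no matching records, no file written",
                     spec$output_name), verbose = verbose)
      next
    }
    seqs <- sel$sequence
    names(seqs) <- paste(sel$uid, sel$accession, sel$genus, sel$species,
                         sel$marker_norm, sep = "|")
    path <- file.path(out_dir, paste0(spec$output_name, ".fas"))
    write_fasta(seqs, path)
    bc_log(sprintf("[make-fastas] %s: %d record(s)", spec$output_name,
                   nrow(sel)), verbose = verbose)
    written <- c(written, path)
  }
  invisible(written)
}

# split a pipeline FASTA header (uid|accession|genus|species|marker_norm)
# into taxonomy fields; headers without enough fields get empty taxonomy
header_taxonomy <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(
    id = ids,
    genus = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "",
                   character(1L)),
    species = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "",
                     character(1L)),
    stringsAsFactors = FALSE)
}
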