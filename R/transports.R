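#' Offline (fixture) transports
#'
#' Transports that replay in-memory records, making the full acquisition
#' stage testable with no network access. `fixture_genbank_transport()`
#' wraps a list of record maps behind the `search`/`fetch` interface used
#' by [fetch_genbank()] (with genuine pagination so pagination logic is
#' exercised); `fixture_bold_transport()` serves canned TSV text per genus
#' to [fetch_bold()].
#'
#' @param records List of record maps (each a named list with at least
#'   `accession`).
#' @return A transport list.
#' @export
fixture_genbank_transport <- function(records) {
  ids <- vapply(records, function(r) as.character(r$accession), character(1L))
  list(
    search = function(query, retstart = 0L, retmax = 100L) {
      if (retstart >= length(ids)) return(character())
      ids[(retstart + 1L):min(retstart + retmax, length(ids))]
    },
    fetch = function(wanted) records[match(wanted, ids)]
  )
}

#' @rdname fixture_genbank_transport
#' @param tsv_by_genus Named list/character vector: genus -> TSV text
#'   (single string or vector of lines). Genera absent from the list yield
#'   a header-only response.
#' @param header Header used for genera without canned data.
#' @export
fixture_bold_transport <- function(tsv_by_genus = list(),
                                   header = "processid\tspecies_name\tmarkercode\tnucleotides") {
  list(specimens = function(genus) {
    if (genus %in% names(tsv_by_genus)) tsv_by_genus[[genus]] else header
  })
}

#' @rdname fixture_genbank_transport
#' @param fail_with Error message the failing transport raises on every
#'   call (for exercising retry/error paths).
#' @export
failing_transport <- function(fail_with = "simulated transport failure") {
  fail <- function(...) stop(fail_with, call. = FALSE)
  list(search = fail, fetch = fail, specimens = fail)
}

read_url_lines <- function(url) {
  con <- url(url, open = "rb")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

#' Live HTTP transports
#'
#' Minimal live transports over NCBI E-utilities and the BOLD public data
#' API, built on base R connections. They satisfy the same interfaces as
#' the fixture transports; retry/backoff is applied by the fetch functions
#' that consume them. These require network access and are never used by
#' the test suite.
#'
#' @param base_url Endpoint root.
#' @param polite_delay Seconds to sleep before each request.
#' @return A transport list.
#' @export
live_genbank_transport <- function(
    base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils",
    polite_delay = 0.4) {
  list(
    search = function(query, retstart = 0L, retmax = 100L) {
      Sys.sleep(polite_delay)
      u <- sprintf("%s/esearch.fcgi?db=nucleotide&term=%s&retstart=%d&retmax=%d",
                   base_url, utils::URLencode(query, reserved = TRUE),
                   retstart, retmax)
      xml <- paste(read_url_lines(u), collapse = "")
      m <- regmatches(xml, gregexpr("<Id>[0-9]+</Id>", xml))[[1L]]
      gsub("</?Id>", "", m)
    },
    fetch = function(ids) {
      Sys.sleep(polite_delay)
      u <- sprintf("%s/efetch.fcgi?db=nucleotide&id=%s&rettype=docsum&retmode=text",
                   base_url, paste(ids, collapse = ","))
      # docsum text is one block per record; callers needing full features
      # should substitute their own transport
      lines <- read_url_lines(u)
      lapply(strsplit(paste(lines, collapse = "\n"), "\n\n")[[1L]], function(b)
        list(accession = sub("^.*?([A-Z]{1,2}[0-9]{5,8}).*$", "\\1", b),
             definition = b, organism = "", gene = "", product = "",
             sequence = ""))
    }
  )
}

#' @rdname live_genbank_transport
#' @export
live_bold_transport <- function(
    base_url = "https://www.boldsystems.org/index.php/API_Public/combined",
    polite_delay = 0.4) {
  list(specimens = function(genus) {
    Sys.sleep(polite_delay)
    u <- sprintf("%s?taxon=%s&format=tsv", base_url,
                 utils::URLencode(genus, reserved = TRUE))
    read_url_lines(u)
  })
}
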