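#' Multiple sequence alignment container
#'
#' A minimal container for an ordered set of equal-length gapped sequences
#' over the IUPAC nucleotide alphabet plus `-`. Sequences are stored
#' uppercase as a named character vector; the optional `ref_id` marks the
#' reference row used by [trim_to_reference()].
#'
#' @param seqs Named character vector of sequences. For an alignment all
#'   elements must have equal length; `msa()` enforces this,
#'   `sequence_set()` does not (use it for unaligned records).
#' @param ref_id Optional identifier of the reference row; must be one of
#'   `names(seqs)`.
#' @return An object of class `msa`: a named character vector with
#'   attribute `ref_id`.
#' @examples
#' aln <- msa(c(s1 = "ACGT", s2 = "AC-T"))
#' msa_width(aln)
#' @export
msa <- function(seqs, ref_id = NULL) {
  x <- sequence_set(seqs, ref_id = ref_id)
  w <- unique(nchar(x))
  if (length(x) > 0L && length(w) != 1L)
    stopf("alignment rows have unequal lengths: %s", paste(w, collapse = ", "))
  x
}

#' @rdname msa
#' @export
sequence_set <- function(seqs, ref_id = NULL) {
  ids <- names(seqs)
  seqs <- setNames(toupper(as.character(seqs)), ids)
  if (length(seqs) > 0L && (is.null(ids) || any(!nzchar(ids))))
    stopf("all sequences must be named")
  if (anyDuplicated(ids))
    stopf("duplicate sequence identifiers: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(ref_id) && !ref_id %in% ids)
    stopf("ref_id '%s' is not among the sequence identifiers", ref_id)
  structure(seqs, ref_id = ref_id, class = "msa")
}

#' @rdname msa
#' @param x An `msa` object.
#' @export
msa_width <- function(x) if (length(x) == 0L) 0L else nchar(x[[1L]])

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequence(s), width %d%s\n", length(x), msa_width(x),
              if (!is.null(attr(x, "ref_id")))
                paste0(", ref: ", attr(x, "ref_id")) else ""))
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  if (length(x) == 0L)
    return(matrix(character(), nrow = 0L, ncol = 0L))
  m <- do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

# rebuild an msa from a character matrix, preserving ref_id when asked
msa_from_matrix <- function(m, ref_id = NULL) {
  if (nrow(m) == 0L)
    return(msa(character(), ref_id = NULL))
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  msa(seqs, ref_id = ref_id)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings' FASTA reader/writer. `read_fasta()`
#' returns a named character vector (full header line as name, sequence
#' uppercased); `read_fasta_msa()` additionally checks equal lengths and
#' returns an [msa]. Sequences are written one per line (no wrapping).
#'
#' @param path File path.
#' @param ref_id Optional reference identifier to attach (see [msa]).
#' @return `read_fasta()`: named character vector. `read_fasta_msa()`: an
#'   [msa]. `write_fasta()`: the path, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' @rdname read_fasta
#' @export
read_fasta_msa <- function(path, ref_id = NULL) {
  msa(read_fasta(path), ref_id = ref_id)
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences (or an [msa]).
#' @export
write_fasta <- function(seqs, path) {
  seqs <- unclass(seqs)
  attr(seqs, "ref_id") <- NULL
  set <- Biostrings::DNAStringSet(seqs)
  width <- max(20000L, if (length(seqs)) max(nchar(seqs)) + 1L else 0L)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
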