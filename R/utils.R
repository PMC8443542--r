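`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
bc_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# strsplit() drops trailing empty fields; pad with a sentinel so ragged-row
# detection and empty trailing cells (common in parameter files) survive.
split_tsv_line <- function(line) {
  parts <- strsplit(paste0(line, "\x1f"), "\t", fixed = TRUE)[[1]]
  n <- length(parts)
  parts[n] <- sub("\x1f$", "", parts[n])
  parts
}

is_blank <- function(x) !nzchar(trimws(x))

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
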