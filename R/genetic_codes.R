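#' Genetic code tables for stop-codon screening
#'
#' Returns a 64-entry codon-to-amino-acid map (stop codons as `"*"`) for
#' the three codes used in barcode screening: `"std"` (standard nuclear
#' code; stops TAA, TAG, TGA), `"vert"` (vertebrate mitochondrial; stops
#' TAA, TAG, AGA, AGG, with TGA read as Trp) and `"invert"` (invertebrate
#' mitochondrial; stops TAA, TAG only, with TGA as Trp and AGA/AGG as
#' Ser). Tables come from Biostrings' NCBI translation tables (ids 1, 2
#' and 5).
#'
#' @param code One of `"std"`, `"vert"`, `"invert"`.
#' @return Named character vector of length 64 with attribute `code_name`.
#' @export
genetic_code <- function(code = c("invert", "vert", "std")) {
  code <- match.arg(code)
  id <- switch(code, std = "1", vert = "2", invert = "5")
  tab <- Biostrings::getGeneticCode(id)
  structure(setNames(as.character(tab), names(tab)), code_name = code)
}
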