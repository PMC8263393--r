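## The four alanine codons.
.ala_codons <- c("GCA", "GCC", "GCG", "GCT")

#' Measure a polyalanine tract and its expansion relative to a reference
#'
#' Locates the tract by an exact-match flanking anchor, then counts the
#' maximal run of consecutive alanine codons (GCA/GCC/GCG/GCT, in the frame
#' fixed by the anchor end) starting immediately after the anchor.
#' Synonymous codon mixtures within the tract are allowed and do not change
#' the count.  The expansion is reported as
#' \code{delta = observed_ala - reference_ala}; a pathogenic polyalanine
#' expansion in a transcription-factor tract (e.g. HOXD13) shows a positive
#' delta.
#'
#' @param seq nucleotide string of the allele (consensus/assembled, not
#'   raw reads).
#' @param anchor flanking sequence immediately 5' of the tract; must occur
#'   exactly once in \code{seq}.
#' @param reference_ala alanine-codon count of the reference tract
#'   (required; there is no built-in constant).
#' @return list with \code{observed_ala}, \code{reference_ala},
#'   \code{delta}.
#' @export
#' @examples
#' allele <- paste0("TTGACG", strrep("GCG", 15), "CACTAA")
#' polyalanine_tract_length(allele, "TTGACG", reference_ala = 15)
polyalanine_tract_length <- function(seq, anchor, reference_ala) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(anchor) >= 1)
  if (missing(reference_ala) || is.na(reference_ala))
    stop("reference_ala is required")
  seq <- toupper(gsub("\\s", "", seq))
  anchor <- toupper(anchor)
  hits <- gregexpr(anchor, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) stop("anchor not found in sequence")
  if (length(hits) > 1L) stop("anchor is ambiguous (", length(hits), " occurrences)")
  at <- hits[1] + nchar(anchor)
  observed <- 0L
  while (at + 2L <= nchar(seq)) {
    codon <- substr(seq, at, at + 2L)
    if (!codon %in% .ala_codons) break
    observed <- observed + 1L
    at <- at + 3L
  }
  list(observed_ala = observed,
       reference_ala = as.integer(reference_ala),
       delta = observed - as.integer(reference_ala))
}
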