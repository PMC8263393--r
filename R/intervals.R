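#' Construct a GRanges interval set
#'
#' Thin convenience wrapper used throughout the package and its tests to
#' build interval sets in the 1-based closed convention.
#'
#' @param chrom character vector of chromosome names (recycled).
#' @param start,end integer vectors, 1-based closed.
#' @param ... further per-interval metadata columns.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
#' @examples
#' gintervals("chr1", c(101, 501), c(200, 520))
gintervals <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end), ...)
}

#' Total base pairs covered by an interval set
#'
#' Intervals are merged (reduced) first, so overlapping input intervals are
#' not double counted.
#'
#' @param gr A \code{GRanges}.
#' @return Integer number of covered base pairs.
#' @export
total_bp <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr))))
}

## Internal: drop metadata and strand so set algebra behaves predictably.
.bare <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  GenomicRanges::strand(gr) <- "*"
  gr
}

## Internal: stop when two tracks use disjoint chromosome namespaces.
.check_chrom_namespace <- function(a, b, what_a = "first", what_b = "second") {
  ca <- GenomeInfoDb::seqlevelsInUse(a)
  cb <- GenomeInfoDb::seqlevelsInUse(b)
  if (length(ca) && length(cb) && !length(intersect(ca, cb))) {
    stop("chromosome namespaces do not overlap between ", what_a, " (",
         paste(ca, collapse = ","), ") and ", what_b, " (",
         paste(cb, collapse = ","), ")")
  }
  invisible(TRUE)
}
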