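#' Structural-variant filter settings
#'
#' @param min_size_bp minimum SV size in bp that passes filtration
#'   (size >= \code{min_size_bp} passes). Default 1500.
#' @param min_support minimum number of supporting informative reads.
#'   Default 2.
#' @param escalated_support support threshold applied when the first pass
#'   yields too many SVs. Default 5.
#' @param escalation_trigger the escalation fires when strictly more than
#'   this many SVs pass the first pass. Default 30.
#' @return list of class \code{sv_filter_config}.
#' @export
sv_filter_config <- function(min_size_bp = 1500L, min_support = 2L,
                             escalated_support = 5L, escalation_trigger = 30L) {
  stopifnot(min_size_bp > 0, escalated_support >= min_support)
  structure(list(min_size_bp = as.integer(min_size_bp),
                 min_support = as.integer(min_support),
                 escalated_support = as.integer(escalated_support),
                 escalation_trigger = as.integer(escalation_trigger)),
            class = "sv_filter_config")
}

.sv_types <- c("DEL", "DUP", "INV", "BND")

## Internal: SV size in bp under the package's 1-based closed convention.
## BND records have no defined length (NA).
.sv_size <- function(svs) {
  ifelse(svs$sv_type == "BND", NA_integer_, svs$end - svs$start + 1L)
}

#' Size/read-support SV filter with escalation
#'
#' First pass keeps SVs with size >= \code{min_size_bp} (BND records, which
#' have no defined length, are exempt from the size rule) and supporting
#' reads >= \code{min_support}.  When strictly more than
#' \code{escalation_trigger} SVs survive the first pass, the support
#' threshold is escalated to \code{escalated_support} and the filter re-run.
#' SVs carrying a \code{poor_quality} flag are always removed.
#'
#' @param svs SV data.frame for one case: \code{sv_id}, \code{sv_type},
#'   \code{chrom}, \code{start}, \code{end}, \code{support_reads}, optional
#'   logical \code{poor_quality}.
#' @param cfg \code{\link{sv_filter_config}}.
#' @return list with \code{kept} and \code{removed} data.frames (the latter
#'   with a \code{reason} column), \code{applied_support} (the support level
#'   of the final pass) and logical \code{escalated}.
#' @export
filter_svs <- function(svs, cfg = sv_filter_config()) {
  if (!"poor_quality" %in% names(svs))
    svs$poor_quality <- rep(FALSE, nrow(svs))
  pass_at <- function(support) {
    size <- .sv_size(svs)
    size_ok <- is.na(size) | size >= cfg$min_size_bp
    supp_ok <- svs$support_reads >= support
    qual_ok <- !svs$poor_quality
    reason <- rep(NA_character_, nrow(svs))
    reason[!qual_ok] <- "poor_quality"
    reason[qual_ok & !size_ok] <- "below_min_size"
    reason[qual_ok & size_ok & !supp_ok] <- "low_read_support"
    list(keep = size_ok & supp_ok & qual_ok, reason = reason)
  }
  first <- pass_at(cfg$min_support)
  escalated <- sum(first$keep) > cfg$escalation_trigger
  final <- if (escalated) pass_at(cfg$escalated_support) else first
  removed <- svs[!final$keep, , drop = FALSE]
  removed$reason <- final$reason[!final$keep]
  list(kept = svs[final$keep, , drop = FALSE], removed = removed,
       applied_support = if (escalated) cfg$escalated_support else cfg$min_support,
       escalated = escalated)
}

#' Inheritance-based SV exclusion
#'
#' Removes SVs inherited from an unaffected parent.  De novo SVs, SVs from
#' an affected parent and SVs of unknown inheritance are retained.  In
#' \code{affected_relative} mode, an SV also carried by an affected relative
#' is retained regardless of the transmitting parent's status (the
#' configuration seen when a variant segregates with disease in the wider
#' family despite an unaffected transmitting parent).
#'
#' @param svs SV data.frame with \code{inheritance} in
#'   \{\code{de_novo}, \code{maternal}, \code{paternal}, \code{unknown}\}
#'   and, for relative mode, a logical \code{carried_by_affected_relative}.
#' @param pedigree list or data.frame mapping \code{mother}/\code{father}
#'   to logical affected status, e.g.
#'   \code{list(mother_affected = FALSE, father_affected = FALSE)}.
#' @param mode \code{"standard"} or \code{"affected_relative"}.
#' @return list with \code{kept} and \code{removed} (with \code{reason}).
#' @export
inheritance_filter <- function(svs, pedigree, mode = c("standard", "affected_relative")) {
  mode <- match.arg(mode)
  need <- c("mother_affected", "father_affected")
  if (!all(need %in% names(pedigree)))
    stop("pedigree must provide mother_affected and father_affected")
  parent_unaffected <- c(maternal = !isTRUE(pedigree$mother_affected),
                         paternal = !isTRUE(pedigree$father_affected))
  inherited_unaff <- svs$inheritance %in% c("maternal", "paternal") &
    parent_unaffected[svs$inheritance]
  rescue <- rep(FALSE, nrow(svs))
  if (mode == "affected_relative" && "carried_by_affected_relative" %in% names(svs))
    rescue <- isTRUE_vec(svs$carried_by_affected_relative)
  drop <- inherited_unaff & !rescue
  removed <- svs[drop, , drop = FALSE]
  removed$reason <- rep("inherited_from_unaffected_parent", nrow(removed))
  list(kept = svs[!drop, , drop = FALSE], removed = removed)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Length of a structural variant
#'
#' @param start,end breakpoint coordinates.
#' @param sv_type one of DEL/DUP/INV (BND has no defined length and errors).
#' @param convention \code{"one_based_inclusive"} (both endpoints are part
#'   of the variant, as in printed coordinates such as
#'   chr10:103,321,526-103,426,609) or \code{"half_open"} (end exclusive).
#' @return list with \code{bp} and \code{kb_rounded} (bp/1000 rounded to the
#'   nearest integer).
#' @export
#' @examples
#' sv_length(103321526, 103426609, "INV", "one_based_inclusive")
sv_length <- function(start, end, sv_type = "DEL",
                      convention = c("one_based_inclusive", "half_open")) {
  convention <- match.arg(convention)
  if (sv_type == "BND") stop("length is undefined for BND records")
  stopifnot(end > start || (convention == "one_based_inclusive" && end >= start))
  bp <- if (convention == "half_open") end - start else end - start + 1
  list(bp = as.numeric(bp), kb_rounded = round(bp / 1000))
}

#' Count structural variants by type
#'
#' @param svs SV data.frame with an \code{sv_type} column.
#' @return named integer vector over DEL/DUP/INV/BND summing to
#'   \code{nrow(svs)}.
#' @export
classify_sv_types <- function(svs) {
  bad <- setdiff(unique(svs$sv_type), .sv_types)
  if (length(bad)) {
    offender <- svs$sv_id[match(bad[1], svs$sv_type)]
    stop("unknown sv_type '", bad[1], "' in record ", offender)
  }
  counts <- table(factor(svs$sv_type, levels = .sv_types))
  setNames(as.integer(counts), .sv_types)
}

#' Annotate one SV against genome tracks
#'
#' Flags computed: limb genes and enhancer elements overlapped by the SV
#' span; base pairs of regulome mask overlapped; whether the SV disrupts a
#' TAD boundary (its span contains a boundary between adjacent TADs, or its
#' two breakpoints fall in different TADs); and copy-number neutrality
#' (inversions and breakend records do not change dosage).
#'
#' @param sv one-row SV data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{sv_type}).
#' @param tads,genes,enhancers \code{GRanges} tracks (genes with
#'   \code{gene_id} and \code{limb_flag}; enhancers with \code{id}).
#' @param mask optional \code{regulome_mask}.
#' @return list of annotation flags.
#' @export
annotate_sv <- function(sv, tads, genes, enhancers = NULL, mask = NULL) {
  span <- gintervals(sv$chrom, sv$start, sv$end)
  limb_genes <- character(0)
  if (!is.null(genes) && length(genes)) {
    hit <- IRanges::subsetByOverlaps(genes[genes$limb_flag], span, ignore.strand = TRUE)
    limb_genes <- sort(hit$gene_id)
  }
  enh_hits <- character(0)
  if (!is.null(enhancers) && length(enhancers)) {
    hit <- IRanges::subsetByOverlaps(enhancers, span, ignore.strand = TRUE)
    enh_hits <- sort(if (is.null(hit$id)) as.character(seq_along(hit)) else hit$id)
  }
  mask_bp <- 0
  if (!is.null(mask)) {
    sites <- if (inherits(mask, "regulome_mask")) mask$sites else mask
    mask_bp <- total_bp(GenomicRanges::intersect(span, .bare(sites), ignore.strand = TRUE))
  }
  boundary <- FALSE
  if (!is.null(tads) && length(tads)) {
    bp1 <- gintervals(sv$chrom, sv$start, sv$start)
    bp2 <- gintervals(sv$chrom, sv$end, sv$end)
    t1 <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(bp1, tads, ignore.strand = TRUE))
    t2 <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(bp2, tads, ignore.strand = TRUE))
    different_tads <- length(t1) && length(t2) && !length(intersect(t1, t2))
    ## a boundary between adjacent TADs is the junction point where one TAD
    ## ends and the next begins strictly inside the SV span
    tt <- sort(tads[GenomicRanges::seqnames(tads) == sv$chrom])
    contains_boundary <- FALSE
    if (length(tt) >= 2) {
      ends <- GenomicRanges::end(tt)[-length(tt)]
      starts <- GenomicRanges::start(tt)[-1]
      junction <- (ends + starts) / 2
      contains_boundary <- any(junction > sv$start & junction < sv$end)
    }
    boundary <- different_tads || contains_boundary
  }
  list(limb_genes = limb_genes,
       enhancers = enh_hits,
       regulome_overlap_bp = mask_bp,
       tad_boundary_disruption = boundary,
       copy_number_neutral = sv$sv_type %in% c("INV", "BND"))
}
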