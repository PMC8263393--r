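#' Regulome construction settings
#'
#' @param phylop_threshold conservation score above which (strictly) a
#'   position counts as conserved. Default 1.3, the phyloP cutoff commonly
#'   used to call a base evolutionarily constrained.
#' @param include_vista include validated enhancer elements in the mask.
#' @param vista_tissue_filter optional tissue label (e.g. \code{"limb"});
#'   when set, only enhancer elements annotated as active in that tissue are
#'   unioned into the mask.
#' @param gene_tad_mode how a gene is assigned to a TAD: \code{"body"}
#'   (default; any >= 1 bp overlap of the gene body) or \code{"tss"} (the
#'   gene's 5' end must fall inside the TAD).
#' @return A list of class \code{regulome_config}.
#' @export
regulome_config <- function(phylop_threshold = 1.3,
                            include_vista = TRUE,
                            vista_tissue_filter = NULL,
                            gene_tad_mode = c("body", "tss")) {
  stopifnot(is.finite(phylop_threshold))
  structure(list(phylop_threshold = phylop_threshold,
                 include_vista = isTRUE(include_vista),
                 vista_tissue_filter = vista_tissue_filter,
                 gene_tad_mode = match.arg(gene_tad_mode)),
            class = "regulome_config")
}

#' Extract conserved intervals from a per-base score track
#'
#' The track is a piecewise-constant segmentation of the genome (as read
#' from a bedGraph) with a numeric \code{score} column; positions not
#' covered by any segment are treated as score 0.  Returns the maximal runs
#' of consecutive positions whose score is \emph{strictly} greater than the
#' threshold, merged into disjoint intervals.
#'
#' @param score_track \code{GRanges} with a numeric \code{score} column.
#' @param threshold numeric cutoff; strict inequality.
#' @return Merged, disjoint \code{GRanges} of conserved runs.
#' @export
conserved_intervals <- function(score_track, threshold = 1.3) {
  stopifnot(is(score_track, "GRanges"), !is.null(score_track$score))
  GenomicRanges::reduce(.bare(score_track[score_track$score > threshold]))
}

#' TADs containing a limb-development gene
#'
#' Returns the subset of TADs whose interval overlaps the body of at least
#' one limb-flagged gene (or, in \code{"tss"} mode, contains the gene's
#' 5' end).
#'
#' @param tads \code{GRanges} of TAD intervals, optionally with an
#'   \code{id} column.
#' @param genes \code{GRanges} of gene bodies with a logical
#'   \code{limb_flag} column.
#' @param mode \code{"body"} or \code{"tss"}; see \code{\link{regulome_config}}.
#' @return Subset of \code{tads}.
#' @export
limb_tads <- function(tads, genes, mode = c("body", "tss")) {
  mode <- match.arg(mode)
  stopifnot(is(tads, "GRanges"), is(genes, "GRanges"))
  if (!length(tads)) {
    warning("empty TAD set; returning empty limb-TAD set")
    return(tads)
  }
  if (is.null(genes$limb_flag)) stop("gene catalog lacks a 'limb_flag' column")
  limb <- genes[genes$limb_flag]
  if (!length(limb)) return(tads[0])
  anchors <- if (mode == "tss") GenomicRanges::resize(limb, width = 1L, fix = "start") else limb
  IRanges::subsetByOverlaps(tads, anchors, ignore.strand = TRUE)
}

#' Build the tissue regulome mask
#'
#' The core of the mask is the three-way intersection of (1) conserved
#' positions, (2) TADs containing a limb gene and (3) active-enhancer
#' (H3K27ac) peaks; validated enhancer elements are unioned in afterwards.
#' Each merged site carries provenance tags saying whether it derives from
#' the core intersection, from an enhancer element, or both.
#'
#' @param conserved \code{GRanges} from \code{\link{conserved_intervals}}.
#' @param limb_tads \code{GRanges} from \code{\link{limb_tads}}.
#' @param peaks \code{GRanges} of chromatin peaks.
#' @param enhancers \code{GRanges} of validated enhancer elements with an
#'   optional \code{tissues} column (comma-separated labels) used by
#'   \code{vista_tissue_filter}.
#' @param cfg a \code{\link{regulome_config}}.
#' @param genome_size total genome size in bp used for the mask's
#'   genome-fraction statistic; \code{NA} leaves the fraction unset.
#' @return A \code{regulome_mask}: list with \code{sites} (merged
#'   \code{GRanges} with a \code{provenance} column), and \code{stats}
#'   (\code{site_count}, \code{bp_covered}, \code{genome_fraction}).
#' @export
build_regulome <- function(conserved, limb_tads, peaks, enhancers = NULL,
                           cfg = regulome_config(), genome_size = NA_real_) {
  stopifnot(is(conserved, "GRanges"), is(limb_tads, "GRanges"), is(peaks, "GRanges"))
  if (length(conserved) && length(limb_tads))
    .check_chrom_namespace(conserved, limb_tads, "conservation", "TADs")
  core <- GenomicRanges::reduce(
    GenomicRanges::intersect(
      GenomicRanges::intersect(.bare(conserved), .bare(limb_tads), ignore.strand = TRUE),
      .bare(peaks), ignore.strand = TRUE))
  enh <- GenomicRanges::GRanges()
  if (cfg$include_vista && !is.null(enhancers) && length(enhancers)) {
    keep <- enhancers
    if (!is.null(cfg$vista_tissue_filter)) {
      tiss <- if (is.null(enhancers$tissues)) character(length(enhancers)) else enhancers$tissues
      keep <- enhancers[vapply(strsplit(tiss, ",", fixed = TRUE),
                               function(x) cfg$vista_tissue_filter %in% trimws(x), logical(1))]
    }
    enh <- GenomicRanges::reduce(.bare(keep))
  }
  sites <- GenomicRanges::reduce(c(core, enh))
  prov <- character(length(sites))
  if (length(sites)) {
    from_core <- IRanges::overlapsAny(sites, core)
    from_enh <- IRanges::overlapsAny(sites, enh)
    prov <- ifelse(from_core & from_enh, "core,vista",
                   ifelse(from_enh, "vista", "core"))
  }
  sites$provenance <- prov
  mask <- structure(list(sites = sites, genome_size = genome_size), class = "regulome_mask")
  mask$stats <- regulome_stats(mask, genome_size)
  mask
}

#' Summary statistics of a regulome mask
#'
#' A "site" is one maximal merged interval of the mask.
#'
#' @param mask a \code{regulome_mask} (or a bare \code{GRanges}).
#' @param genome_size genome size in bp; must be > 0 unless \code{NA}.
#' @return List with \code{site_count}, \code{bp_covered},
#'   \code{genome_fraction}.
#' @export
regulome_stats <- function(mask, genome_size = NA_real_) {
  sites <- if (inherits(mask, "regulome_mask")) mask$sites else mask
  if (!is.na(genome_size) && genome_size <= 0) stop("genome_size must be > 0")
  bp <- total_bp(sites)
  list(site_count = length(sites),
       bp_covered = bp,
       genome_fraction = if (is.na(genome_size)) NA_real_ else bp / genome_size)
}

#' @export
print.regulome_mask <- function(x, ...) {
  s <- x$stats
  cat(sprintf("regulome mask: %d sites covering %d bp", s$site_count, s$bp_covered))
  if (!is.na(s$genome_fraction))
    cat(sprintf(" (%.4f%% of the genome)", 100 * s$genome_fraction))
  cat("\n")
  invisible(x)
}

#' Subset variants to those inside the regulome mask
#'
#' A variant is inside the mask iff its reference-anchored span (the single
#' base for an SNV; every reference base of the affected span for an indel)
#' overlaps a mask site.  Variants on chromosomes unknown to the mask are
#' treated as outside and counted in a message.
#'
#' @param mask a \code{regulome_mask} or \code{GRanges}.
#' @param variants variant data.frame with columns \code{chrom}, \code{pos}
#'   (1-based), \code{ref}.
#' @return The subset of rows of \code{variants} inside the mask, input
#'   order preserved.
#' @export
mask_contains <- function(mask, variants) {
  sites <- if (inherits(mask, "regulome_mask")) mask$sites else mask
  if (!nrow(variants) || !length(sites)) return(variants[0, , drop = FALSE])
  known <- variants$chrom %in% GenomeInfoDb::seqlevels(sites)
  if (any(!known))
    message(sum(!known), " variant(s) on chromosomes absent from the mask; treated as outside")
  hit <- logical(nrow(variants))
  if (any(known)) {
    v <- variants[known, , drop = FALSE]
    spans <- gintervals(v$chrom, v$pos, v$pos + nchar(v$ref) - 1L)
    hit[known] <- IRanges::overlapsAny(spans, sites, ignore.strand = TRUE)
  }
  variants[hit, , drop = FALSE]
}
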