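#' SNV filter settings
#'
#' Named thresholds of the SNV prioritization cascade.  Two rarity cutoffs
#' coexist deliberately: \code{rare_af_noncoding} (frequency < 0.1%) drives
#' the regulome filtering itself, while \code{rare_af_reported} (AF < 1%)
#' reproduces the looser cutoff used for descriptive cohort counts.
#'
#' @param rare_af_noncoding allele-frequency cutoff (strict <) for the
#'   noncoding regulome filter. Default 0.001.
#' @param rare_af_reported looser AF cutoff for descriptive counts. Default 0.01.
#' @param proximity_bp cross-case pairing distance; strict < by default.
#' @param proximity_inclusive use <= instead of strict < for the distance rule.
#' @param trans_maf MAF cutoff (strict <) for the in-trans noncoding screen.
#' @param cadd_lof CADD score above which (strict) a missense call counts as
#'   probable loss of function.
#' @param pli_min pLI above which (strict) a gene counts as LoF intolerant.
#' @param coding_flank_bp a variant within this many bp of an exon counts as
#'   coding-proximal.
#' @param min_gq optional minimum genotype quality for de novo calling;
#'   \code{NA} (default) disables the check.
#' @return list of class \code{snv_filter_config}.
#' @export
snv_filter_config <- function(rare_af_noncoding = 0.001,
                              rare_af_reported = 0.01,
                              proximity_bp = 300L,
                              proximity_inclusive = FALSE,
                              trans_maf = 0.03,
                              cadd_lof = 20,
                              pli_min = 0.9,
                              coding_flank_bp = 10L,
                              min_gq = NA_real_) {
  cfg <- list(rare_af_noncoding = rare_af_noncoding,
              rare_af_reported = rare_af_reported,
              proximity_bp = as.integer(proximity_bp),
              proximity_inclusive = isTRUE(proximity_inclusive),
              trans_maf = trans_maf, cadd_lof = cadd_lof, pli_min = pli_min,
              coding_flank_bp = as.integer(coding_flank_bp), min_gq = min_gq)
  num <- vapply(cfg[c("rare_af_noncoding", "rare_af_reported", "proximity_bp",
                      "trans_maf", "cadd_lof", "pli_min", "coding_flank_bp")],
                as.numeric, numeric(1))
  if (any(num < 0)) stop("all thresholds must be >= 0")
  structure(cfg, class = "snv_filter_config")
}

## Internal genotype helpers: GT strings "0/0", "0/1", "1/1", "1" (hemizygous),
## "./." etc.  Phasing separators are tolerated.
.gt_alleles <- function(gt) strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
.gt_alt_count <- function(gt) {
  vapply(.gt_alleles(gt), function(a) {
    if (any(a == "." | a == "")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}
.gt_missing <- function(gt) is.na(gt) | gt == "" | vapply(
  .gt_alleles(gt), function(a) any(a == "." | a == ""), logical(1))

#' Classify variants as coding-proximal or noncoding
#'
#' A variant is \code{coding_proximal} iff its reference span overlaps an
#' exon or lies within \code{flank_bp} of an exon boundary; otherwise it is
#' \code{noncoding}.  Variants on chromosomes absent from the annotation are
#' noncoding (with a message).  Also fills \code{gene_hits} with the ids of
#' genes whose body or flank the variant touches.
#'
#' @param variants variant data.frame (\code{chrom}, \code{pos}, \code{ref}).
#' @param exons \code{GRanges} of exons with a \code{gene_id} column.
#' @param flank_bp flank width in bp (default 10).
#' @return \code{variants} with \code{coding_context} and \code{gene_hits}
#'   columns added.
#' @export
classify_coding_context <- function(variants, exons, flank_bp = 10L) {
  stopifnot(is(exons, "GRanges"))
  variants$coding_context <- rep("noncoding", nrow(variants))
  variants$gene_hits <- rep("", nrow(variants))
  if (!nrow(variants)) return(variants)
  unknown <- !(variants$chrom %in% GenomeInfoDb::seqlevels(exons))
  if (any(unknown))
    message(sum(unknown), " variant(s) on unannotated chromosomes; classified noncoding")
  spans <- gintervals(variants$chrom[!unknown], variants$pos[!unknown],
                      variants$pos[!unknown] + nchar(variants$ref[!unknown]) - 1L)
  widened <- GenomicRanges::resize(exons, GenomicRanges::width(exons) + 2L * flank_bp,
                                   fix = "center")
  ov <- GenomicRanges::findOverlaps(spans, widened, ignore.strand = TRUE)
  ctx <- rep("noncoding", length(spans))
  ctx[unique(S4Vectors::queryHits(ov))] <- "coding_proximal"
  hits <- vapply(seq_along(spans), function(i) {
    g <- unique(widened$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]])
    paste(sort(g), collapse = ",")
  }, character(1))
  variants$coding_context[!unknown] <- ctx
  variants$gene_hits[!unknown] <- hits
  variants
}

#' Keep variants with population allele frequency strictly below a threshold
#'
#' Missing AF is treated as rare (an unobserved allele).  Row order is
#' preserved.
#'
#' @param variants variant data.frame with an \code{af} column.
#' @param threshold AF cutoff in [0, 1]; strict inequality.
#' @return The rare subset.
#' @export
filter_rare <- function(variants, threshold = 0.001) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- is.na(variants$af) | variants$af < threshold
  variants[keep, , drop = FALSE]
}

#' Detect de novo variants in one trio
#'
#' A variant is de novo iff the index carries at least one alternate allele
#' while both parents are homozygous reference.  Variants with a missing
#' parental genotype are not evaluable and are excluded (their count is
#' returned as an attribute \code{n_unevaluable}).  A case without parental
#' genotype columns yields an empty result with attribute
#' \code{status = "singleton"}.
#'
#' @param variants variant data.frame for one case with \code{gt_index},
#'   \code{gt_mother}, \code{gt_father} columns (and optional \code{gq_*}
#'   columns when \code{min_gq} is set).
#' @param min_gq optional minimum genotype quality applied to all three
#'   samples; \code{NA} disables.
#' @return de novo subset of \code{variants}.
#' @export
detect_de_novo <- function(variants, min_gq = NA_real_) {
  if (!all(c("gt_mother", "gt_father") %in% names(variants))) {
    out <- variants[0, , drop = FALSE]
    attr(out, "status") <- "singleton"
    return(out)
  }
  idx <- .gt_alt_count(variants$gt_index)
  mo <- .gt_alt_count(variants$gt_mother)
  fa <- .gt_alt_count(variants$gt_father)
  unevaluable <- is.na(idx) | is.na(mo) | is.na(fa)
  dn <- !unevaluable & idx >= 1L & mo == 0L & fa == 0L
  if (!is.na(min_gq)) {
    for (col in c("gq_index", "gq_mother", "gq_father"))
      if (col %in% names(variants)) dn <- dn & !is.na(variants[[col]]) & variants[[col]] >= min_gq
  }
  out <- variants[dn, , drop = FALSE]
  attr(out, "n_unevaluable") <- sum(unevaluable)
  out
}

#' Hemizygous X-chromosome candidates for a male index
#'
#' For male index cases only: X-chromosome variants where the index is
#' hemizygous (or homozygous-called) alternate and the mother is a
#' heterozygous carrier, or the call is de novo (both parents reference).
#' Female index cases return an empty set.
#'
#' @param variants trio variant data.frame for one case.
#' @param index_sex \code{"male"} or \code{"female"}; required.
#' @param x_chrom name of the X chromosome in this genome (default "chrX").
#' @return candidate subset.
#' @export
hemizygous_x_candidates <- function(variants, index_sex, x_chrom = "chrX") {
  if (missing(index_sex) || is.na(index_sex) || !index_sex %in% c("male", "female"))
    stop("index_sex must be given as 'male' or 'female'")
  if (index_sex == "female") return(variants[0, , drop = FALSE])
  on_x <- variants$chrom == x_chrom
  idx <- .gt_alleles(variants$gt_index)
  hemi_alt <- vapply(idx, function(a) length(a) >= 1 && all(a != "0" & a != "."), logical(1))
  mo <- .gt_alt_count(variants$gt_mother)
  fa <- .gt_alt_count(variants$gt_father)
  carrier_mother <- !is.na(mo) & mo == 1L
  de_novo <- !is.na(mo) & mo == 0L & (is.na(fa) | fa == 0L)
  variants[on_x & hemi_alt & (carrier_mother | de_novo), , drop = FALSE]
}

#' Resolve parental origin of heterozygous variants from trio transmission
#'
#' Origin is \code{maternal}/\code{paternal} when exactly one parent carries
#' the allele, \code{de_novo} when neither does, and \code{unknown} when
#' both carry it or a genotype is missing.
#'
#' @param variants trio variant data.frame.
#' @return \code{variants} with a \code{parental_origin} column.
#' @export
resolve_parental_origin <- function(variants) {
  mo <- .gt_alt_count(variants$gt_mother)
  fa <- .gt_alt_count(variants$gt_father)
  origin <- rep("unknown", nrow(variants))
  known <- !is.na(mo) & !is.na(fa)
  origin[known & mo > 0 & fa == 0] <- "maternal"
  origin[known & fa > 0 & mo == 0] <- "paternal"
  origin[known & mo == 0 & fa == 0] <- "de_novo"
  variants$parental_origin <- origin
  variants
}

#' Cross-case proximity pairs of rare noncoding variants
#'
#' Reports every unordered pair of variants from distinct cases that lie on
#' the same chromosome either closer than \code{proximity_bp} (strict by
#' default) or inside the same enhancer element.  Each pair is annotated
#' with its distance, the rule that matched, and whether both members fall
#' inside the regulome mask.
#'
#' @param variants rare noncoding variant data.frame across cases
#'   (\code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{case_id}).
#' @param cfg \code{\link{snv_filter_config}}.
#' @param enhancers optional \code{GRanges} of enhancer elements for the
#'   same-enhancer rule.
#' @param mask optional \code{regulome_mask} for the in-mask annotation.
#' @return data.frame with one row per pair: members' case/chrom/pos/ref/alt,
#'   \code{distance}, \code{rule} (\code{distance} / \code{same_enhancer} /
#'   \code{both}), \code{both_in_mask}.
#' @export
proximity_pairs <- function(variants, cfg = snv_filter_config(),
                            enhancers = NULL, mask = NULL) {
  empty <- data.frame(case1 = character(), case2 = character(),
                      chrom = character(), pos1 = integer(), pos2 = integer(),
                      ref1 = character(), alt1 = character(),
                      ref2 = character(), alt2 = character(),
                      distance = integer(), rule = character(),
                      both_in_mask = logical(), stringsAsFactors = FALSE)
  if (nrow(variants) < 2) return(empty)
  pts <- gintervals(variants$chrom, variants$pos, variants$pos)
  ## maxgap g pairs positions with |p1-p2| <= g+1, so strict "< d" means
  ## maxgap = d - 2 and inclusive "<= d" means maxgap = d - 1.
  gap <- cfg$proximity_bp - (if (cfg$proximity_inclusive) 1L else 2L)
  hits <- GenomicRanges::findOverlaps(pts, maxgap = gap, drop.self = TRUE,
                                      drop.redundant = TRUE, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  dist_ok <- rep(TRUE, length(i))
  if (!is.null(enhancers) && length(enhancers)) {
    ov <- GenomicRanges::findOverlaps(pts, .bare(enhancers), ignore.strand = TRUE)
    by_enh <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
    enh_pairs <- unique(do.call(rbind, lapply(by_enh, function(v) {
      v <- sort(unique(v))
      if (length(v) < 2) return(NULL)
      t(utils::combn(v, 2))
    })))
    if (!is.null(enh_pairs) && nrow(enh_pairs)) {
      key_old <- paste(i, j)
      key_new <- paste(enh_pairs[, 1], enh_pairs[, 2])
      add <- !(key_new %in% key_old)
      same_enh_key <- key_new
      i <- c(i, enh_pairs[add, 1]); j <- c(j, enh_pairs[add, 2])
      dist_ok <- c(dist_ok, rep(FALSE, sum(add)))
      in_enh <- paste(i, j) %in% same_enh_key
    } else in_enh <- rep(FALSE, length(i))
  } else in_enh <- rep(FALSE, length(i))
  keep <- variants$case_id[i] != variants$case_id[j]
  i <- i[keep]; j <- j[keep]; dist_ok <- dist_ok[keep]; in_enh <- in_enh[keep]
  if (!length(i)) return(empty)
  ## canonical member order: by position, then case id
  swap <- variants$pos[i] > variants$pos[j] |
    (variants$pos[i] == variants$pos[j] & variants$case_id[i] > variants$case_id[j])
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  rule <- ifelse(dist_ok & in_enh, "both", ifelse(dist_ok, "distance", "same_enhancer"))
  out <- data.frame(case1 = variants$case_id[a], case2 = variants$case_id[b],
                    chrom = variants$chrom[a],
                    pos1 = variants$pos[a], pos2 = variants$pos[b],
                    ref1 = variants$ref[a], alt1 = variants$alt[a],
                    ref2 = variants$ref[b], alt2 = variants$alt[b],
                    distance = abs(variants$pos[a] - variants$pos[b]),
                    rule = rule, both_in_mask = NA, stringsAsFactors = FALSE)
  if (!is.null(mask)) {
    sites <- if (inherits(mask, "regulome_mask")) mask$sites else mask
    inmask <- IRanges::overlapsAny(pts, sites, ignore.strand = TRUE)
    out$both_in_mask <- inmask[a] & inmask[b]
  }
  out <- out[order(out$chrom, out$pos1, out$pos2, out$case1, out$case2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Double hits: identical rare calls shared by two or more index cases
#'
#' Groups proximity pairs whose two members are the identical call (same
#' chromosome, position, ref and alt) and reports each such position with
#' the set of carrier cases.
#'
#' @param pairs pair data.frame from \code{\link{proximity_pairs}}.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{cases} (comma-separated, sorted), \code{n_cases}.
#' @export
double_hits <- function(pairs) {
  same <- pairs$pos1 == pairs$pos2 & pairs$ref1 == pairs$ref2 & pairs$alt1 == pairs$alt2
  p <- pairs[same, , drop = FALSE]
  if (!nrow(p)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), cases = character(), n_cases = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(p$chrom, p$pos1, p$ref1, p$alt1, sep = ":")
  groups <- split(seq_len(nrow(p)), key)
  out <- do.call(rbind, lapply(groups, function(rows) {
    cases <- sort(unique(c(p$case1[rows], p$case2[rows])))
    data.frame(chrom = p$chrom[rows[1]], pos = p$pos1[rows[1]],
               ref = p$ref1[rows[1]], alt = p$alt1[rows[1]],
               cases = paste(cases, collapse = ","), n_cases = length(cases),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-trans screen: coding hit plus opposite-haplotype noncoding hit in one TAD
#'
#' For each rare heterozygous, potentially pathogenic (truncating or
#' CADD > \code{cadd_lof}) coding variant in a gene flagged with a recessive
#' limb phenotype, reports conserved noncoding variants of the same case
#' with MAF strictly below \code{trans_maf} that lie in the same TAD as the
#' gene and are carried on the opposite parental haplotype.  Pairs whose
#' phase cannot be resolved from trio transmission are returned separately,
#' never silently dropped.
#'
#' @param variants trio variant data.frame for one case, already passed
#'   through \code{\link{classify_coding_context}}; needs \code{af},
#'   \code{cadd}, \code{truncating} columns.
#' @param genes \code{GRanges} gene catalog with \code{gene_id},
#'   \code{recessive_flag} (and \code{pli}) columns.
#' @param tads \code{GRanges} of TADs.
#' @param conserved \code{GRanges} of conserved intervals (the noncoding
#'   partner must be conserved).
#' @param cfg \code{\link{snv_filter_config}}.
#' @return list with \code{candidates} and \code{phase_unknown} data.frames
#'   (columns: gene_id, coding and noncoding chrom/pos/ref/alt and origins).
#' @export
trans_screen <- function(variants, genes, tads, conserved,
                         cfg = snv_filter_config()) {
  variants <- resolve_parental_origin(variants)
  empty <- data.frame(case_id = character(), gene_id = character(),
                      coding_chrom = character(), coding_pos = integer(),
                      coding_ref = character(), coding_alt = character(),
                      coding_origin = character(),
                      nc_chrom = character(), nc_pos = integer(),
                      nc_ref = character(), nc_alt = character(),
                      nc_origin = character(), nc_af = numeric(),
                      stringsAsFactors = FALSE)
  res <- list(candidates = empty, phase_unknown = empty)
  rec_genes <- genes[genes$recessive_flag]
  if (!length(rec_genes) || !nrow(variants)) return(res)

  het <- .gt_alt_count(variants$gt_index) == 1L
  rare <- is.na(variants$af) | variants$af < cfg$trans_maf
  patho <- (!is.na(variants$truncating) & variants$truncating) |
    (!is.na(variants$cadd) & variants$cadd > cfg$cadd_lof)
  coding <- variants$coding_context == "coding_proximal"
  cvars <- variants[het & rare & patho & coding, , drop = FALSE]
  if (!nrow(cvars)) return(res)

  nc <- variants[variants$coding_context == "noncoding" &
                   (is.na(variants$af) | variants$af < cfg$trans_maf), , drop = FALSE]
  if (nrow(nc)) {
    nc_pts <- gintervals(nc$chrom, nc$pos, nc$pos)
    nc <- nc[IRanges::overlapsAny(nc_pts, conserved, ignore.strand = TRUE), , drop = FALSE]
  }
  if (!nrow(nc)) return(res)

  rows_cand <- list(); rows_unk <- list()
  for (ci in seq_len(nrow(cvars))) {
    cv <- cvars[ci, ]
    ## recessive genes this coding variant hits
    hit_ids <- intersect(strsplit(cv$gene_hits, ",", fixed = TRUE)[[1]], rec_genes$gene_id)
    if (!length(hit_ids)) next
    g <- rec_genes[rec_genes$gene_id %in% hit_ids]
    gene_tads <- IRanges::subsetByOverlaps(tads, g, ignore.strand = TRUE)
    if (!length(gene_tads)) next
    in_tad <- IRanges::overlapsAny(gintervals(nc$chrom, nc$pos, nc$pos),
                                   gene_tads, ignore.strand = TRUE)
    partners <- nc[in_tad, , drop = FALSE]
    for (ni in seq_len(nrow(partners))) {
      nv <- partners[ni, ]
      if (nv$pos == cv$pos && nv$chrom == cv$chrom) next
      row <- data.frame(case_id = cv$case_id,
                        gene_id = paste(hit_ids, collapse = ","),
                        coding_chrom = cv$chrom, coding_pos = cv$pos,
                        coding_ref = cv$ref, coding_alt = cv$alt,
                        coding_origin = cv$parental_origin,
                        nc_chrom = nv$chrom, nc_pos = nv$pos,
                        nc_ref = nv$ref, nc_alt = nv$alt,
                        nc_origin = nv$parental_origin, nc_af = nv$af,
                        stringsAsFactors = FALSE)
      phased <- cv$parental_origin %in% c("maternal", "paternal") &&
        nv$parental_origin %in% c("maternal", "paternal")
      if (!phased) rows_unk[[length(rows_unk) + 1L]] <- row
      else if (cv$parental_origin != nv$parental_origin)
        rows_cand[[length(rows_cand) + 1L]] <- row
    }
  }
  if (length(rows_cand)) res$candidates <- do.call(rbind, rows_cand)
  if (length(rows_unk)) res$phase_unknown <- do.call(rbind, rows_unk)
  res
}

#' LoF double-hit gene screen
#'
#' Reports genes of high LoF intolerance (pLI strictly above
#' \code{pli_min}) in which qualifying variants — truncating, or with CADD
#' strictly above \code{cadd_lof} — occur in at least two distinct cases.
#' Genes without a pLI value are skipped with a message.
#'
#' @param variants coding variant data.frame across cases with
#'   \code{gene_hits}, \code{cadd}, \code{truncating}, \code{case_id}.
#' @param genes \code{GRanges} gene catalog with \code{gene_id}, \code{pli}.
#' @param cfg \code{\link{snv_filter_config}}.
#' @return data.frame with \code{gene_id}, \code{pli}, \code{cases},
#'   \code{n_cases}.
#' @export
lof_double_hit_genes <- function(variants, genes, cfg = snv_filter_config()) {
  empty <- data.frame(gene_id = character(), pli = numeric(),
                      cases = character(), n_cases = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(variants)) return(empty)
  qual <- (!is.na(variants$truncating) & variants$truncating) |
    (!is.na(variants$cadd) & variants$cadd > cfg$cadd_lof)
  v <- variants[qual & variants$gene_hits != "", , drop = FALSE]
  if (!nrow(v)) return(empty)
  long <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    data.frame(gene_id = strsplit(v$gene_hits[i], ",", fixed = TRUE)[[1]],
               case_id = v$case_id[i], stringsAsFactors = FALSE)
  }))
  pli <- setNames(genes$pli, genes$gene_id)
  rows <- lapply(split(long$case_id, long$gene_id), unique)
  out <- do.call(rbind, lapply(names(rows), function(g) {
    if (!g %in% names(pli) || is.na(pli[[g]])) {
      message("gene ", g, " lacks a pLI value; skipped")
      return(NULL)
    }
    if (pli[[g]] <= cfg$pli_min || length(rows[[g]]) < 2) return(NULL)
    data.frame(gene_id = g, pli = pli[[g]],
               cases = paste(sort(rows[[g]]), collapse = ","),
               n_cases = length(rows[[g]]), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
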