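#' Counts of events planted into a synthetic cohort
#'
#' Event classes mirror the findings the prioritization pipeline is built
#' to recover: de novo SNVs inside (and outside) the regulome mask,
#' cross-case proximity pairs at a controlled distance, pairs sharing one
#' enhancer element, identical rare calls in two cases (double hits),
#' in-trans coding/noncoding pairs with opposite parental origins, a
#' loss-of-function double-hit gene, hemizygous X candidates in male
#' trios, a structural-variant slate spanning the filter cascade's
#' outcomes, and polyalanine repeat expansions.
#'
#' @param n_regulome_de_novo de novo SNVs planted inside the regulome mask.
#' @param n_nonregulome_de_novo de novo SNVs planted outside the mask.
#' @param n_proximity_pairs cross-case pairs at \code{proximity_distance}.
#' @param proximity_distance bp distance of planted pairs (must be below
#'   the 300 bp pairing rule to be recoverable).
#' @param n_enhancer_pairs cross-case pairs co-located in one enhancer at a
#'   distance beyond the bp rule.
#' @param enhancer_pair_distance bp distance of enhancer-mediated pairs.
#' @param n_double_hits identical rare calls planted in two cases each, at
#'   regulome positions.
#' @param n_trans_pairs coding het + opposite-haplotype conserved noncoding
#'   pairs in a recessive-limb-phenotype gene's TAD.
#' @param n_lof_genes genes (pLI > 0.9) given qualifying LoF variants in
#'   two cases.
#' @param n_hemi_x hemizygous X-chromosome candidates in male trios.
#' @param n_sv_causal de novo inversions spanning a TAD boundary (retained).
#' @param n_sv_inherited_unaffected SVs inherited from an unaffected parent
#'   (excluded by the inheritance filter).
#' @param n_sv_affected_relative SVs from an unaffected parent but carried
#'   by an affected relative (retained only in affected-relative mode).
#' @param n_sv_small SVs below the minimum size (removed).
#' @param n_sv_low_support SVs below the read-support threshold (removed).
#' @param n_sv_pass_mix additional passing de novo SVs of mixed type.
#' @param repeat_deltas alanine-codon expansions planted as allele
#'   sequences; defaults +8 (pathogenic-like) and +1 (polymorphic-like).
#' @param repeat_reference_ala reference tract length in alanine codons.
#' @return list of class \code{plant_spec}.
#' @export
plant_spec <- function(n_regulome_de_novo = 3L,
                       n_nonregulome_de_novo = 2L,
                       n_proximity_pairs = 3L,
                       proximity_distance = 250L,
                       n_enhancer_pairs = 1L,
                       enhancer_pair_distance = 500L,
                       n_double_hits = 2L,
                       n_trans_pairs = 1L,
                       n_lof_genes = 1L,
                       n_hemi_x = 1L,
                       n_sv_causal = 1L,
                       n_sv_inherited_unaffected = 3L,
                       n_sv_affected_relative = 1L,
                       n_sv_small = 2L,
                       n_sv_low_support = 2L,
                       n_sv_pass_mix = 4L,
                       repeat_deltas = c(maternal = 8L, paternal = 1L),
                       repeat_reference_ala = 15L) {
  spec <- as.list(environment())
  counts <- grep("^n_", names(spec), value = TRUE)
  for (f in counts) if (spec[[f]] < 0) stop("invalid plant_spec: ", f, " must be >= 0")
  structure(spec, class = "plant_spec")
}

#' Background allele-frequency model
#'
#' Mixture of a point mass of singletons (AF 0) and a beta distribution,
#' giving both rare and common strata.
#'
#' @param singleton_prob probability a background variant is a singleton.
#' @param beta_shape1,beta_shape2 beta parameters for non-singleton AFs.
#' @return list of class \code{af_model}.
#' @export
af_model <- function(singleton_prob = 0.25, beta_shape1 = 0.3, beta_shape2 = 1.5) {
  stopifnot(singleton_prob >= 0, singleton_prob <= 1,
            beta_shape1 > 0, beta_shape2 > 0)
  structure(list(singleton_prob = singleton_prob,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2),
            class = "af_model")
}

.bases <- c("A", "C", "G", "T")

## Internal: one ref/alt SNV base pair.
.draw_snv_alleles <- function(n = 1L) {
  ref <- sample(.bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1), character(1))
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

## Internal: position registry enforcing a minimum cross-variant spacing so
## that the truth ledger stays the exhaustive record of cross-case
## proximity events.
.new_registry <- function(min_gap = 400L) {
  env <- new.env(parent = emptyenv())
  env$min_gap <- min_gap
  env$pos <- list()
  env
}
.registry_free <- function(reg, chrom, pos) {
  occ <- reg$pos[[chrom]]
  is.null(occ) || all(abs(occ - pos) >= reg$min_gap)
}
.registry_add <- function(reg, chrom, pos) {
  reg$pos[[chrom]] <- c(reg$pos[[chrom]], pos)
  invisible(NULL)
}

## Internal: sample one position inside `within` (GRanges), outside
## `avoid` (GRanges or NULL), respecting the spacing registry.
.sample_position_in <- function(within, reg, avoid = NULL, tries = 500L) {
  if (!length(within)) return(NULL)
  w <- GenomicRanges::width(within)
  for (i in seq_len(tries)) {
    k <- sample.int(length(within), 1, prob = w)
    pos <- GenomicRanges::start(within)[k] + sample.int(w[k], 1) - 1L
    chrom <- as.character(GenomicRanges::seqnames(within))[k]
    if (!is.null(avoid) && length(avoid) &&
        IRanges::overlapsAny(gintervals(chrom, pos, pos), avoid, ignore.strand = TRUE))
      next
    if (.registry_free(reg, chrom, pos)) return(list(chrom = chrom, pos = pos))
  }
  NULL
}

## Internal: genotype triple for an inherited het call in the index.
.inherited_gt <- function() {
  if (runif(1) < 0.5) c(index = "0/1", mother = "0/1", father = "0/0")
  else c(index = "0/1", mother = "0/0", father = "0/1")
}

## Internal: build one variant row.
.variant_row <- function(case_id, chrom, pos, ref, alt, gt, af, cadd,
                         truncating = FALSE) {
  data.frame(case_id = case_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt,
             gt_index = gt[["index"]], gt_mother = gt[["mother"]],
             gt_father = gt[["father"]],
             af = af, cadd = cadd, truncating = truncating,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic trio cohort with planted events and a truth ledger
#'
#' Produces per-trio SNV calls, structural variants, repeat-allele
#' sequences and an exhaustive ledger of every planted event.  Background
#' variants are drawn with allele frequencies from \code{af_model}; their
#' genotypes are always consistent with inheritance (no accidental de
#' novos) and their positions keep a minimum spacing from each other and
#' from planted sites, so the ledger is the complete list of cross-case
#' proximity and double-hit events.  Background variants on the X
#' chromosome are only assigned to female-index trios, and TADs used for
#' in-trans plants are excluded from background placement.
#'
#' @param genome a \code{genome_model} from \code{\link{make_genome}}.
#' @param n_trios number of trios (>= 1).
#' @param plant a \code{\link{plant_spec}}.
#' @param af a \code{\link{af_model}}.
#' @param n_background number of background SNVs across the cohort.
#' @param seed integer random seed (required).
#' @param regulome_cfg \code{\link{regulome_config}} used to build the mask
#'   that regulome plants are placed in (must match the analysis settings).
#' @return list of class \code{trio_cohort}: \code{variants}, \code{svs},
#'   \code{trios}, \code{repeat_alleles}, \code{repeat_anchor},
#'   \code{truth} (ledger data.frames), \code{mask}.
#' @export
make_cohort <- function(genome, n_trios = 12L, plant = plant_spec(),
                        af = af_model(), n_background = 6000L, seed,
                        regulome_cfg = regulome_config()) {
  if (missing(seed)) stop("seed is required")
  if (n_trios < 1) stop("n_trios must be >= 1")
  set.seed(seed)
  cases <- sprintf("case%02d", seq_len(n_trios))
  ## fixed male/female alternation keeps sex deterministic per case index
  sexes <- rep_len(c("male", "female"), n_trios)
  trios <- data.frame(case_id = cases, index_sex = sexes,
                      mother_affected = FALSE, father_affected = FALSE,
                      stringsAsFactors = FALSE)

  mask <- genome_regulome(genome, regulome_cfg)
  exon_flanks <- GenomicRanges::resize(genome$exons,
                                       GenomicRanges::width(genome$exons) + 22L,
                                       fix = "center")
  all_chroms <- gintervals(genome$chromosomes$name, 1, genome$chromosomes$length)
  noncoding_space <- GenomicRanges::setdiff(all_chroms, .bare(exon_flanks),
                                            ignore.strand = TRUE)
  mask_noncoding <- GenomicRanges::intersect(mask$sites, noncoding_space,
                                             ignore.strand = TRUE)
  conserved <- conserved_intervals(genome$conservation, regulome_cfg$phylop_threshold)
  reg <- .new_registry(400L)
  rows <- list()
  truth <- list()
  blocked <- GenomicRanges::GRanges()

  rare_af <- function(n = 1L) round(runif(n, 0, 8e-4), 6)

  ## --- in-trans pairs (planted first; their TADs are blocked afterwards)
  trans_rows <- list()
  if (plant$n_trans_pairs > 0) {
    rec <- genome$genes[genome$genes$recessive_flag]
    if (length(rec) < plant$n_trans_pairs)
      stop("infeasible plant_spec: ", plant$n_trans_pairs,
           " trans pairs requested but only ", length(rec),
           " recessive-limb genes in the genome")
    gsel <- sample(seq_along(rec), plant$n_trans_pairs)
    for (k in seq_len(plant$n_trans_pairs)) {
      g <- rec[gsel[k]]
      case <- sample(cases, 1)
      g_tads <- IRanges::subsetByOverlaps(genome$tads, g, ignore.strand = TRUE)
      ex <- genome$exons[genome$exons$gene_id == g$gene_id]
      ## coding plants live outside the noncoding analyses; no spacing needed
      cpos <- .sample_position_in(ex, .new_registry(1L))
      nc_space <- GenomicRanges::setdiff(GenomicRanges::intersect(
        GenomicRanges::intersect(.bare(g_tads), conserved, ignore.strand = TRUE),
        noncoding_space, ignore.strand = TRUE),
        .bare(genome$enhancers), ignore.strand = TRUE)
      npos <- .sample_position_in(nc_space, reg)
      if (is.null(cpos) || is.null(npos))
        stop("infeasible plant_spec: no room for trans pair in TAD of ", g$gene_id)
      .registry_add(reg, npos$chrom, npos$pos)
      al_c <- .draw_snv_alleles(); al_n <- .draw_snv_alleles()
      coding_origin <- sample(c("maternal", "paternal"), 1)
      nc_origin <- setdiff(c("maternal", "paternal"), coding_origin)
      gt_for <- function(origin) c(index = "0/1",
                                   mother = if (origin == "maternal") "0/1" else "0/0",
                                   father = if (origin == "paternal") "0/1" else "0/0")
      rows[[length(rows) + 1L]] <- .variant_row(
        case, cpos$chrom, cpos$pos, al_c$ref, al_c$alt, gt_for(coding_origin),
        af = round(runif(1, 0.001, 0.02), 5), cadd = round(runif(1, 25, 35), 1))
      rows[[length(rows) + 1L]] <- .variant_row(
        case, npos$chrom, npos$pos, al_n$ref, al_n$alt, gt_for(nc_origin),
        af = round(runif(1, 0.001, 0.025), 5), cadd = round(runif(1, 5, 15), 1))
      trans_rows[[k]] <- data.frame(case_id = case, gene_id = g$gene_id,
                                    coding_chrom = cpos$chrom, coding_pos = cpos$pos,
                                    coding_origin = coding_origin,
                                    nc_chrom = npos$chrom, nc_pos = npos$pos,
                                    nc_origin = nc_origin, stringsAsFactors = FALSE)
      blocked <- c(blocked, .bare(g_tads))
    }
  }
  truth$trans <- if (length(trans_rows)) do.call(rbind, trans_rows) else
    data.frame(case_id = character(), gene_id = character(),
               coding_chrom = character(), coding_pos = integer(),
               coding_origin = character(), nc_chrom = character(),
               nc_pos = integer(), nc_origin = character(),
               stringsAsFactors = FALSE)

  ## enhancer bodies are reserved for intentional same-enhancer pairs only,
  ## so every co-located pair the analysis can find is in the ledger
  trans_blocked <- blocked
  blocked <- c(blocked, .bare(genome$enhancers))
  plantable_mask <- GenomicRanges::setdiff(mask_noncoding, blocked,
                                           ignore.strand = TRUE)

  ## --- de novo SNVs (inside and outside the regulome mask)
  dn_rows <- list()
  plant_dn <- function(space, in_regulome, n) {
    for (k in seq_len(n)) {
      p <- .sample_position_in(space, reg, avoid = blocked)
      if (is.null(p))
        stop("infeasible plant_spec: no room for ",
             if (in_regulome) "regulome" else "non-regulome", " de novo SNV")
      .registry_add(reg, p$chrom, p$pos)
      case <- sample(cases, 1)
      al <- .draw_snv_alleles()
      rows[[length(rows) + 1L]] <<- .variant_row(
        case, p$chrom, p$pos, al$ref, al$alt,
        c(index = "0/1", mother = "0/0", father = "0/0"),
        af = 0, cadd = round(runif(1, 5, 20), 1))
      dn_rows[[length(dn_rows) + 1L]] <<- data.frame(
        case_id = case, chrom = p$chrom, pos = p$pos, ref = al$ref, alt = al$alt,
        in_regulome = in_regulome, stringsAsFactors = FALSE)
    }
  }
  if (plant$n_regulome_de_novo > 0 && !length(plantable_mask))
    stop("infeasible plant_spec: regulome mask is empty, cannot plant regulome de novos")
  plant_dn(plantable_mask, TRUE, plant$n_regulome_de_novo)
  nonmask_space <- GenomicRanges::setdiff(noncoding_space, mask$sites,
                                          ignore.strand = TRUE)
  plant_dn(GenomicRanges::setdiff(nonmask_space, blocked, ignore.strand = TRUE),
           FALSE, plant$n_nonregulome_de_novo)
  truth$de_novo <- if (length(dn_rows)) do.call(rbind, dn_rows) else
    data.frame(case_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), in_regulome = logical(),
               stringsAsFactors = FALSE)

  ## --- cross-case proximity pairs (distance rule)
  prox_rows <- list()
  if (plant$n_proximity_pairs > 0 && n_trios < 2)
    stop("infeasible plant_spec: proximity pairs need >= 2 trios")
  for (k in seq_len(plant$n_proximity_pairs)) {
    d <- plant$proximity_distance
    ## both members inside the regulome mask, d bp apart
    wide_enough <- plantable_mask  # members may sit in different mask sites
    p <- NULL
    for (i in seq_len(500)) {
      cand <- .sample_position_in(wide_enough, reg, avoid = blocked)
      if (is.null(cand)) break
      p2 <- cand$pos + d
      ok2 <- IRanges::overlapsAny(gintervals(cand$chrom, p2, p2),
                                  plantable_mask, ignore.strand = TRUE) &&
        .registry_free(reg, cand$chrom, p2)
      if (ok2) { p <- cand; break }
    }
    if (is.null(p)) stop("infeasible plant_spec: no room for proximity pair at distance ",
                         d, " inside the regulome mask")
    cc <- sample(cases, 2)
    .registry_add(reg, p$chrom, p$pos)
    .registry_add(reg, p$chrom, p$pos + d)
    a1 <- .draw_snv_alleles(); a2 <- .draw_snv_alleles()
    rows[[length(rows) + 1L]] <- .variant_row(cc[1], p$chrom, p$pos, a1$ref, a1$alt,
                                              .inherited_gt(), rare_af(),
                                              round(runif(1, 5, 18), 1))
    rows[[length(rows) + 1L]] <- .variant_row(cc[2], p$chrom, p$pos + d, a2$ref, a2$alt,
                                              .inherited_gt(), rare_af(),
                                              round(runif(1, 5, 18), 1))
    prox_rows[[length(prox_rows) + 1L]] <- data.frame(
      case1 = cc[1], case2 = cc[2], chrom = p$chrom,
      pos1 = p$pos, pos2 = p$pos + d, distance = d, rule = "distance",
      enhancer_id = NA_character_, stringsAsFactors = FALSE)
  }

  ## --- cross-case pairs sharing one enhancer element beyond the bp rule
  if (plant$n_enhancer_pairs > 0) {
    wide <- genome$enhancers[GenomicRanges::width(genome$enhancers) >
                               plant$enhancer_pair_distance + 40L]
    ## keep clear of TADs reserved for in-trans plants and of exons
    wide <- wide[!IRanges::overlapsAny(wide, trans_blocked, ignore.strand = TRUE)]
    wide <- wide[!IRanges::overlapsAny(wide, exon_flanks, ignore.strand = TRUE)]
    if (length(wide) < 1)
      stop("infeasible plant_spec: no enhancer wide enough for an enhancer pair (need > ",
           plant$enhancer_pair_distance, " bp)")
    for (k in seq_len(plant$n_enhancer_pairs)) {
      e <- wide[sample.int(length(wide), 1)]
      d <- plant$enhancer_pair_distance
      p1 <- GenomicRanges::start(e) + sample.int(GenomicRanges::width(e) - d - 1L, 1)
      p2 <- p1 + d
      chrom <- as.character(GenomicRanges::seqnames(e))
      if (!.registry_free(reg, chrom, p1) || !.registry_free(reg, chrom, p2)) next
      .registry_add(reg, chrom, p1); .registry_add(reg, chrom, p2)
      cc <- sample(cases, 2)
      a1 <- .draw_snv_alleles(); a2 <- .draw_snv_alleles()
      rows[[length(rows) + 1L]] <- .variant_row(cc[1], chrom, p1, a1$ref, a1$alt,
                                                .inherited_gt(), rare_af(),
                                                round(runif(1, 5, 18), 1))
      rows[[length(rows) + 1L]] <- .variant_row(cc[2], chrom, p2, a2$ref, a2$alt,
                                                .inherited_gt(), rare_af(),
                                                round(runif(1, 5, 18), 1))
      prox_rows[[length(prox_rows) + 1L]] <- data.frame(
        case1 = cc[1], case2 = cc[2], chrom = chrom, pos1 = p1, pos2 = p2,
        distance = d, rule = "same_enhancer", enhancer_id = e$id,
        stringsAsFactors = FALSE)
    }
  }
  truth$proximity <- if (length(prox_rows)) do.call(rbind, prox_rows) else
    data.frame(case1 = character(), case2 = character(), chrom = character(),
               pos1 = integer(), pos2 = integer(), distance = integer(),
               rule = character(), enhancer_id = character(),
               stringsAsFactors = FALSE)

  ## --- double hits: identical rare call in two cases at a regulome position
  dh_rows <- list()
  if (plant$n_double_hits > 0 && n_trios < 2)
    stop("infeasible plant_spec: double hits need >= 2 trios")
  for (k in seq_len(plant$n_double_hits)) {
    p <- .sample_position_in(plantable_mask, reg, avoid = blocked)
    if (is.null(p)) stop("infeasible plant_spec: no room for double hit in regulome mask")
    .registry_add(reg, p$chrom, p$pos)
    cc <- sort(sample(cases, 2))
    al <- .draw_snv_alleles()
    af_dh <- rare_af()
    for (case in cc)
      rows[[length(rows) + 1L]] <- .variant_row(case, p$chrom, p$pos, al$ref, al$alt,
                                                .inherited_gt(), af_dh,
                                                round(runif(1, 5, 18), 1))
    dh_rows[[k]] <- data.frame(chrom = p$chrom, pos = p$pos, ref = al$ref,
                               alt = al$alt, cases = paste(cc, collapse = ","),
                               stringsAsFactors = FALSE)
  }
  truth$double_hits <- if (length(dh_rows)) do.call(rbind, dh_rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), cases = character(), stringsAsFactors = FALSE)

  ## --- LoF double-hit genes
  lof_rows <- list()
  if (plant$n_lof_genes > 0) {
    lof_genes <- genome$genes[genome$genes$pli > 0.9]
    if (length(lof_genes) < plant$n_lof_genes)
      stop("infeasible plant_spec: not enough genes with pLI > 0.9")
    if (n_trios < 2) stop("infeasible plant_spec: LoF double hits need >= 2 trios")
    gsel <- sample(seq_along(lof_genes), plant$n_lof_genes)
    for (k in seq_len(plant$n_lof_genes)) {
      g <- lof_genes[gsel[k]]
      ex <- genome$exons[genome$exons$gene_id == g$gene_id]
      cc <- sort(sample(cases, 2))
      exon_reg <- .new_registry(1L)  # coding: only forbid identical positions
      ## one truncating call, one probable-LoF missense (CADD > 20)
      for (m in 1:2) {
        p <- .sample_position_in(ex, exon_reg)
        if (is.null(p)) stop("infeasible plant_spec: no room in exons of ", g$gene_id)
        .registry_add(exon_reg, p$chrom, p$pos)
        al <- .draw_snv_alleles()
        rows[[length(rows) + 1L]] <- .variant_row(
          cc[m], p$chrom, p$pos, al$ref, al$alt, .inherited_gt(),
          af = rare_af(), cadd = if (m == 1) round(runif(1, 30, 45), 1)
          else round(runif(1, 22, 30), 1),
          truncating = (m == 1))
      }
      lof_rows[[k]] <- data.frame(gene_id = g$gene_id,
                                  cases = paste(cc, collapse = ","),
                                  stringsAsFactors = FALSE)
    }
  }
  truth$lof_genes <- if (length(lof_rows)) do.call(rbind, lof_rows) else
    data.frame(gene_id = character(), cases = character(), stringsAsFactors = FALSE)

  ## --- hemizygous X candidates (male trios)
  hemi_rows <- list()
  if (plant$n_hemi_x > 0) {
    male_cases <- cases[sexes == "male"]
    has_x <- "chrX" %in% genome$chromosomes$name
    if (!length(male_cases) || !has_x)
      stop("infeasible plant_spec: hemizygous X plants need a chrX and a male trio")
    x_len <- genome$chromosomes$length[genome$chromosomes$name == "chrX"]
    x_space <- GenomicRanges::setdiff(gintervals("chrX", 1, x_len),
                                      blocked, ignore.strand = TRUE)
    for (k in seq_len(plant$n_hemi_x)) {
      p <- .sample_position_in(x_space, reg)
      if (is.null(p)) stop("infeasible plant_spec: no room on chrX")
      .registry_add(reg, p$chrom, p$pos)
      case <- sample(male_cases, 1)
      al <- .draw_snv_alleles()
      rows[[length(rows) + 1L]] <- .variant_row(
        case, p$chrom, p$pos, al$ref, al$alt,
        c(index = "1", mother = "0/1", father = "0"),
        af = rare_af(), cadd = round(runif(1, 10, 25), 1))
      hemi_rows[[k]] <- data.frame(case_id = case, chrom = p$chrom, pos = p$pos,
                                   ref = al$ref, alt = al$alt,
                                   stringsAsFactors = FALSE)
    }
  }
  truth$hemi_x <- if (length(hemi_rows)) do.call(rbind, hemi_rows) else
    data.frame(case_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)

  ## --- background variants
  if (n_background > 0) {
    bg_chroms <- genome$chromosomes
    lens <- setNames(bg_chroms$length, bg_chroms$name)
    accepted_chrom <- character(0); accepted_pos <- integer(0)
    accepted_case <- character(0)
    female_cases <- cases[sexes == "female"]
    tries <- 0L
    while (length(accepted_pos) < n_background && tries < 40L) {
      tries <- tries + 1L
      need <- n_background - length(accepted_pos)
      chr <- sample(bg_chroms$name, 2L * need, replace = TRUE,
                    prob = bg_chroms$length / sum(bg_chroms$length))
      pos <- floor(runif(2L * need, 1, lens[chr])) + 0L
      keep <- !IRanges::overlapsAny(gintervals(chr, pos, pos), blocked,
                                    ignore.strand = TRUE)
      chr <- chr[keep]; pos <- pos[keep]
      for (i in seq_along(pos)) {
        if (length(accepted_pos) >= n_background) break
        if (.registry_free(reg, chr[i], pos[i])) {
          .registry_add(reg, chr[i], pos[i])
          accepted_chrom <- c(accepted_chrom, chr[i])
          accepted_pos <- c(accepted_pos, pos[i])
          ## X-chromosome background only in female-index trios (diploid GTs)
          accepted_case <- c(accepted_case,
                             if (chr[i] == "chrX" && length(female_cases))
                               sample(female_cases, 1) else sample(cases, 1))
        }
      }
    }
    nb <- length(accepted_pos)
    if (nb < n_background)
      warning("placed ", nb, " of ", n_background,
              " background variants (spacing-limited)")
    al <- .draw_snv_alleles(nb)
    singleton <- runif(nb) < af$singleton_prob
    afs <- ifelse(singleton, 0, round(rbeta(nb, af$beta_shape1, af$beta_shape2), 6))
    carried <- runif(nb) < 0.5
    gt_idx <- ifelse(carried, "0/1", "0/0")
    from_mother <- runif(nb) < 0.5
    gt_mo <- ifelse(carried & from_mother, "0/1",
                    ifelse(!carried & from_mother, "0/1", "0/0"))
    gt_fa <- ifelse(carried & !from_mother, "0/1",
                    ifelse(!carried & !from_mother, "0/1", "0/0"))
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = accepted_case, chrom = accepted_chrom, pos = accepted_pos,
      ref = al$ref, alt = al$alt, gt_index = gt_idx, gt_mother = gt_mo,
      gt_father = gt_fa, af = afs, cadd = round(runif(nb, 0, 15), 1),
      truncating = FALSE, stringsAsFactors = FALSE)
  }

  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), gt_index = character(),
               gt_mother = character(), gt_father = character(), af = numeric(),
               cadd = numeric(), truncating = logical(), stringsAsFactors = FALSE)
  variants <- variants[order(variants$case_id, variants$chrom, variants$pos), ,
                       drop = FALSE]
  rownames(variants) <- NULL

  ## --- structural variants
  svs <- .plant_svs(genome, cases, plant)
  truth$svs <- svs$truth
  sv_df <- svs$records

  ## --- polyalanine repeat-allele sequences
  anchor <- paste(sample(.bases, 24, replace = TRUE), collapse = "")
  flank3 <- paste(sample(.bases, 24, replace = TRUE), collapse = "")
  ref_ala <- plant$repeat_reference_ala
  rep_rows <- list(); alleles <- character(0)
  if (length(plant$repeat_deltas)) {
    case <- sample(cases, 1)
    for (allele in names(plant$repeat_deltas)) {
      delta <- plant$repeat_deltas[[allele]]
      tract <- paste(sample(.ala_codons, ref_ala + delta, replace = TRUE),
                     collapse = "")
      id <- paste0(case, "_", allele, "_allele")
      alleles[id] <- paste0(anchor, tract, flank3)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        case_id = case, allele = allele, delta = as.integer(delta),
        reference_ala = ref_ala, fasta_id = id, stringsAsFactors = FALSE)
    }
  }
  truth$repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(case_id = character(), allele = character(), delta = integer(),
               reference_ala = integer(), fasta_id = character(),
               stringsAsFactors = FALSE)

  structure(list(variants = variants, svs = sv_df, trios = trios,
                 repeat_alleles = alleles, repeat_anchor = anchor,
                 repeat_reference_ala = ref_ala, truth = truth, mask = mask,
                 seed = seed),
            class = "trio_cohort")
}

## Internal: plant the SV slate. Categories map to the filter cascade's
## expected outcomes under default settings (standard inheritance mode).
.plant_svs <- function(genome, cases, plant) {
  rows <- list()
  next_id <- 1L
  tads <- genome$tads
  chroms <- genome$chromosomes
  pick_span <- function(min_w, max_w) {
    ci <- sample.int(nrow(chroms), 1, prob = chroms$length)
    w <- round(runif(1, min_w, max_w))
    s <- sample.int(max(1L, chroms$length[ci] - w), 1)
    list(chrom = chroms$name[ci], start = s, end = s + w - 1L)
  }
  add <- function(case, type, span, support, inheritance, category,
                  expect_retained, relative = FALSE) {
    carrier_mother <- inheritance == "maternal"
    carrier_father <- inheritance == "paternal"
    rows[[length(rows) + 1L]] <<- data.frame(
      sv_id = sprintf("sv%03d", next_id), case_id = case, sv_type = type,
      chrom = span$chrom, start = as.integer(span$start), end = as.integer(span$end),
      support_reads = as.integer(support),
      carrier_index = TRUE, carrier_mother = carrier_mother,
      carrier_father = carrier_father,
      carried_by_affected_relative = relative,
      inheritance = inheritance, category = category,
      expect_retained = expect_retained, stringsAsFactors = FALSE)
    next_id <<- next_id + 1L
  }
  ## causal-like: de novo inversion spanning a TAD boundary
  for (k in seq_len(plant$n_sv_causal)) {
    ## centre the span on a junction between adjacent abutting TADs
    tt <- sort(tads)
    same_chrom <- as.character(GenomicRanges::seqnames(tt))[-1] ==
      as.character(GenomicRanges::seqnames(tt))[-length(tt)]
    junctions <- which(same_chrom)
    j <- sample(junctions, 1)
    b <- GenomicRanges::end(tt)[j]
    w <- round(runif(1, 5e4, 1.2e5))
    span <- list(chrom = as.character(GenomicRanges::seqnames(tt))[j],
                 start = max(1L, b - w %/% 2L), end = b + w %/% 2L)
    add(sample(cases, 1), "INV", span, sample(6:15, 1), "de_novo",
        "causal_inv_tad_boundary", TRUE)
  }
  for (k in seq_len(plant$n_sv_inherited_unaffected))
    add(sample(cases, 1), sample(c("DEL", "DUP"), 1), pick_span(2e3, 5e4),
        sample(6:15, 1), sample(c("maternal", "paternal"), 1),
        "inherited_unaffected", FALSE)
  for (k in seq_len(plant$n_sv_affected_relative))
    add(sample(cases, 1), "INV", pick_span(8e4, 1.2e5), sample(6:15, 1),
        "maternal", "affected_relative", FALSE, relative = TRUE)
  for (k in seq_len(plant$n_sv_small))
    add(sample(cases, 1), "DEL", pick_span(200, 1400), sample(6:15, 1),
        "de_novo", "below_min_size", FALSE)
  for (k in seq_len(plant$n_sv_low_support))
    add(sample(cases, 1), sample(c("DEL", "INV"), 1), pick_span(2e3, 5e4), 1L,
        "de_novo", "low_support", FALSE)
  for (k in seq_len(plant$n_sv_pass_mix)) {
    type <- sample(c("DEL", "DUP", "INV", "BND"), 1)
    span <- if (type == "BND") {
      s <- pick_span(2e3, 2e3); s$end <- s$start + 1L; s
    } else pick_span(2e3, 6e4)
    add(sample(cases, 1), type, span, sample(6:15, 1), "de_novo",
        "pass_mix", TRUE)
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sv_id = character(), case_id = character(), sv_type = character(),
               chrom = character(), start = integer(), end = integer(),
               support_reads = integer(), carrier_index = logical(),
               carrier_mother = logical(), carrier_father = logical(),
               carried_by_affected_relative = logical(),
               inheritance = character(), category = character(),
               expect_retained = logical(), stringsAsFactors = FALSE)
  list(records = records,
       truth = records[, c("sv_id", "case_id", "sv_type", "chrom", "start",
                           "end", "support_reads", "inheritance", "category",
                           "expect_retained")])
}
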