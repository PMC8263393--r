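#' Settings for the synthetic toy genome
#'
#' The generator emulates the track universe the prioritization pipeline
#' consumes: a small multi-chromosome genome, abutting TADs, a
#' piecewise-constant conservation track (multi-bp conserved runs, as a
#' phyloP segmentation would give), chromatin peaks standing in for
#' H3K27ac, validated enhancer elements with tissue labels, and a gene
#' catalog with limb/pLI/recessive annotations.
#'
#' @param n_chromosomes number of chromosomes (>= 1). When
#'   \code{include_x} is TRUE the last one is named \code{chrX}.
#' @param chrom_length chromosome length(s) in bp, recycled. Default 2 Mb.
#' @param include_x name the last chromosome \code{chrX} (needed by the
#'   hemizygous screen).
#' @param n_genes number of genes.
#' @param limb_fraction fraction of genes flagged as limb-development genes.
#' @param recessive_fraction fraction of limb genes additionally flagged
#'   with a recessive limb phenotype.
#' @param gene_width_range gene body width range in bp.
#' @param tad_size_range TAD size range in bp; TADs tile each chromosome
#'   with abutting boundaries.
#' @param cons_segment_mean mean length (bp) of the piecewise-constant
#'   conservation segments.
#' @param cons_conserved_prob probability that a segment is conserved
#'   (score above the usual phyloP cutoff).
#' @param peak_density peaks per Mb.
#' @param peak_width_range peak width range in bp.
#' @param n_enhancers number of validated enhancer elements.
#' @param enhancer_width_range enhancer width range in bp.
#' @param limb_enhancer_prob probability an enhancer is active in limb.
#' @return list of class \code{genome_config}.
#' @export
genome_config <- function(n_chromosomes = 3L,
                          chrom_length = 2e6,
                          include_x = TRUE,
                          n_genes = 40L,
                          limb_fraction = 0.35,
                          recessive_fraction = 0.3,
                          gene_width_range = c(5e3, 3e4),
                          tad_size_range = c(1.5e5, 3.5e5),
                          cons_segment_mean = 40,
                          cons_conserved_prob = 0.12,
                          peak_density = 25,
                          peak_width_range = c(300, 2000),
                          n_enhancers = 12L,
                          enhancer_width_range = c(400, 2000),
                          limb_enhancer_prob = 0.6) {
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "n_genes", "n_enhancers")
  for (f in counts) if (cfg[[f]] < 0) stop("invalid config: ", f, " must be >= 0")
  if (cfg$n_chromosomes < 1) stop("invalid config: n_chromosomes must be >= 1")
  if (any(cfg$chrom_length < 1e3)) stop("invalid config: chrom_length must be >= 1 kb")
  for (f in c("limb_fraction", "recessive_fraction", "cons_conserved_prob",
              "limb_enhancer_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config: ", f, " must be in [0, 1]")
  structure(cfg, class = "genome_config")
}

#' Generate a synthetic toy genome with annotation tracks
#'
#' Deterministic for a fixed (config, seed): calling twice with the same
#' arguments yields byte-identical models.
#'
#' @param config a \code{\link{genome_config}}.
#' @param seed integer random seed (required).
#' @return list of class \code{genome_model}: \code{chromosomes}
#'   (data.frame name/length), \code{genes}, \code{exons}, \code{tads},
#'   \code{conservation} (full-coverage score segments), \code{peaks},
#'   \code{enhancers} — all \code{GRanges}.
#' @export
make_genome <- function(config = genome_config(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  cfg <- config
  nchr <- cfg$n_chromosomes
  lens <- rep_len(cfg$chrom_length, nchr)
  names_chr <- paste0("chr", seq_len(nchr))
  if (cfg$include_x) names_chr[nchr] <- "chrX"
  chromosomes <- data.frame(name = names_chr, length = as.integer(lens),
                            stringsAsFactors = FALSE)
  si <- GenomeInfoDb::Seqinfo(seqnames = names_chr, seqlengths = as.integer(lens))

  empty_gr <- function(...) {
    g <- GenomicRanges::GRanges(seqinfo = si)
    extra <- list(...)
    for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
    g
  }

  ## TADs tile each chromosome with abutting boundaries
  tad_list <- lapply(seq_len(nchr), function(ci) {
    len <- lens[ci]
    sizes <- integer(0); tot <- 0
    while (tot < len) {
      s <- round(runif(1, cfg$tad_size_range[1], cfg$tad_size_range[2]))
      sizes <- c(sizes, s); tot <- tot + s
    }
    ends <- pmin(cumsum(sizes), len)
    starts <- c(1, head(ends, -1) + 1)
    keep <- starts <= ends
    gintervals(names_chr[ci], starts[keep], ends[keep])
  })
  tads <- suppressWarnings(do.call(c, tad_list))
  GenomeInfoDb::seqlevels(tads) <- names_chr
  GenomeInfoDb::seqlengths(tads) <- as.integer(lens)
  tads$id <- paste0("tad_", seq_along(tads))

  ## genes with 1-3 exons each
  genes <- empty_gr(gene_id = character(0), limb_flag = logical(0),
                    pli = numeric(0), recessive_flag = logical(0))
  exons <- empty_gr(gene_id = character(0))
  if (cfg$n_genes > 0) {
    gchr <- sample(names_chr, cfg$n_genes, replace = TRUE,
                   prob = lens / sum(lens))
    gw <- round(runif(cfg$n_genes, cfg$gene_width_range[1], cfg$gene_width_range[2]))
    gstart <- vapply(seq_len(cfg$n_genes), function(i) {
      round(runif(1, 1, lens[match(gchr[i], names_chr)] - gw[i]))
    }, numeric(1))
    limb <- runif(cfg$n_genes) < cfg$limb_fraction
    if (cfg$limb_fraction > 0 && !any(limb)) limb[sample.int(cfg$n_genes, 1)] <- TRUE
    ## bimodal pLI as in real catalogs: most genes tolerant, some intolerant
    pli <- round(rbeta(cfg$n_genes, 0.25, 0.25), 4)
    rec <- limb & runif(cfg$n_genes) < cfg$recessive_fraction
    if (cfg$recessive_fraction > 0 && any(limb) && !any(rec))
      rec[sample(which(limb), 1)] <- TRUE
    ## the LoF screen needs at least one clearly intolerant gene
    if (!any(pli > 0.9)) pli[sample.int(cfg$n_genes, 1)] <- 0.99
    genes <- gintervals(gchr, gstart, gstart + gw - 1,
                        gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
                        limb_flag = limb, pli = pli, recessive_flag = rec)
    GenomeInfoDb::seqlevels(genes) <- names_chr
    GenomeInfoDb::seqlengths(genes) <- as.integer(lens)
    exon_rows <- lapply(seq_along(genes), function(i) {
      n_ex <- sample(1:3, 1)
      w <- GenomicRanges::width(genes)[i]
      ex_w <- pmax(60L, round(runif(n_ex, 100, 400)))
      ex_s <- sort(sample.int(max(1L, w - max(ex_w)), n_ex))
      s <- GenomicRanges::start(genes)[i] + ex_s
      ## merge within the gene so every gene keeps >= 1 exon of its own
      ex <- GenomicRanges::reduce(
        gintervals(as.character(GenomicRanges::seqnames(genes))[i],
                   s, pmin(s + ex_w - 1, GenomicRanges::end(genes)[i])))
      ex$gene_id <- genes$gene_id[i]
      ex
    })
    exons <- suppressWarnings(do.call(c, exon_rows))
    GenomeInfoDb::seqlevels(exons) <- names_chr
    GenomeInfoDb::seqlengths(exons) <- as.integer(lens)
  }

  ## piecewise-constant conservation segments covering every base
  cons_list <- lapply(seq_len(nchr), function(ci) {
    len <- lens[ci]
    n_seg <- ceiling(len / cfg$cons_segment_mean * 1.6) + 10
    sizes <- stats::rgeom(n_seg, 1 / cfg$cons_segment_mean) + 1L
    while (sum(sizes) < len)
      sizes <- c(sizes, stats::rgeom(n_seg, 1 / cfg$cons_segment_mean) + 1L)
    ends <- pmin(cumsum(as.numeric(sizes)), len)
    keep <- c(TRUE, head(ends, -1) < len) & ends >= 1
    ends <- ends[keep]
    ends <- ends[!duplicated(ends)]
    starts <- c(1, head(ends, -1) + 1)
    n <- length(starts)
    conserved <- runif(n) < cfg$cons_conserved_prob
    score <- ifelse(conserved, runif(n, 1.4, 6), runif(n, -2, 1.2))
    gintervals(names_chr[ci], starts, ends, score = round(score, 3))
  })
  conservation <- suppressWarnings(do.call(c, cons_list))
  GenomeInfoDb::seqlevels(conservation) <- names_chr
  GenomeInfoDb::seqlengths(conservation) <- as.integer(lens)

  ## H3K27ac-like peaks
  n_peaks <- round(cfg$peak_density * sum(lens) / 1e6)
  peaks <- empty_gr()
  if (n_peaks > 0) {
    pchr <- sample(names_chr, n_peaks, replace = TRUE, prob = lens / sum(lens))
    pw <- round(runif(n_peaks, cfg$peak_width_range[1], cfg$peak_width_range[2]))
    ps <- vapply(seq_len(n_peaks), function(i) {
      round(runif(1, 1, lens[match(pchr[i], names_chr)] - pw[i]))
    }, numeric(1))
    peaks <- GenomicRanges::reduce(gintervals(pchr, ps, ps + pw - 1))
    GenomeInfoDb::seqlevels(peaks) <- names_chr
    GenomeInfoDb::seqlengths(peaks) <- as.integer(lens)
  }

  ## validated enhancer elements with tissue labels
  enhancers <- empty_gr(id = character(0), tissues = character(0))
  if (cfg$n_enhancers > 0) {
    tissue_pool <- c("heart", "forebrain", "neural_tube")
    echr <- sample(names_chr, cfg$n_enhancers, replace = TRUE, prob = lens / sum(lens))
    ew <- round(runif(cfg$n_enhancers, cfg$enhancer_width_range[1],
                      cfg$enhancer_width_range[2]))
    es <- vapply(seq_len(cfg$n_enhancers), function(i) {
      round(runif(1, 1, lens[match(echr[i], names_chr)] - ew[i]))
    }, numeric(1))
    is_limb <- runif(cfg$n_enhancers) < cfg$limb_enhancer_prob
    if (cfg$limb_enhancer_prob > 0 && !any(is_limb))
      is_limb[sample.int(cfg$n_enhancers, 1)] <- TRUE
    tissues <- vapply(seq_len(cfg$n_enhancers), function(i) {
      t <- sample(tissue_pool, sample(0:2, 1))
      if (is_limb[i]) t <- c("limb", t)
      paste(sort(unique(t)), collapse = ",")
    }, character(1))
    enhancers <- gintervals(echr, es, es + ew - 1,
                            id = sprintf("enh%03d", seq_len(cfg$n_enhancers)),
                            tissues = tissues)
    GenomeInfoDb::seqlevels(enhancers) <- names_chr
    GenomeInfoDb::seqlengths(enhancers) <- as.integer(lens)
  }

  structure(list(config = cfg, seed = seed, chromosomes = chromosomes,
                 genes = genes, exons = exons, tads = tads,
                 conservation = conservation, peaks = peaks,
                 enhancers = enhancers),
            class = "genome_model")
}

#' Total size of a genome model in bp
#' @param genome a \code{genome_model}.
#' @return numeric bp.
#' @export
genome_size <- function(genome) sum(as.numeric(genome$chromosomes$length))

#' Validate a genome model against its structural invariants
#'
#' Independent re-scan used by tests: chromosome lengths positive, every
#' annotation interval within its chromosome bounds, TADs per chromosome
#' non-overlapping, pLI within [0, 1].
#'
#' @param genome a \code{genome_model}.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(all(genome$chromosomes$length > 0))
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  in_bounds <- function(gr) {
    if (!length(gr)) return(TRUE)
    chr <- as.character(GenomicRanges::seqnames(gr))
    all(chr %in% names(lens)) &&
      all(GenomicRanges::start(gr) >= 1) &&
      all(GenomicRanges::end(gr) <= lens[chr])
  }
  for (track in c("genes", "exons", "tads", "conservation", "peaks", "enhancers"))
    if (!in_bounds(genome[[track]])) stop("track out of chromosome bounds: ", track)
  ## TADs on one chromosome must not overlap
  ov <- GenomicRanges::findOverlaps(genome$tads, drop.self = TRUE)
  if (length(ov)) stop("overlapping TADs")
  if (length(genome$genes) &&
      (any(genome$genes$pli < 0) || any(genome$genes$pli > 1)))
    stop("pLI outside [0, 1]")
  invisible(TRUE)
}

#' Build the regulome mask directly from a genome model
#'
#' Convenience wrapper chaining \code{\link{conserved_intervals}},
#' \code{\link{limb_tads}} and \code{\link{build_regulome}}.
#'
#' @param genome a \code{genome_model}.
#' @param cfg a \code{\link{regulome_config}}.
#' @return a \code{regulome_mask}.
#' @export
genome_regulome <- function(genome, cfg = regulome_config()) {
  build_regulome(conserved_intervals(genome$conservation, cfg$phylop_threshold),
                 limb_tads(genome$tads, genome$genes, cfg$gene_tad_mode),
                 genome$peaks, genome$enhancers, cfg,
                 genome_size = genome_size(genome))
}
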