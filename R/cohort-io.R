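## VCF emitter for the toy cohorts.  Reading always goes through vcfR;
## writing these small fixed-layout records is done directly.

.vcf_header <- function(chromosomes, samples, sv = FALSE) {
  c("##fileformat=VCFv4.2",
    "##source=trioregulome-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", chromosomes$name, chromosomes$length),
    if (!sv) c(
      '##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency">',
      '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD deleteriousness score">',
      '##INFO=<ID=TRUNC,Number=0,Type=Flag,Description="Truncating consequence">')
    else c(
      '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Structural variant type">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="End coordinate">',
      '##INFO=<ID=SUPP,Number=1,Type=Integer,Description="Supporting informative reads">',
      '##INFO=<ID=CASE,Number=1,Type=String,Description="Case identifier">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

.write_trio_vcf <- function(variants, chromosomes, case_id, path) {
  samples <- paste0(case_id, c("_index", "_mother", "_father"))
  v <- variants[variants$case_id == case_id, , drop = FALSE]
  v <- v[order(match(v$chrom, chromosomes$name), v$pos), , drop = FALSE]
  fmt <- function(x) vapply(x, function(e) format(e, scientific = FALSE, trim = TRUE),
                            character(1))
  info <- sprintf("AF=%s;CADD=%s", fmt(v$af), fmt(v$cadd))
  info[is.na(v$af)] <- sprintf("CADD=%s", fmt(v$cadd[is.na(v$af)]))
  info <- ifelse(v$truncating, paste0(info, ";TRUNC"), info)
  recs <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s\t%s\t%s",
                  v$chrom, v$pos, paste0("snv", seq_len(nrow(v))),
                  v$ref, v$alt, info, v$gt_index, v$gt_mother, v$gt_father)
  writeLines(c(.vcf_header(chromosomes, samples), recs), path)
}

.write_sv_vcf <- function(svs, chromosomes, path) {
  s <- svs[order(match(svs$chrom, chromosomes$name), svs$start), , drop = FALSE]
  gt <- function(carrier) ifelse(carrier, "0/1", "0/0")
  recs <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SUPP=%d;CASE=%s\tGT\t%s\t%s\t%s",
                  s$chrom, s$start, s$sv_id, s$sv_type, s$sv_type, s$end,
                  s$support_reads, s$case_id, gt(s$carrier_index),
                  gt(s$carrier_mother), gt(s$carrier_father))
  writeLines(c(.vcf_header(chromosomes, c("index", "mother", "father"), sv = TRUE),
               recs), path)
}

#' Write a synthetic cohort and its genome tracks to disk
#'
#' Emits per-trio multi-sample VCFs (GT per sample; AF/CADD/TRUNC INFO
#' keys), an SV VCF plus a TSV dialect of the same records, BED files for
#' TADs/peaks/enhancers and the regulome mask, a bedGraph conservation
#' track, TSV gene/exon catalogs, repeat-allele FASTA, a pedigree-style
#' trio table and the machine-readable truth ledger (one TSV per event
#' class).
#'
#' @param cohort a \code{trio_cohort} from \code{\link{make_cohort}}.
#' @param genome the \code{genome_model} the cohort was generated on.
#' @param outdir output directory (created if absent).
#' @return \code{outdir}, invisibly.
#' @export
write_cohort <- function(cohort, genome, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chromosomes <- genome$chromosomes
  utils::write.table(chromosomes, file.path(outdir, "chromosomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## annotation tracks
  tads <- genome$tads; tads$name <- tads$id
  rtracklayer::export(tads, file.path(outdir, "tads.bed"), format = "BED")
  rtracklayer::export(genome$peaks, file.path(outdir, "peaks.bed"), format = "BED")
  enh <- genome$enhancers
  if (length(enh)) enh$name <- enh$id
  rtracklayer::export(enh, file.path(outdir, "enhancers.bed"), format = "BED")
  utils::write.table(
    data.frame(id = genome$enhancers$id, tissues = genome$enhancers$tissues),
    file.path(outdir, "enhancer_tissues.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  rtracklayer::export(genome$conservation, file.path(outdir, "conservation.bedGraph"),
                      format = "bedGraph")
  genes_df <- data.frame(gene_id = genome$genes$gene_id,
                         chrom = as.character(GenomicRanges::seqnames(genome$genes)),
                         start = GenomicRanges::start(genome$genes),
                         end = GenomicRanges::end(genome$genes),
                         limb_flag = genome$genes$limb_flag,
                         pli = genome$genes$pli,
                         recessive_flag = genome$genes$recessive_flag)
  utils::write.table(genes_df, file.path(outdir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  exons_df <- data.frame(gene_id = genome$exons$gene_id,
                         chrom = as.character(GenomicRanges::seqnames(genome$exons)),
                         start = GenomicRanges::start(genome$exons),
                         end = GenomicRanges::end(genome$exons))
  utils::write.table(exons_df, file.path(outdir, "exons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## regulome mask as built from this genome (provenance in the name field)
  sites <- cohort$mask$sites
  if (length(sites)) sites$name <- sites$provenance
  rtracklayer::export(sites, file.path(outdir, "regulome_mask.bed"), format = "BED")

  ## trio VCFs and pedigree-style table
  for (case in cohort$trios$case_id)
    .write_trio_vcf(cohort$variants, chromosomes, case,
                    file.path(outdir, paste0(case, ".vcf")))
  utils::write.table(cohort$trios, file.path(outdir, "trios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## SVs: VCF and TSV dialect
  .write_sv_vcf(cohort$svs, chromosomes, file.path(outdir, "svs.vcf"))
  utils::write.table(
    cohort$svs[, c("sv_id", "case_id", "sv_type", "chrom", "start", "end",
                   "support_reads", "carrier_index", "carrier_mother",
                   "carrier_father", "carried_by_affected_relative")],
    file.path(outdir, "svs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  ## repeat alleles
  if (length(cohort$repeat_alleles)) {
    seqs <- Biostrings::DNAStringSet(cohort$repeat_alleles)
    Biostrings::writeXStringSet(seqs, file.path(outdir, "repeat_alleles.fasta"))
  }

  ## truth ledger
  for (nm in names(cohort$truth))
    utils::write.table(cohort$truth[[nm]],
                       file.path(outdir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Read one trio VCF into the package's variant table
#'
#' Parsing goes through \pkg{vcfR}; AF, CADD and the TRUNC flag are taken
#' from INFO and genotypes from the GT FORMAT field.
#'
#' @param path VCF file path.
#' @param case_id case identifier; defaults to the file stem.
#' @return variant data.frame in the package's canonical layout.
#' @export
read_trio_vcf <- function(path, case_id = sub("\\.vcf$", "", basename(path))) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  empty <- data.frame(case_id = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(), gt_index = character(),
                      gt_mother = character(), gt_father = character(),
                      af = numeric(), cadd = numeric(), truncating = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  role_col <- function(role) {
    hit <- grep(paste0("_", role, "$"), samples)
    if (length(hit) != 1) NA_integer_ else hit
  }
  ri <- role_col("index"); rm_ <- role_col("mother"); rf <- role_col("father")
  info_num <- function(key) suppressWarnings(as.numeric(vcfR::extract.info(vcf, key)))
  data.frame(case_id = case_id, chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             gt_index = if (is.na(ri)) NA_character_ else unname(gt[, ri]),
             gt_mother = if (is.na(rm_)) NA_character_ else unname(gt[, rm_]),
             gt_father = if (is.na(rf)) NA_character_ else unname(gt[, rf]),
             af = info_num("AF"), cadd = info_num("CADD"),
             truncating = grepl("(^|;)TRUNC(;|$)", vcfR::getINFO(vcf)),
             stringsAsFactors = FALSE)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param outdir cohort directory.
#' @return list with \code{chromosomes}, annotation tracks (\code{GRanges}),
#'   \code{variants}, \code{svs}, \code{trios}, \code{truth},
#'   \code{repeat_alleles}.
#' @export
read_cohort <- function(outdir) {
  chromosomes <- utils::read.delim(file.path(outdir, "chromosomes.tsv"),
                                   stringsAsFactors = FALSE)
  si <- GenomeInfoDb::Seqinfo(seqnames = chromosomes$name,
                              seqlengths = chromosomes$length)
  imp <- function(file, format) {
    gr <- rtracklayer::import(file.path(outdir, file), format = format)
    GenomeInfoDb::seqlevels(gr) <- chromosomes$name
    GenomeInfoDb::seqlengths(gr) <- chromosomes$length
    GenomicRanges::strand(gr) <- "*"
    gr
  }
  tads <- imp("tads.bed", "BED"); tads$id <- tads$name
  peaks <- imp("peaks.bed", "BED")
  enhancers <- imp("enhancers.bed", "BED")
  if (length(enhancers)) {
    enhancers$id <- enhancers$name
    tiss <- utils::read.delim(file.path(outdir, "enhancer_tissues.tsv"),
                              stringsAsFactors = FALSE)
    enhancers$tissues <- tiss$tissues[match(enhancers$id, tiss$id)]
  }
  conservation <- imp("conservation.bedGraph", "bedGraph")
  genes_df <- utils::read.delim(file.path(outdir, "genes.tsv"),
                                stringsAsFactors = FALSE)
  genes <- gintervals(genes_df$chrom, genes_df$start, genes_df$end,
                      gene_id = genes_df$gene_id, limb_flag = genes_df$limb_flag,
                      pli = genes_df$pli, recessive_flag = genes_df$recessive_flag)
  exons_df <- utils::read.delim(file.path(outdir, "exons.tsv"),
                                stringsAsFactors = FALSE)
  exons <- gintervals(exons_df$chrom, exons_df$start, exons_df$end,
                      gene_id = exons_df$gene_id)
  for (g in c("genes", "exons")) {
    gr <- get(g)
    GenomeInfoDb::seqlevels(gr) <- chromosomes$name
    GenomeInfoDb::seqlengths(gr) <- chromosomes$length
    assign(g, gr)
  }
  trios <- utils::read.delim(file.path(outdir, "trios.tsv"),
                             stringsAsFactors = FALSE)
  variants <- do.call(rbind, lapply(trios$case_id, function(case)
    read_trio_vcf(file.path(outdir, paste0(case, ".vcf")), case)))
  svs <- utils::read.delim(file.path(outdir, "svs.tsv"), stringsAsFactors = FALSE)
  svs$inheritance <- ifelse(!svs$carrier_mother & !svs$carrier_father, "de_novo",
                            ifelse(svs$carrier_mother & !svs$carrier_father,
                                   "maternal",
                                   ifelse(svs$carrier_father & !svs$carrier_mother,
                                          "paternal", "unknown")))
  truth_files <- list.files(outdir, pattern = "^truth_.*\\.tsv$")
  truth <- lapply(truth_files, function(f)
    utils::read.delim(file.path(outdir, f), stringsAsFactors = FALSE))
  names(truth) <- sub("^truth_(.*)\\.tsv$", "\\1", truth_files)
  repeat_alleles <- character(0)
  fa <- file.path(outdir, "repeat_alleles.fasta")
  if (file.exists(fa)) {
    seqs <- Biostrings::readDNAStringSet(fa)
    repeat_alleles <- setNames(as.character(seqs), names(seqs))
  }
  list(chromosomes = chromosomes, tads = tads, peaks = peaks,
       enhancers = enhancers, conservation = conservation, genes = genes,
       exons = exons, trios = trios, variants = variants, svs = svs,
       truth = truth, repeat_alleles = repeat_alleles, seqinfo = si)
}
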