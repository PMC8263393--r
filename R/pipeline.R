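#' Full-pipeline run configuration
#'
#' Either a simulation block (genome/cohort generator settings and a seed)
#' or an input directory previously written by \code{\link{write_cohort}}.
#'
#' @param input_dir cohort directory to ingest; \code{NULL} to simulate.
#' @param genome \code{\link{genome_config}} for simulation.
#' @param n_trios,plant,af,n_background cohort generator settings.
#' @param seed integer seed (required when simulating; recorded always).
#' @param regulome \code{\link{regulome_config}}.
#' @param snv \code{\link{snv_filter_config}}.
#' @param sv \code{\link{sv_filter_config}}.
#' @param sv_mode inheritance mode, \code{"standard"} or
#'   \code{"affected_relative"}.
#' @param outdir optional directory for stage TSVs and the JSON summary.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(input_dir = NULL, genome = genome_config(),
                       n_trios = 12L, plant = plant_spec(), af = af_model(),
                       n_background = 6000L, seed = 1L,
                       regulome = regulome_config(), snv = snv_filter_config(),
                       sv = sv_filter_config(),
                       sv_mode = c("standard", "affected_relative"),
                       outdir = NULL) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(list(input_dir = input_dir, genome = genome, n_trios = n_trios,
                 plant = plant, af = af, n_background = n_background,
                 seed = as.integer(seed), regulome = regulome, snv = snv,
                 sv = sv, sv_mode = match.arg(sv_mode), outdir = outdir),
            class = "run_config")
}

#' Run the prioritization pipeline end to end
#'
#' Stage order: simulate or ingest the cohort; build the regulome mask;
#' classify coding context; restrict to index-carried calls; rare filter;
#' regulome intersection; de novo, hemizygous-X, cross-case proximity,
#' double-hit and in-trans analyses; LoF double-hit gene screen; SV
#' size/support cascade with escalation and inheritance exclusion plus
#' annotation.  Every stage reports kept/removed counts; the result is
#' deterministic given the configuration and seed.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return list of class \code{run_summary}: \code{counts},
#'   \code{regulome_stats}, \code{candidates} (de novo regulome SNVs,
#'   proximity pairs, double hits, trans pairs, phase-unknown trans pairs,
#'   hemizygous-X, LoF genes, retained SVs with annotation),
#'   \code{sv_type_counts}, \code{params}, and (when simulating)
#'   \code{truth}.
#' @export
run_pipeline <- function(cfg = run_config()) {
  simulate <- is.null(cfg$input_dir)
  if (simulate) {
    genome <- make_genome(cfg$genome, seed = cfg$seed)
    cohort <- make_cohort(genome, n_trios = cfg$n_trios, plant = cfg$plant,
                          af = cfg$af, n_background = cfg$n_background,
                          seed = cfg$seed + 1L, regulome_cfg = cfg$regulome)
    tracks <- list(tads = genome$tads, peaks = genome$peaks,
                   enhancers = genome$enhancers, genes = genome$genes,
                   exons = genome$exons, conservation = genome$conservation,
                   chromosomes = genome$chromosomes)
    variants <- cohort$variants
    svs <- cohort$svs
    trios <- cohort$trios
    truth <- cohort$truth
  } else {
    dat <- read_cohort(cfg$input_dir)
    tracks <- dat
    variants <- dat$variants
    svs <- dat$svs
    trios <- dat$trios
    truth <- dat$truth
  }
  gsize <- sum(as.numeric(tracks$chromosomes$length))

  conserved <- conserved_intervals(tracks$conservation, cfg$regulome$phylop_threshold)
  ltads <- limb_tads(tracks$tads, tracks$genes, cfg$regulome$gene_tad_mode)
  mask <- build_regulome(conserved, ltads, tracks$peaks, tracks$enhancers,
                         cfg$regulome, genome_size = gsize)

  counts <- list(n_trios = nrow(trios), n_variants = nrow(variants))

  variants <- classify_coding_context(variants, tracks$exons,
                                      cfg$snv$coding_flank_bp)
  carried <- variants[.gt_alt_count(variants$gt_index) >= 1L &
                        !.gt_missing(variants$gt_index), , drop = FALSE]
  counts$n_index_carried <- nrow(carried)
  coding <- carried[carried$coding_context == "coding_proximal", , drop = FALSE]
  noncoding <- carried[carried$coding_context == "noncoding", , drop = FALSE]
  counts$n_coding <- nrow(coding)
  counts$n_noncoding <- nrow(noncoding)

  rare_nc <- filter_rare(noncoding, cfg$snv$rare_af_noncoding)
  counts$n_rare_noncoding <- nrow(rare_nc)
  counts$n_rare_noncoding_reported <- nrow(filter_rare(noncoding,
                                                       cfg$snv$rare_af_reported))
  in_mask <- mask_contains(mask, rare_nc)
  counts$n_in_regulome <- nrow(in_mask)

  ## trio-wise analyses
  by_case <- split(seq_len(nrow(carried)), carried$case_id)
  de_novo <- do.call(rbind, lapply(by_case, function(i)
    detect_de_novo(carried[i, , drop = FALSE], cfg$snv$min_gq)))
  rownames(de_novo) <- NULL
  dn_rare_nc <- filter_rare(de_novo[de_novo$coding_context == "noncoding", ,
                                    drop = FALSE], cfg$snv$rare_af_noncoding)
  dn_regulome <- mask_contains(mask, dn_rare_nc)
  counts$n_de_novo <- nrow(de_novo)
  counts$n_de_novo_regulome <- nrow(dn_regulome)

  hemi <- do.call(rbind, lapply(trios$case_id, function(case) {
    i <- which(carried$case_id == case)
    hemizygous_x_candidates(carried[i, , drop = FALSE],
                            trios$index_sex[trios$case_id == case])
  }))
  rownames(hemi) <- NULL
  counts$n_hemizygous_x <- nrow(hemi)

  pairs <- proximity_pairs(rare_nc, cfg$snv, tracks$enhancers, mask)
  counts$n_proximity_pairs <- nrow(pairs)
  dhits <- double_hits(pairs)
  counts$n_double_hits <- nrow(dhits)

  trans_cand <- list(); trans_unknown <- list()
  for (case in trios$case_id) {
    res <- trans_screen(variants[variants$case_id == case, , drop = FALSE],
                        tracks$genes, tracks$tads, conserved, cfg$snv)
    trans_cand[[case]] <- res$candidates
    trans_unknown[[case]] <- res$phase_unknown
  }
  trans_cand <- do.call(rbind, trans_cand); rownames(trans_cand) <- NULL
  trans_unknown <- do.call(rbind, trans_unknown); rownames(trans_unknown) <- NULL
  counts$n_trans_candidates <- nrow(trans_cand)

  rare_coding <- filter_rare(coding, cfg$snv$rare_af_reported)
  lof <- lof_double_hit_genes(rare_coding, tracks$genes, cfg$snv)
  counts$n_lof_double_hit_genes <- nrow(lof)

  ## structural variants
  sv_kept <- list(); sv_removed <- list(); escalated_cases <- character(0)
  for (case in unique(svs$case_id)) {
    s <- svs[svs$case_id == case, , drop = FALSE]
    f <- filter_svs(s, cfg$sv)
    if (f$escalated) escalated_cases <- c(escalated_cases, case)
    ped <- trios[trios$case_id == case, ]
    inh <- inheritance_filter(f$kept, as.list(ped), mode = cfg$sv_mode)
    sv_kept[[case]] <- inh$kept
    sv_removed[[case]] <- rbind(f$removed, inh$removed)
  }
  sv_kept <- do.call(rbind, sv_kept); rownames(sv_kept) <- NULL
  sv_removed <- do.call(rbind, sv_removed); rownames(sv_removed) <- NULL
  counts$n_svs <- nrow(svs)
  counts$n_svs_retained <- if (is.null(sv_kept)) 0L else nrow(sv_kept)
  sv_types <- classify_sv_types(if (is.null(sv_kept)) svs[0, ] else sv_kept)
  annotations <- if (!is.null(sv_kept) && nrow(sv_kept)) {
    lapply(seq_len(nrow(sv_kept)), function(i)
      c(list(sv_id = sv_kept$sv_id[i]),
        annotate_sv(sv_kept[i, ], tracks$tads, tracks$genes,
                    tracks$enhancers, mask)))
  } else list()

  summary <- structure(list(
    counts = counts,
    regulome_stats = mask$stats,
    candidates = list(de_novo = de_novo, de_novo_regulome = dn_regulome,
                      in_regulome = in_mask, proximity_pairs = pairs,
                      double_hits = dhits, trans = trans_cand,
                      trans_phase_unknown = trans_unknown,
                      hemizygous_x = hemi, lof_genes = lof,
                      svs_retained = sv_kept, svs_removed = sv_removed),
    sv_type_counts = sv_types,
    sv_annotations = annotations,
    sv_escalated_cases = escalated_cases,
    params = list(seed = cfg$seed, regulome = unclass(cfg$regulome),
                  snv = unclass(cfg$snv), sv = unclass(cfg$sv),
                  sv_mode = cfg$sv_mode,
                  package_version = as.character(utils::packageVersion("trioregulome"))),
    mask = mask,
    truth = if (simulate) truth else NULL),
    class = "run_summary")

  if (!is.null(cfg$outdir)) write_run_summary(summary, cfg$outdir)
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  c_ <- x$counts
  cat("trioregulome run summary\n")
  cat(sprintf("  trios: %d, variants: %d (index-carried %d)\n",
              c_$n_trios, c_$n_variants, c_$n_index_carried))
  cat(sprintf("  noncoding: %d, rare noncoding: %d, in regulome: %d\n",
              c_$n_noncoding, c_$n_rare_noncoding, c_$n_in_regulome))
  cat(sprintf("  regulome: %d sites / %d bp (%.3f%% of genome)\n",
              x$regulome_stats$site_count, x$regulome_stats$bp_covered,
              100 * x$regulome_stats$genome_fraction))
  cat(sprintf("  de novo: %d (in regulome %d), proximity pairs: %d, double hits: %d\n",
              c_$n_de_novo, c_$n_de_novo_regulome, c_$n_proximity_pairs,
              c_$n_double_hits))
  cat(sprintf("  trans candidates: %d, hemizygous-X: %d, LoF double-hit genes: %d\n",
              c_$n_trans_candidates, c_$n_hemizygous_x, c_$n_lof_double_hit_genes))
  cat(sprintf("  SVs: %d in, %d retained (%s)\n", c_$n_svs, c_$n_svs_retained,
              paste(names(x$sv_type_counts), x$sv_type_counts, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Write a run summary to disk (stage TSVs plus a JSON summary)
#'
#' @param summary a \code{run_summary}.
#' @param outdir output directory.
#' @return \code{outdir}, invisibly.
#' @export
write_run_summary <- function(summary, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(summary$candidates)) {
    df <- summary$candidates[[nm]]
    if (!is.null(df))
      utils::write.table(df, file.path(outdir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  js <- list(counts = summary$counts,
             regulome_stats = summary$regulome_stats,
             sv_type_counts = as.list(summary$sv_type_counts),
             sv_escalated_cases = summary$sv_escalated_cases,
             params = summary$params)
  jsonlite::write_json(js, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(outdir)
}
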