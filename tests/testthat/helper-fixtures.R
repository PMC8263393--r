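## Shared fixtures: a small genome configuration that keeps generator-based
## tests fast, and independent brute-force oracles used against the
## interval-based implementations.

tiny_genome_config <- function(chrom_length = 5e4, n_chromosomes = 2L) {
  genome_config(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                include_x = FALSE, n_genes = 8L, limb_fraction = 0.5,
                gene_width_range = c(2e3, 6e3), tad_size_range = c(8e3, 2e4),
                cons_segment_mean = 25, cons_conserved_prob = 0.2,
                peak_density = 400, peak_width_range = c(100, 600),
                n_enhancers = 4L, enhancer_width_range = c(200, 800))
}

## Per-base logical membership vector for one chromosome, built with plain
## vector assignment (no interval machinery).
per_base_cover <- function(gr, chrom, len) {
  v <- logical(len)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (i in seq_along(gr)) {
    s <- max(1L, GenomicRanges::start(gr)[i])
    e <- min(len, GenomicRanges::end(gr)[i])
    if (s <= e) v[s:e] <- TRUE
  }
  v
}

## Per-base score vector from a piecewise-constant segment track.
per_base_score <- function(track, chrom, len) {
  v <- numeric(len)
  tr <- track[as.character(GenomicRanges::seqnames(track)) == chrom]
  for (i in seq_along(tr)) {
    s <- max(1L, GenomicRanges::start(tr)[i])
    e <- min(len, GenomicRanges::end(tr)[i])
    if (s <= e) v[s:e] <- tr$score[i]
  }
  v
}

## O(n^2) all-pairs proximity oracle over a variant table: cross-case pairs
## with |pos1 - pos2| < limit on one chromosome, or both positions inside a
## common enhancer element.  Returns a sorted key set.
brute_force_pairs <- function(variants, limit = 300L, enhancers = NULL,
                              inclusive = FALSE) {
  keys <- character(0)
  n <- nrow(variants)
  if (n < 2) return(keys)
  e_chrom <- if (is.null(enhancers)) character(0) else
    as.character(GenomicRanges::seqnames(enhancers))
  e_start <- if (is.null(enhancers)) integer(0) else GenomicRanges::start(enhancers)
  e_end <- if (is.null(enhancers)) integer(0) else GenomicRanges::end(enhancers)
  in_enh <- function(chrom, pos)
    e_chrom == chrom & pos >= e_start & pos <= e_end
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (variants$case_id[i] == variants$case_id[j]) next
      if (variants$chrom[i] != variants$chrom[j]) next
      d <- abs(variants$pos[i] - variants$pos[j])
      hit <- if (inclusive) d <= limit else d < limit
      if (!hit && length(e_chrom))
        hit <- any(in_enh(variants$chrom[i], variants$pos[i]) &
                     in_enh(variants$chrom[j], variants$pos[j]))
      if (hit) {
        a <- paste(variants$case_id[i], variants$chrom[i], variants$pos[i],
                   variants$ref[i], variants$alt[i])
        b <- paste(variants$case_id[j], variants$chrom[j], variants$pos[j],
                   variants$ref[j], variants$alt[j])
        keys <- c(keys, paste(sort(c(a, b)), collapse = " | "))
      }
    }
  }
  sort(unique(keys))
}

## Vectorized all-pairs scan for larger cohorts: enumerates every i<j pair
## explicitly and applies the distance and same-enhancer conditions with
## plain arithmetic on flat vectors.
brute_force_pairs_vectorized <- function(variants, limit = 300L,
                                         enhancers = NULL) {
  n <- nrow(variants)
  if (n < 2) return(character(0))
  idx <- utils::combn(n, 2L)
  i <- idx[1, ]; j <- idx[2, ]
  cross <- variants$case_id[i] != variants$case_id[j] &
    variants$chrom[i] == variants$chrom[j]
  near <- abs(variants$pos[i] - variants$pos[j]) < limit
  hit <- cross & near
  if (!is.null(enhancers) && length(enhancers)) {
    memb <- vapply(seq_along(enhancers), function(k) {
      variants$chrom == as.character(GenomicRanges::seqnames(enhancers))[k] &
        variants$pos >= GenomicRanges::start(enhancers)[k] &
        variants$pos <= GenomicRanges::end(enhancers)[k]
    }, logical(n))
    shared <- rowSums(memb[i, , drop = FALSE] & memb[j, , drop = FALSE]) > 0
    hit <- hit | (cross & shared)
  }
  i <- i[hit]; j <- j[hit]
  a <- paste(variants$case_id[i], variants$chrom[i], variants$pos[i],
             variants$ref[i], variants$alt[i])
  b <- paste(variants$case_id[j], variants$chrom[j], variants$pos[j],
             variants$ref[j], variants$alt[j])
  sort(unique(vapply(seq_along(a), function(k)
    paste(sort(c(a[k], b[k])), collapse = " | "), character(1))))
}

## Canonical key set for implementation pair output, matching
## brute_force_pairs keys.
pair_keys <- function(pairs) {
  if (!nrow(pairs)) return(character(0))
  a <- paste(pairs$case1, pairs$chrom, pairs$pos1, pairs$ref1, pairs$alt1)
  b <- paste(pairs$case2, pairs$chrom, pairs$pos2, pairs$ref2, pairs$alt2)
  sort(unique(vapply(seq_along(a), function(i)
    paste(sort(c(a[i], b[i])), collapse = " | "), character(1))))
}

## A deterministic small cohort shared by recovery tests (built once per
## test run; generation is seeded and reproducible).
demo_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- make_genome(genome_config(), seed = 404)
      cohort <- make_cohort(genome, n_trios = 8L, n_background = 1500L,
                            seed = 405)
      cache <<- list(genome = genome, cohort = cohort)
    }
    cache
  }
})
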