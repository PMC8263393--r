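test_that("conserved_intervals returns maximal runs above a strict threshold", {
  ## per-base segment track: scores 0.5, 2.0, 2.0, 1.0, 1.4 at positions 1-5
  track <- gintervals("chr1", 1:5, 1:5, score = c(0.5, 2.0, 2.0, 1.0, 1.4))
  runs <- conserved_intervals(track, 1.3)
  expect_equal(GenomicRanges::start(runs), c(2L, 5L))
  expect_equal(GenomicRanges::end(runs), c(3L, 5L))

  ## score exactly at the threshold is excluded
  at <- gintervals("chr1", 1, 10, score = 1.3)
  expect_length(conserved_intervals(at, 1.3), 0)

  ## all scores below: empty
  low <- gintervals("chr1", c(1, 50), c(49, 100), score = c(0.2, 1.29))
  expect_length(conserved_intervals(low, 1.3), 0)
})

test_that("conserved_intervals agrees with a per-base brute-force scan", {
  set.seed(7)
  for (rep in 1:5) {
    len <- 2000L
    n_seg <- 60
    ends <- sort(sample.int(len - 1, n_seg - 1))
    ends <- c(ends, len)
    starts <- c(1L, head(ends, -1) + 1L)
    track <- gintervals("chr1", starts, ends,
                        score = round(runif(n_seg, -2, 4), 2))
    runs <- conserved_intervals(track, 1.3)
    expect_equal(per_base_cover(runs, "chr1", len),
                 per_base_score(track, "chr1", len) > 1.3)
  }
})

test_that("limb_tads keeps TADs overlapping a limb gene body", {
  genes <- gintervals("chr1", 100, 200, gene_id = "g1", limb_flag = TRUE)
  tads <- gintervals("chr1", c(1, 151), c(150, 400), id = c("t1", "t2"))
  ## the gene straddles the boundary: both TADs overlap its body
  expect_equal(limb_tads(tads, genes)$id, c("t1", "t2"))

  ## gene fully inside one TAD: only that TAD
  inner <- gintervals("chr1", 160, 180, gene_id = "g2", limb_flag = TRUE)
  expect_equal(limb_tads(tads, inner)$id, "t2")

  ## no limb-flagged genes: empty
  off <- gintervals("chr1", 100, 200, gene_id = "g3", limb_flag = FALSE)
  expect_length(limb_tads(tads, off), 0)

  ## tss mode anchors on the 5' end only
  expect_equal(limb_tads(tads, genes, mode = "tss")$id, "t1")

  expect_warning(limb_tads(tads[0], genes), "empty TAD")
})

test_that("build_regulome intersects core conditions and unions enhancers", {
  conserved <- gintervals("chr1", 101, 110)
  tad <- gintervals("chr1", 1, 1000)
  peaks <- gintervals("chr1", 106, 200)
  enh <- gintervals("chr1", 501, 520, id = "e1", tissues = "limb")
  mask <- build_regulome(conserved, tad, peaks, enh, genome_size = 10000)
  expect_equal(GenomicRanges::start(mask$sites), c(106L, 501L))
  expect_equal(GenomicRanges::end(mask$sites), c(110L, 520L))
  expect_equal(mask$stats$bp_covered, 25)
  expect_equal(mask$stats$site_count, 2L)
  expect_equal(mask$stats$genome_fraction, 0.0025)
  expect_equal(mask$sites$provenance, c("core", "vista"))

  ## empty limb TADs with enhancers: mask is the enhancers alone
  m2 <- build_regulome(conserved, tad[0], peaks, enh)
  expect_equal(GenomicRanges::start(m2$sites), 501L)
  expect_equal(m2$sites$provenance, "vista")

  ## no vista, empty core: empty mask with zeroed stats
  m3 <- build_regulome(conserved, tad[0], peaks, enh,
                       cfg = regulome_config(include_vista = FALSE),
                       genome_size = 10000)
  expect_equal(m3$stats$site_count, 0L)
  expect_equal(m3$stats$bp_covered, 0)
  expect_equal(m3$stats$genome_fraction, 0)

  ## tissue filter restricts which enhancers enter the mask
  enh2 <- c(enh, gintervals("chr1", 701, 720, id = "e2", tissues = "heart"))
  m4 <- build_regulome(conserved, tad, peaks, enh2,
                       cfg = regulome_config(vista_tissue_filter = "limb"))
  expect_false(any(GenomicRanges::start(m4$sites) == 701))

  expect_error(build_regulome(gintervals("chrZ", 1, 10), tad, peaks),
               "namespaces")
})

test_that("regulome_stats handles boundary cases", {
  one <- build_regulome(gintervals("c", 1, 1), gintervals("c", 1, 1),
                        gintervals("c", 1, 1), genome_size = 1)
  expect_equal(one$stats, list(site_count = 1L, bp_covered = 1,
                               genome_fraction = 1))
  expect_error(regulome_stats(one, genome_size = 0), "genome_size")
})

test_that("mask membership respects interval boundaries and matches brute force", {
  mask <- build_regulome(gintervals("chr1", 106, 110), gintervals("chr1", 1, 1000),
                         gintervals("chr1", 1, 1000))
  v <- data.frame(chrom = "chr1", pos = c(106L, 111L, 105L), ref = "A",
                  alt = "T", stringsAsFactors = FALSE)
  hit <- mask_contains(mask, v)
  expect_equal(hit$pos, 106L)

  ## an indel is inside if any affected reference base overlaps
  indel <- data.frame(chrom = "chr1", pos = 104L, ref = "AAA", alt = "A",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(mask_contains(mask, indel)), 1L)

  ## unknown chromosomes are treated as outside
  odd <- data.frame(chrom = c("chr1", "chrZ"), pos = c(107L, 107L),
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  expect_message(out <- mask_contains(mask, odd), "absent")
  expect_equal(out$chrom, "chr1")

  ## random variants against a random mask equal a per-variant scan
  set.seed(11)
  len <- 5000L
  sites <- GenomicRanges::reduce(gintervals("chr1", s <- sample.int(len - 60, 40),
                                            s + sample.int(50, 40)))
  vs <- data.frame(chrom = "chr1", pos = sample.int(len, 1000, replace = TRUE),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  base <- per_base_cover(sites, "chr1", len + 60L)
  expect_equal(mask_contains(sites, vs)$pos, vs$pos[base[vs$pos]])
})

test_that("regulome construction is merge-idempotent, monotone and order-invariant", {
  set.seed(21)
  g <- make_genome(tiny_genome_config(), seed = 21)
  cons <- function(thr) conserved_intervals(g$conservation, thr)
  lt <- limb_tads(g$tads, g$genes)
  bp_at <- function(thr, peaks = g$peaks)
    build_regulome(cons(thr), lt, peaks, g$enhancers)$stats$bp_covered
  ## raising the conservation threshold never increases coverage
  expect_true(all(diff(vapply(c(0.5, 1.3, 2, 3), bp_at, numeric(1))) <= 0))
  ## adding a peak never decreases coverage
  extra <- c(g$peaks, gintervals("chr1", 101, 2000))
  expect_gte(bp_at(1.3, extra), bp_at(1.3))
  ## merge idempotence
  m <- build_regulome(cons(1.3), lt, g$peaks, g$enhancers)
  expect_identical(GenomicRanges::reduce(m$sites, ignore.strand = TRUE),
                   GenomicRanges::granges(m$sites))
  ## input order does not matter
  scramble <- function(gr) gr[sample(length(gr))]
  m2 <- build_regulome(scramble(cons(1.3)), scramble(lt), scramble(g$peaks),
                       scramble(g$enhancers))
  expect_identical(GenomicRanges::granges(m$sites), GenomicRanges::granges(m2$sites))
})
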