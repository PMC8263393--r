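make_variants <- function(pos, case_id = "caseA", chrom = "chr1",
                          gt_index = "0/1", gt_mother = "0/0",
                          gt_father = "0/0", af = 0, cadd = 10,
                          truncating = FALSE, ref = "A", alt = "T") {
  data.frame(case_id = case_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gt_index = gt_index, gt_mother = gt_mother,
             gt_father = gt_father, af = af, cadd = cadd,
             truncating = truncating, stringsAsFactors = FALSE)
}

test_that("coding context uses the 10-bp exon flank with a hard boundary", {
  exons <- gintervals("chr1", 1000, 1200, gene_id = "g1")
  v <- make_variants(c(1100, 1210, 1211, 989, 990))
  out <- classify_coding_context(v, exons)
  expect_equal(out$coding_context,
               c("coding_proximal",  # inside the exon
                 "coding_proximal",  # 10 bp past the exon end
                 "noncoding",        # 11 bp past: outside the flank
                 "noncoding",        # 11 bp before the start
                 "coding_proximal")) # 10 bp before the start
  expect_equal(out$gene_hits[1], "g1")
  expect_message(classify_coding_context(make_variants(5, chrom = "chrZ"), exons),
                 "unannotated")
})

test_that("rare filter is strict and matches a linear scan", {
  v <- make_variants(1:6, af = c(0.0009, 0.001, 0.0011, NA, 0, 0.5))
  kept <- filter_rare(v, 0.001)
  expect_equal(kept$pos, c(1L, 4L, 5L))  # missing AF counts as rare

  set.seed(3)
  sim <- make_variants(1:500, af = round(runif(500, 0, 0.01), 5))
  kept <- filter_rare(sim, 0.003)
  expect_equal(kept$pos, sim$pos[sapply(seq_len(500), function(i)
    is.na(sim$af[i]) || sim$af[i] < 0.003)])
  ## loosening the threshold never shrinks the kept set
  expect_true(all(kept$pos %in% filter_rare(sim, 0.01)$pos))
})

test_that("de novo detection requires alt in index and hom-ref parents", {
  v <- make_variants(1:5,
                     gt_index = c("0/1", "0/1", "1/1", "0/1", "0/1"),
                     gt_mother = c("0/0", "0/1", "0/0", "./.", "0/0"),
                     gt_father = c("0/0", "0/0", "0/0", "0/0", "0/1"))
  dn <- detect_de_novo(v)
  expect_equal(dn$pos, c(1L, 3L))
  expect_equal(attr(dn, "n_unevaluable"), 1L)

  singleton <- make_variants(1)[, !(names(make_variants(1)) %in%
                                      c("gt_mother", "gt_father"))]
  out <- detect_de_novo(singleton)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "status"), "singleton")
})

test_that("hemizygous X candidates are restricted to male indexes", {
  v <- make_variants(c(100, 200, 300, 400), chrom = "chrX",
                     gt_index = c("1", "1", "0/1", "1"),
                     gt_mother = c("0/1", "0/0", "0/1", "1/1"),
                     gt_father = c("0", "0", "0/0", "0"))
  expect_equal(nrow(hemizygous_x_candidates(v, "female")), 0L)
  out <- hemizygous_x_candidates(v, "male")
  ## carrier mother (100), de novo (200); het child (300) and hom-alt
  ## mother (400) do not qualify
  expect_equal(out$pos, c(100L, 200L))
  ## autosomal variants never qualify
  auto <- make_variants(5, gt_index = "1")
  expect_equal(nrow(hemizygous_x_candidates(auto, "male")), 0L)
  expect_error(hemizygous_x_candidates(v, NA), "index_sex")
})

test_that("parental origin is resolved by transmission", {
  v <- make_variants(1:4,
                     gt_mother = c("0/1", "0/0", "0/1", "./."),
                     gt_father = c("0/0", "0/1", "0/1", "0/0"))
  out <- resolve_parental_origin(v)
  expect_equal(out$parental_origin,
               c("maternal", "paternal", "unknown", "unknown"))
})

test_that("proximity pairing enforces a strict 300-bp rule across cases", {
  v <- rbind(make_variants(1000, "caseA"), make_variants(1299, "caseB"),
             make_variants(5000, "caseA"), make_variants(5300, "caseB"))
  p <- proximity_pairs(v)
  expect_equal(nrow(p), 1L)  # 299 bp pairs; 300 bp does not (strict)
  expect_equal(p$distance, 299L)
  ## inclusive mode admits the 300-bp pair
  p_inc <- proximity_pairs(v, snv_filter_config(proximity_inclusive = TRUE))
  expect_equal(sort(p_inc$distance), c(299L, 300L))
  ## same-case pairs never count
  same <- rbind(make_variants(1000, "caseA"), make_variants(1010, "caseA"))
  expect_equal(nrow(proximity_pairs(same)), 0L)
})

test_that("distant variants inside one enhancer element pair up", {
  enh <- gintervals("chr1", 1000, 9000, id = "e1")
  v <- rbind(make_variants(1500, "caseA"), make_variants(6500, "caseB"))
  p <- proximity_pairs(v, enhancers = enh)
  expect_equal(nrow(p), 1L)
  expect_equal(p$rule, "same_enhancer")
  ## without the enhancer there is no pair
  expect_equal(nrow(proximity_pairs(v)), 0L)
})

test_that("proximity pairs equal the all-pairs brute-force scan", {
  set.seed(17)
  n <- 400
  v <- make_variants(sample.int(50000, n), case_id = sample(paste0("case", 1:6),
                                                            n, replace = TRUE),
                     chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
  v$ref <- sample(c("A", "C"), n, replace = TRUE)
  v$alt <- sample(c("G", "T"), n, replace = TRUE)
  enh <- gintervals(c("chr1", "chr2"), c(10000, 20000), c(12000, 23000),
                    id = c("e1", "e2"))
  p <- proximity_pairs(v, enhancers = enh)
  expect_equal(pair_keys(p), brute_force_pairs(v, 300L, enh))
  ## symmetry: input order does not change the reported pair set
  p2 <- proximity_pairs(v[sample(n), ], enhancers = enh)
  expect_equal(pair_keys(p2), pair_keys(p))
})

test_that("double hits group identical calls across cases", {
  v <- rbind(make_variants(1000, "caseA", ref = "G", alt = "C"),
             make_variants(1000, "caseB", ref = "G", alt = "C"),
             make_variants(1000, "caseC", ref = "G", alt = "A"),
             make_variants(2000, "caseA"), make_variants(2100, "caseB"))
  dh <- double_hits(proximity_pairs(v))
  expect_equal(nrow(dh), 1L)
  expect_equal(dh$cases, "caseA,caseB")
  expect_equal(dh$pos, 1000L)
  expect_equal(nrow(double_hits(proximity_pairs(make_variants(1:2)))), 0L)
})

test_that("trans screen demands opposite parental origins in one TAD", {
  genes <- gintervals("chr1", 1000, 3000, gene_id = "g1", limb_flag = TRUE,
                      pli = 0.5, recessive_flag = TRUE)
  exons <- gintervals("chr1", 1200, 1500, gene_id = "g1")
  tads <- gintervals("chr1", c(1, 10001), c(10000, 20000), id = c("t1", "t2"))
  conserved <- gintervals("chr1", 8000, 8200)
  base <- function(nc_mother, nc_father, nc_af = 0.02, nc_pos = 8100) {
    rbind(make_variants(1300, gt_mother = "0/0", gt_father = "0/1",
                        af = 0.01, cadd = 30),
          make_variants(nc_pos, gt_mother = nc_mother, gt_father = nc_father,
                        af = nc_af))
  }
  run <- function(v) trans_screen(classify_coding_context(v, exons), genes,
                                  tads, conserved)
  ## coding paternal + noncoding maternal: candidate
  res <- run(base("0/1", "0/0"))
  expect_equal(nrow(res$candidates), 1L)
  expect_equal(res$candidates$nc_origin, "maternal")
  ## both paternal: cis, rejected
  expect_equal(nrow(run(base("0/0", "0/1"))$candidates), 0L)
  ## MAF exactly 3%: rejected (strict)
  expect_equal(nrow(run(base("0/1", "0/0", nc_af = 0.03))$candidates), 0L)
  ## unphaseable partner goes to the phase-unknown list, not dropped
  res <- run(base("0/1", "0/1"))
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(nrow(res$phase_unknown), 1L)
  ## noncoding partner outside the gene's TAD: no candidate
  far <- base("0/1", "0/0")
  far$pos[2] <- 15000L
  cons2 <- c(conserved, gintervals("chr1", 14900, 15100))
  res <- trans_screen(classify_coding_context(far, exons), genes, tads, cons2)
  expect_equal(nrow(res$candidates), 0L)
})

test_that("LoF double-hit screen needs pLI > 0.9 and two distinct cases", {
  genes <- gintervals("chr1", c(1000, 5000), c(3000, 7000),
                      gene_id = c("g1", "g2"), limb_flag = TRUE,
                      pli = c(0.95, 0.9), recessive_flag = FALSE)
  v <- rbind(make_variants(1, "case1", cadd = 10, truncating = TRUE),
             make_variants(2, "case2", cadd = 25, truncating = FALSE))
  v$gene_hits <- "g1"
  out <- lof_double_hit_genes(v, genes)
  expect_equal(out$gene_id, "g1")
  expect_equal(out$cases, "case1,case2")
  ## pLI exactly 0.9 fails the strict cutoff
  v2 <- v; v2$gene_hits <- "g2"
  expect_equal(nrow(lof_double_hit_genes(v2, genes)), 0L)
  ## both hits in one case: not reported
  v3 <- v; v3$case_id <- "case1"
  expect_equal(nrow(lof_double_hit_genes(v3, genes)), 0L)
  ## CADD exactly 20, non-truncating: does not qualify
  v4 <- v; v4$cadd <- 20; v4$truncating <- FALSE
  expect_equal(nrow(lof_double_hit_genes(v4, genes)), 0L)
})
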