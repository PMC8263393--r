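make_svs <- function(n, size = 2000L, support = 10L, type = "DEL",
                     case_id = "caseA", inheritance = "de_novo") {
  start <- seq(1L, by = 1e5L, length.out = n)
  data.frame(sv_id = sprintf("sv%03d", seq_len(n)),
             case_id = rep_len(case_id, n),
             sv_type = rep_len(type, n), chrom = rep_len("chr1", n),
             start = start,
             end = start + rep_len(size, n) - 1L,
             support_reads = rep_len(support, n),
             inheritance = rep_len(inheritance, n), stringsAsFactors = FALSE)
}

test_that("size filter admits 1500 bp and rejects 1499 bp", {
  svs <- make_svs(2, size = c(1499L, 1500L))
  f <- filter_svs(svs)
  expect_equal(f$kept$sv_id, "sv002")
  expect_equal(f$removed$reason, "below_min_size")
  ## BND records have no length and are exempt from the size rule
  bnd <- make_svs(1, size = 2L, type = "BND")
  expect_equal(nrow(filter_svs(bnd)$kept), 1L)
  ## empty input: no escalation, empty output
  f0 <- filter_svs(make_svs(0))
  expect_equal(nrow(f0$kept), 0L)
  expect_false(f0$escalated)
})

test_that("support escalation fires above 30 passing SVs and not at 30", {
  at30 <- make_svs(30, support = rep(c(2L, 5L), 15))
  f30 <- filter_svs(at30)
  expect_false(f30$escalated)
  expect_equal(f30$applied_support, 2L)
  expect_equal(nrow(f30$kept), 30L)

  at31 <- make_svs(31, support = c(rep(2L, 16), rep(5L, 15)))
  f31 <- filter_svs(at31)
  expect_true(f31$escalated)
  expect_equal(f31$applied_support, 5L)
  expect_equal(nrow(f31$kept), 15L)
  expect_true(all(f31$kept$support_reads >= 5))
  ## every record lands in exactly one of kept/removed
  expect_equal(nrow(f31$kept) + nrow(f31$removed), 31L)
  ## re-running on the escalated output changes nothing
  again <- filter_svs(f31$kept)
  expect_equal(again$kept$sv_id, f31$kept$sv_id)
})

test_that("inheritance filter removes unaffected-parent SVs, keeps the rest", {
  svs <- make_svs(4, inheritance = c("maternal", "paternal", "de_novo", "unknown"))
  ped <- list(mother_affected = FALSE, father_affected = TRUE)
  out <- inheritance_filter(svs, ped)
  ## only the unaffected mother's SV goes; affected father's stays
  expect_equal(out$removed$sv_id, "sv001")
  expect_equal(out$removed$reason, "inherited_from_unaffected_parent")
  expect_equal(nrow(out$kept), 3L)

  ## affected-relative mode rescues an SV segregating with disease in the
  ## wider family despite an unaffected transmitting parent
  fam <- make_svs(1, type = "INV", inheritance = "maternal")
  fam$carried_by_affected_relative <- TRUE
  ped2 <- list(mother_affected = FALSE, father_affected = FALSE)
  expect_equal(nrow(inheritance_filter(fam, ped2)$kept), 0L)
  expect_equal(nrow(inheritance_filter(fam, ped2, "affected_relative")$kept), 1L)

  expect_error(inheritance_filter(svs, list()), "pedigree")
})

test_that("sv_length reproduces the printed inversion and counts bases", {
  ## inversion at the split-hand/foot locus printed as
  ## chr10:103,321,526-103,426,609 (1-based inclusive endpoints)
  inv <- sv_length(103321526, 103426609, "INV", "one_based_inclusive")
  expect_equal(inv$bp, 105084)
  expect_equal(inv$kb_rounded, 105)

  expect_equal(sv_length(0, 1000, "DEL", "half_open")$bp, 1000)
  expect_equal(sv_length(0, 1000, "DEL", "half_open")$kb_rounded, 1)
  expect_error(sv_length(1, 2, "BND"), "undefined")

  ## random intervals: bp equals the enumerated count of covered positions
  set.seed(5)
  for (i in 1:20) {
    s <- sample.int(1e6, 1); w <- sample.int(5000, 1)
    expect_equal(sv_length(s, s + w - 1, "DEL", "one_based_inclusive")$bp,
                 length(s:(s + w - 1)))
  }
})

test_that("SV type counts cover all classes and sum to the input size", {
  svs <- make_svs(4, type = c("INV", "INV", "DEL", "BND"))
  counts <- classify_sv_types(svs)
  expect_equal(counts, c(DEL = 1L, DUP = 0L, INV = 2L, BND = 1L))
  expect_equal(sum(counts), nrow(svs))
  expect_equal(classify_sv_types(make_svs(0)),
               c(DEL = 0L, DUP = 0L, INV = 0L, BND = 0L))
  bad <- make_svs(1); bad$sv_type <- "CNV"
  expect_error(classify_sv_types(bad), "sv001")
})

test_that("SV annotation flags TAD-boundary disruption and dosage neutrality", {
  tads <- gintervals("chr1", c(1, 10001), c(10000, 20000), id = c("t1", "t2"))
  genes <- gintervals("chr1", 12000, 13000, gene_id = "g1", limb_flag = TRUE,
                      pli = 0.5, recessive_flag = FALSE)
  enh <- gintervals("chr1", 2000, 3500, id = "e1")

  inside <- data.frame(chrom = "chr1", start = 3000L, end = 8000L,
                       sv_type = "INV", stringsAsFactors = FALSE)
  a <- annotate_sv(inside, tads, genes, enh)
  expect_false(a$tad_boundary_disruption)
  expect_true(a$copy_number_neutral)
  expect_equal(a$enhancers, "e1")

  spanning <- data.frame(chrom = "chr1", start = 8000L, end = 12000L,
                         sv_type = "INV", stringsAsFactors = FALSE)
  b <- annotate_sv(spanning, tads, genes, enh)
  expect_true(b$tad_boundary_disruption)
  expect_true(b$copy_number_neutral)

  del <- data.frame(chrom = "chr1", start = 11500L, end = 14000L,
                    sv_type = "DEL", stringsAsFactors = FALSE)
  d <- annotate_sv(del, tads, genes, enh)
  expect_equal(d$limb_genes, "g1")
  expect_false(d$copy_number_neutral)
  expect_false(d$tad_boundary_disruption)
})
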