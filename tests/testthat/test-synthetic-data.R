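test_that("genome generation is deterministic and satisfies its invariants", {
  cfg <- tiny_genome_config()
  g1 <- make_genome(cfg, seed = 7)
  g2 <- make_genome(cfg, seed = 7)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  expect_false(identical(serialize(make_genome(cfg, seed = 8), NULL),
                         serialize(g1, NULL)))
  ## independent re-scan of structural invariants over several seeds
  for (s in c(1, 7, 23)) expect_true(validate_genome(make_genome(cfg, seed = s)))
  ## limb genes exist whenever requested
  g <- make_genome(genome_config(n_genes = 5, limb_fraction = 0.1), seed = 3)
  expect_true(any(g$genes$limb_flag))
})

test_that("an empty genome configuration yields empty tracks", {
  g <- make_genome(genome_config(n_genes = 0, n_enhancers = 0, peak_density = 0),
                   seed = 1)
  expect_length(g$genes, 0)
  expect_length(g$peaks, 0)
  expect_length(g$enhancers, 0)
  expect_equal(nrow(g$chromosomes), 3L)
  expect_true(validate_genome(g))
})

test_that("invalid generator settings name the offending field", {
  expect_error(genome_config(n_genes = -1), "n_genes")
  expect_error(genome_config(limb_fraction = 1.5), "limb_fraction")
  expect_error(genome_config(chrom_length = 10), "chrom_length")
  expect_error(make_genome(genome_config()), "seed")
  expect_error(plant_spec(n_double_hits = -2), "n_double_hits")
  expect_error(af_model(singleton_prob = 2), "singleton_prob")
})

test_that("a cohort with no planted events has only background variants", {
  g <- make_genome(tiny_genome_config(), seed = 5)
  zero <- plant_spec(n_regulome_de_novo = 0, n_nonregulome_de_novo = 0,
                     n_proximity_pairs = 0, n_enhancer_pairs = 0,
                     n_double_hits = 0, n_trans_pairs = 0, n_lof_genes = 0,
                     n_hemi_x = 0, n_sv_causal = 0,
                     n_sv_inherited_unaffected = 0, n_sv_affected_relative = 0,
                     n_sv_small = 0, n_sv_low_support = 0, n_sv_pass_mix = 0,
                     repeat_deltas = integer(0))
  co <- make_cohort(g, n_trios = 2, plant = zero, n_background = 120, seed = 6)
  expect_equal(nrow(co$variants), 120L)
  for (nm in names(co$truth)) expect_equal(nrow(co$truth[[nm]]), 0L)
  ## background genotypes are never de novo
  dn <- do.call(rbind, lapply(split(co$variants, co$variants$case_id),
                              detect_de_novo))
  expect_equal(nrow(dn), 0L)
})

test_that("planted de novo calls carry the trio genotype contract", {
  dat <- demo_cohort()
  co <- dat$cohort
  for (i in seq_len(nrow(co$truth$de_novo))) {
    t <- co$truth$de_novo[i, ]
    v <- co$variants[co$variants$case_id == t$case_id &
                       co$variants$chrom == t$chrom & co$variants$pos == t$pos, ]
    expect_equal(nrow(v), 1L)
    expect_equal(v$gt_index, "0/1")
    expect_equal(v$gt_mother, "0/0")
    expect_equal(v$gt_father, "0/0")
  }
  ## regulome plants fall inside the mask built from the same genome
  mask <- genome_regulome(dat$genome)
  reg <- co$truth$de_novo[co$truth$de_novo$in_regulome, ]
  hit <- mask_contains(mask, data.frame(chrom = reg$chrom, pos = reg$pos,
                                        ref = reg$ref, alt = reg$alt))
  expect_equal(nrow(hit), nrow(reg))
})

test_that("planted cross-case pairs are exactly what a brute-force scan finds", {
  dat <- demo_cohort()
  co <- dat$cohort
  carried <- co$variants[sapply(strsplit(co$variants$gt_index, "/"),
                                function(a) any(a == "1")), ]
  rare_nc <- filter_rare(
    classify_coding_context(carried, dat$genome$exons), 0.001)
  rare_nc <- rare_nc[rare_nc$coding_context == "noncoding", ]
  found <- brute_force_pairs(rare_nc, 300L, dat$genome$enhancers)
  ## expected: the proximity ledger plus the distance-zero pairs implied by
  ## planted double hits
  truth <- co$truth$proximity
  dh <- co$truth$double_hits
  exp_keys <- character(0)
  key_of <- function(case, chrom, pos) {
    v <- rare_nc[rare_nc$case_id == case & rare_nc$chrom == chrom &
                   rare_nc$pos == pos, ]
    paste(v$case_id, v$chrom, v$pos, v$ref, v$alt)
  }
  for (i in seq_len(nrow(truth)))
    exp_keys <- c(exp_keys, paste(sort(c(
      key_of(truth$case1[i], truth$chrom[i], truth$pos1[i]),
      key_of(truth$case2[i], truth$chrom[i], truth$pos2[i]))), collapse = " | "))
  for (i in seq_len(nrow(dh))) {
    cases <- strsplit(dh$cases[i], ",")[[1]]
    exp_keys <- c(exp_keys, paste(sort(c(
      key_of(cases[1], dh$chrom[i], dh$pos[i]),
      key_of(cases[2], dh$chrom[i], dh$pos[i]))), collapse = " | "))
  }
  expect_setequal(found, exp_keys)
})

test_that("cohort generation is deterministic for a fixed seed", {
  g <- make_genome(tiny_genome_config(), seed = 9)
  pl <- plant_spec(n_regulome_de_novo = 1, n_nonregulome_de_novo = 0,
                   n_proximity_pairs = 1, n_enhancer_pairs = 0,
                   n_double_hits = 1, n_trans_pairs = 0, n_lof_genes = 0,
                   n_hemi_x = 0)
  c1 <- make_cohort(g, n_trios = 3, plant = pl, n_background = 100, seed = 10)
  c2 <- make_cohort(g, n_trios = 3, plant = pl, n_background = 100, seed = 10)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
})

test_that("infeasible plant requests fail with the violated constraint", {
  g <- make_genome(tiny_genome_config(), seed = 12)
  only <- function(...) {
    zero <- list(n_regulome_de_novo = 0, n_nonregulome_de_novo = 0,
                 n_proximity_pairs = 0, n_enhancer_pairs = 0,
                 n_double_hits = 0, n_trans_pairs = 0, n_lof_genes = 0,
                 n_hemi_x = 0, n_sv_causal = 0, n_sv_inherited_unaffected = 0,
                 n_sv_affected_relative = 0, n_sv_small = 0,
                 n_sv_low_support = 0, n_sv_pass_mix = 0,
                 repeat_deltas = integer(0))
    do.call(plant_spec, utils::modifyList(zero, list(...)))
  }
  expect_error(make_cohort(g, n_trios = 1, plant = only(n_proximity_pairs = 1),
                           n_background = 0, seed = 2),
               "trios")
  ## no chrX in this tiny genome: hemizygous plants are impossible
  expect_error(make_cohort(g, n_trios = 4, plant = only(n_hemi_x = 1),
                           n_background = 0, seed = 2),
               "chrX")
})
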