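test_that("hypothesis scoring picks the right allelic fate in clear-cut
           cases", {
  # wildtype copy deleted, high purity: expected VAF 1 / (2 - 0.8) = 0.833;
  # best hypothesis among those compatible with the one-copy segment
  sc <- score_hypotheses(95, 5, make_segment(1, 0), purity = 0.8)
  comp <- sc$loglik[sc$compatible]
  expect_equal(names(which.max(comp)), "wt_lost_deletion")
  expect_equal(sc$expected_vafs[["wt_lost_deletion"]], 1 / 1.2)

  # balanced reads on a balanced segment
  sc2 <- score_hypotheses(50, 50, make_segment(2, 1), purity = 0.5)
  expect_equal(names(which.max(sc2$loglik)), "balanced_het")

  # variant allele lost: expected VAF (1 - p) / (2 - p) = 0.167
  sc3 <- score_hypotheses(10, 90, make_segment(1, 0), purity = 0.8)
  expect_equal(names(which.max(sc3$loglik)), "variant_lost")
  expect_equal(sc3$expected_vafs[["variant_lost"]], 0.2 / 1.2)

  expect_error(score_hypotheses(0, 0, make_segment(2, 1), 0.5), "depth")
})

test_that("noise-free observations classify perfectly across fates and
           purities", {
  d <- 200
  for (p in c(0.3, 0.5, 0.7, 0.9, 1.0)) {
    cases <- list(
      list(seg = make_segment(1, 0), ev = expected_vaf(1, 1, p),
           want = "WT_LOST"),
      list(seg = make_segment(2, 0), ev = expected_vaf(2, 2, p),
           want = "WT_LOST"),
      list(seg = make_segment(1, 0), ev = expected_vaf(0, 1, p),
           want = "VARIANT_LOST"),
      list(seg = make_segment(2, 1), ev = 0.5, want = "HETEROZYGOUS"))
    for (cs in cases) {
      alt <- round(d * cs$ev)
      call <- classify_allelic_status(make_obs(alt, d - alt), cs$seg, p)
      expect_equal(call$category, cs$want)
    }
  }
})

test_that("copy-number evidence gates the call: conflicts and weak evidence
           are AMBIGUOUS, Sanger-style overrides resolve them", {
  # extreme VAF on a balanced segment: VAF and CN disagree
  call <- classify_allelic_status(make_obs(98, 2), make_segment(2, 1), 0.8)
  expect_equal(call$category, "AMBIGUOUS")
  expect_false(call$biallelic)

  over <- classify_allelic_status(make_obs(98, 2), make_segment(2, 1), 0.8,
                                  override = "WT_LOST")
  expect_equal(over$category, "WT_LOST")

  # shallow depth cannot separate the LOH fates at low purity
  weak <- classify_allelic_status(make_obs(6, 4), make_segment(1, 0), 0.3)
  expect_equal(weak$category, "AMBIGUOUS")

  expect_error(classify_allelic_status(make_obs(50, 50),
                                       make_segment(2, 1), 0.2),
               "floor")
})

test_that("somatic second hits and promoter methylation upgrade calls as in
           the published call vocabulary", {
  p <- 0.7
  d <- 120
  low <- round(d * expected_vaf(0, 1, p))   # variant allele lost
  bal <- round(d * 0.5)

  missense_hit <- variant_table(data.frame(
    chrom = "chr1", pos = 55e6 + 10, ref = "G", alt = "T", gene = "GENE1",
    consequence = "missense", origin = "somatic", alt_reads = 40,
    ref_reads = 60, cadd_phred = 26.6, revel = 0.558))
  stop_hit <- variant_table(data.frame(
    chrom = "chr1", pos = 55e6 + 10, ref = "G", alt = "A", gene = "GENE1",
    consequence = "stop_gain", origin = "somatic", alt_reads = 40,
    ref_reads = 60))

  # variant lost + predicted-pathogenic somatic missense in the WT allele
  c1 <- classify_allelic_status(make_obs(low, d - low), make_segment(1, 0),
                                p, somatic_hits = missense_hit)
  expect_equal(c1$category, "WT_LOST_BY_SOMATIC_HIT")
  expect_true(c1$biallelic)

  # sub-threshold missense does not qualify as a second hit
  weak_hit <- missense_hit
  weak_hit$cadd_phred <- 15
  c2 <- classify_allelic_status(make_obs(low, d - low), make_segment(1, 0),
                                p, somatic_hits = weak_hit)
  expect_equal(c2$category, "VARIANT_LOST")
  expect_false(c2$biallelic)

  # heterozygous with somatic stop-gain, phase unknown
  c3 <- classify_allelic_status(make_obs(bal, d - bal), make_segment(2, 1),
                                p, somatic_hits = stop_hit)
  expect_equal(c3$category, "HET_WITH_SOMATIC_HIT_PHASE_UNKNOWN")
  expect_true(c3$biallelic)
  strict <- status_config(phase_unknown_biallelic = FALSE)
  c3s <- classify_allelic_status(make_obs(bal, d - bal), make_segment(2, 1),
                                 p, somatic_hits = stop_hit, cfg = strict)
  expect_false(c3s$biallelic)

  # variant lost with promoter methylation of the remaining WT allele
  meth_hom <- methylation_call("S1", "GENE1", "homozygous_methylated")
  c4 <- classify_allelic_status(make_obs(low, d - low), make_segment(1, 0),
                                p, methylation = meth_hom)
  expect_equal(c4$category, "VARIANT_LOST_WT_METHYLATED")
  expect_true(c4$biallelic)

  # heterozygous with methylation of the WT allele vs an unknown allele
  meth_wt <- methylation_call("S1", "GENE1", "heterozygous_methylated",
                              "wildtype")
  c5 <- classify_allelic_status(make_obs(bal, d - bal), make_segment(2, 1),
                                p, methylation = meth_wt)
  expect_equal(c5$category, "HET_WT_METHYLATED")
  expect_true(c5$biallelic)
  meth_unk <- methylation_call("S1", "GENE1", "heterozygous_methylated")
  c6 <- classify_allelic_status(make_obs(bal, d - bal), make_segment(2, 1),
                                p, methylation = meth_unk)
  expect_equal(c6$category, "HET_ONE_ALLELE_METHYLATED")
  expect_false(c6$biallelic)
})

test_that("raising the alternate-read count never flips a call from
           WT_LOST to VARIANT_LOST", {
  d <- 100
  seg <- make_segment(1, 0)
  cats <- vapply(0:d, function(a)
    classify_allelic_status(make_obs(a, d - a), seg, 0.6)$category, "")
  first_wt <- match("WT_LOST", cats)
  expect_false(is.na(first_wt))
  expect_false(any(cats[first_wt:length(cats)] == "VARIANT_LOST"))
  # and the variant-lost calls all precede the wildtype-lost calls
  expect_lt(max(which(cats == "VARIANT_LOST")), first_wt)
})

test_that("gene-level summaries aggregate calls into the published
           patterns", {
  mk <- function(category, biallelic) structure(
    list(category = category, biallelic = biallelic),
    class = "allelic_status_call")
  s1 <- summarize_gene(list(mk("WT_LOST", TRUE), mk("WT_LOST", TRUE),
                            mk("VARIANT_LOST_WT_METHYLATED", TRUE)))
  expect_equal(s1$pattern, "consistent_biallelic")
  expect_equal(s1$n_biallelic, 3)
  expect_equal(s1$n_wt_lost + s1$n_variant_lost + s1$n_het, s1$n_tumours)

  s2 <- summarize_gene(list(mk("HETEROZYGOUS", FALSE),
                            mk("HETEROZYGOUS", FALSE)))
  expect_equal(s2$pattern, "heterozygous_only")

  s3 <- summarize_gene(list(mk("WT_LOST", TRUE), mk("VARIANT_LOST", FALSE)))
  expect_equal(s3$pattern, "variant_loss_observed")

  s4 <- summarize_gene(list(mk("WT_LOST", TRUE), mk("HETEROZYGOUS", FALSE)))
  expect_equal(s4$pattern, "partial")
})
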