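test_that("LoF allele counting respects consequence class, rarity threshold
           and carrier genotype", {
  carriers <- variant_table(data.frame(
    chrom = "chr16", pos = c(1, 2, 3, 4, 5), ref = "C", alt = "T",
    gene = "PALB2",
    consequence = c("stop_gain", "stop_gain", "frameshift", "missense",
                    "stop_gain"),
    gnomad_af = c(1e-5, NA, 1e-4, 1e-5, 0.006),
    alt_reads = 20, ref_reads = 20))
  rec <- count_lof_alleles(carriers, "PALB2", n_individuals = 496,
                           cohort = "cases")
  # missense excluded; gnomAD AF 0.006 > 0.005 excluded; NA AF counts
  expect_equal(rec$lof_alleles, 3L)
  expect_equal(rec$total_alleles, 992L)
  expect_equal(round(rec$af_percent, 2), 0.30)

  # genotype-expansion oracle: a homozygote is two carrier chromosomes
  carriers$n_alt_alleles <- c(1, 2, 1, 1, 1)
  rec2 <- count_lof_alleles(carriers, "PALB2", 496)
  qualifies <- carriers$consequence %in% c("stop_gain", "frameshift") &
    (is.na(carriers$gnomad_af) | carriers$gnomad_af <= 0.005)
  expect_equal(rec2$lof_alleles, sum(carriers$n_alt_alleles[qualifies]))
  expect_equal(rec2$lof_alleles, 4L)

  expect_error(count_lof_alleles(carriers, "PALB2", NULL), "cohort size")
  expect_error(count_lof_alleles(carriers, "PALB2", 496,
                                 lof_classes = "nonsense"), "legal values")
})

test_that("fisher_enrichment matches the published PALB2 comparison and
           handles degenerate tables", {
  r <- fisher_enrichment(3, 992, 86, 118190)
  expect_equal(round(r$odds_ratio, 1), 4.2)
  expect_equal(round(r$p_one_sided, 3), 0.039)
  expect_lte(r$ci_low, r$odds_ratio)
  expect_gte(r$ci_high, r$odds_ratio)

  empty <- fisher_enrichment(0, 992, 0, 118190)
  expect_true(is.na(empty$odds_ratio))
  expect_equal(empty$p_one_sided, 1)

  zero_ctrl <- fisher_enrichment(3, 992, 0, 8550)
  expect_true(is.na(zero_ctrl$odds_ratio))
  hald <- fisher_enrichment(3, 992, 0, 8550, haldane = TRUE)
  expect_false(is.na(hald$odds_ratio))

  expect_error(fisher_enrichment(-1, 10, 1, 10), "negative")
})

test_that("one-sided p equals brute-force hypergeometric enumeration on
           small tables", {
  for (tab in list(c(2, 10, 1, 10), c(5, 12, 2, 30), c(0, 8, 3, 9),
                   c(7, 7, 1, 20), c(3, 15, 15, 15))) {
    expect_equal(
      fisher_enrichment(tab[1], tab[2], tab[3], tab[4])$p_one_sided,
      hyper_tail_oracle(tab[1], tab[2], tab[3], tab[4]),
      tolerance = 1e-12)
  }
})

test_that("cohort combination sums counts and is consistent with testing the
           pre-summed table", {
  recs <- rbind(gene_burden("PALB2", "mgrb", 4, 5144),
                gene_burden("PALB2", "lifepool", 3, 3406))
  comb <- combine_cohorts(recs)
  expect_equal(comb$lof_alleles, 7L)
  expect_equal(comb$total_alleles, 8550L)
  expect_equal(round(comb$af_percent, 3), 0.082)

  via_comb <- fisher_enrichment(3, 992, comb$lof_alleles,
                                comb$total_alleles)
  direct <- fisher_enrichment(3, 992, 7, 8550)
  expect_equal(via_comb, direct)
  expect_equal(round(direct$odds_ratio, 1), 3.7)

  expect_equal(combine_cohorts(recs[1, ]), gene_burden("PALB2", "combined",
                                                       4, 5144))
  expect_error(combine_cohorts(rbind(recs, recs[1, ])), "disjoint")
})

test_that("gene ranking is p-ascending within groups, deterministic under
           ties and invariant to input order", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    p_one_sided = c(0.01, 0.5, 0.01, 0.2),
                    odds_ratio = c(3, 1, 8, 2))
  r <- rank_genes(res)
  expect_equal(r$rank[r$gene == "C"], 1L)  # tie broken by descending OR
  expect_equal(r$rank[r$gene == "A"], 2L)

  shuffled <- rank_genes(res[c(3, 1, 4, 2), ])
  expect_equal(shuffled$rank[shuffled$gene == "C"], 1L)
  expect_equal(sort(shuffled$rank), 1:4)

  ties <- data.frame(gene = c("B", "A"), p_one_sided = 0.1, odds_ratio = 2)
  expect_equal(rank_genes(ties)$rank, c(2L, 1L))  # alphabetical last resort
})

test_that("the packaged count fixture reproduces the published gnomAD
           ranking of candidate genes", {
  counts <- hgsoc_lof_counts()
  tb <- burden_table(counts, control_cohorts = "gnomad")
  cand <- tb[counts$group[counts$cohort == "cases"] == "candidate", ]
  cand <- rank_genes(cand)
  expect_equal(cand$gene[cand$rank == 1], "MAP6D1")
})

test_that("combined-cohort OR lies between the per-cohort ORs when both are
           defined", {
  counts <- hgsoc_lof_counts()
  wide <- split(counts, counts$cohort)
  for (g in c("PALB2", "ATM", "ZCCHC4", "ANKAR", "CCDC88B")) {
    a_case <- wide$cases$lof_alleles[wide$cases$gene == g]
    ors <- vapply(c("mgrb", "lifepool", "combined"), function(ch) {
      w <- wide[[ch]]
      fisher_enrichment(a_case, 992, w$lof_alleles[w$gene == g],
                        w$total_alleles[w$gene == g])$odds_ratio
    }, 0)
    expect_gte(ors["combined"], min(ors[1:2]) - 1e-12)
    expect_lte(ors["combined"], max(ors[1:2]) + 1e-12)
  }
})

test_that("the one-sided exact test controls type I error on null cohorts", {
  sim <- gen_cohort(200, 800, paste0("G", 1:500),
                    base_carrier_freq = 0.002, or_per_gene = 1, seed = 2024)
  p <- vapply(seq_len(500), function(i)
    fisher_enrichment(sim$case$lof_alleles[i], sim$case$total_alleles[i],
                      sim$control$lof_alleles[i],
                      sim$control$total_alleles[i])$p_one_sided, 0)
  # discrete exact test is conservative: rejection rate at or below nominal
  # (allowing Monte Carlo error over 500 replicates)
  expect_lte(mean(p <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})
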