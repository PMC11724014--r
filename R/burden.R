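#' Per-gene, per-cohort LoF allele count record
#'
#' @param gene gene symbol.
#' @param cohort cohort name.
#' @param lof_alleles number of qualifying LoF variant alleles observed (a).
#' @param total_alleles allele denominator of the cohort (N), i.e. twice the
#'   number of individuals for autosomal genes.
#' @return one-row data.frame with `gene`, `cohort`, `lof_alleles`,
#'   `total_alleles`, `af_percent` (= 100 a / N).
#' @export
gene_burden <- function(gene, cohort, lof_alleles, total_alleles) {
  if (lof_alleles < 0 || total_alleles <= 0 || lof_alleles > total_alleles)
    stop("need 0 <= lof_alleles <= total_alleles and total_alleles > 0")
  data.frame(gene = gene, cohort = cohort,
             lof_alleles = as.integer(lof_alleles),
             total_alleles = as.integer(total_alleles),
             af_percent = 100 * lof_alleles / total_alleles,
             stringsAsFactors = FALSE)
}

#' Count rare LoF alleles for one gene in a cohort
#'
#' Counts each qualifying variant allele once per carrier chromosome: a row of
#' the variant table contributes its `n_alt_alleles` (default 1; 2 for a
#' homozygous carrier). A variant qualifies if its gene matches, its
#' consequence is in `lof_classes`, and its gnomAD AF (missing treated as 0,
#' i.e. absent from gnomAD) does not exceed `af_threshold`.
#'
#' @param variants variant table; one row per carrier per variant, optional
#'   integer column `n_alt_alleles`.
#' @param gene gene symbol to count.
#' @param n_individuals cohort size (number of individuals).
#' @param cohort cohort name for the output record.
#' @param af_threshold maximum gnomAD AF for a variant to count as rare.
#' @param lof_classes consequence classes counted as loss-of-function.
#' @param alleles_per_individual allele denominator per individual: 2 for
#'   autosomes and for female-only cohorts on X; 1 for hemizygous males.
#' @return a [gene_burden()] record.
#' @export
count_lof_alleles <- function(variants, gene, n_individuals,
                              cohort = "cohort", af_threshold = 0.005,
                              lof_classes = c("stop_gain", "frameshift",
                                              "splice_essential"),
                              alleles_per_individual = 2) {
  if (missing(n_individuals) || is.null(n_individuals))
    stop("cohort size (n_individuals) is required")
  bad <- setdiff(lof_classes, .consequence_levels)
  if (length(bad))
    stop("unknown consequence class '", bad[1], "'; legal values: ",
         paste(.consequence_levels, collapse = ", "))
  v <- variants[!is.na(variants$gene) & variants$gene == gene, , drop = FALSE]
  af <- ifelse(is.na(v$gnomad_af), 0, v$gnomad_af)
  v <- v[v$consequence %in% lof_classes & af <= af_threshold, , drop = FALSE]
  n_alt <- if ("n_alt_alleles" %in% names(v)) v$n_alt_alleles else
    rep(1L, nrow(v))
  gene_burden(gene, cohort, sum(n_alt),
              alleles_per_individual * n_individuals)
}

#' Case-control enrichment for one gene (exact test)
#'
#' The point estimate is the unconditional cross-product odds ratio
#' \deqn{OR = \frac{a_{case} (N_{ctrl} - a_{ctrl})}{(N_{case} - a_{case})\,
#' a_{ctrl}},}
#' the p-value is the one-sided (enrichment-direction) exact hypergeometric
#' upper tail \eqn{P(X \ge a_{case})} with margins fixed, and the confidence
#' interval is the conditional exact interval (as returned by Fisher's exact
#' test), which is approximate relative to the cross-product point estimate.
#' With a zero cell the OR is undefined (`NA`) unless `haldane = TRUE`, which
#' adds 0.5 to every cell for the point estimate.
#'
#' @param a_case,n_case LoF alleles and allele denominator in cases.
#' @param a_ctrl,n_ctrl same for the control cohort.
#' @param gene optional gene symbol carried into the result.
#' @param two_sided also report the two-sided Fisher p-value.
#' @param haldane apply the Haldane-Anscombe 0.5 correction to zero cells.
#' @param conf_level confidence level of the interval.
#' @return one-row data.frame with `gene`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_one_sided` (and `p_two_sided` if requested).
#' @export
fisher_enrichment <- function(a_case, n_case, a_ctrl, n_ctrl, gene = NA,
                              two_sided = FALSE, haldane = FALSE,
                              conf_level = 0.95) {
  if (any(c(a_case, n_case, a_ctrl, n_ctrl) < 0))
    stop("negative inputs")
  if (a_case > n_case || a_ctrl > n_ctrl)
    stop("allele count exceeds allele denominator")
  b_case <- n_case - a_case
  b_ctrl <- n_ctrl - a_ctrl
  if (a_ctrl == 0 || b_case == 0) {
    odds_ratio <- if (haldane)
      ((a_case + 0.5) * (b_ctrl + 0.5)) / ((b_case + 0.5) * (a_ctrl + 0.5))
    else NA_real_
  } else {
    odds_ratio <- (a_case * b_ctrl) / (b_case * a_ctrl)
  }
  # exact hypergeometric upper tail P(X >= a_case), margins fixed
  k <- a_case + a_ctrl
  p_one <- if (a_case == 0) 1 else
    phyper(a_case - 1, k, (n_case + n_ctrl) - k, n_case, lower.tail = FALSE)
  tab <- matrix(c(a_case, b_case, a_ctrl, b_ctrl), nrow = 2)
  ft <- fisher.test(tab, conf.level = conf_level)
  out <- data.frame(gene = gene, odds_ratio = odds_ratio,
                    ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                    p_one_sided = p_one, stringsAsFactors = FALSE)
  if (two_sided) out$p_two_sided <- ft$p.value
  out
}

#' Combine burden records from disjoint cohorts
#'
#' @param records data.frame of [gene_burden()] rows for a single gene from
#'   disjoint cohorts.
#' @param cohort name of the combined cohort.
#' @return a [gene_burden()] record with summed counts and denominators.
#' @export
combine_cohorts <- function(records, cohort = "combined") {
  if (nrow(records) == 0) stop("no records to combine")
  if (length(unique(records$gene)) != 1)
    stop("combine_cohorts expects records for a single gene")
  if (anyDuplicated(records$cohort))
    stop("cohorts must be disjoint (duplicate cohort name)")
  gene_burden(records$gene[1], cohort,
              sum(records$lof_alleles), sum(records$total_alleles))
}

#' Rank genes by ascending p-value within groups
#'
#' Rank 1 is the smallest p-value within each group; ties are broken by
#' descending odds ratio, then by gene symbol.
#'
#' @param results data.frame with columns `gene`, `p_one_sided`, `odds_ratio`.
#' @param group optional vector of group labels (one per row); a single group
#'   by default.
#' @return `results` with a `rank` column appended, original row order kept.
#' @export
rank_genes <- function(results, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(results))
  if (anyDuplicated(paste(group, results$gene)))
    stop("one result per gene per group required")
  rank <- integer(nrow(results))
  or_key <- ifelse(is.na(results$odds_ratio), -Inf, results$odds_ratio)
  for (g in unique(group)) {
    i <- which(group == g)
    ord <- order(results$p_one_sided[i], -or_key[i], results$gene[i],
                 method = "radix")
    rank[i[ord]] <- seq_along(i)
  }
  results$rank <- rank
  results
}

#' Case-control burden table across genes and control cohorts
#'
#' High-level wrapper reproducing the shape of a published burden table: for
#' each gene and each control cohort it computes the cross-product OR, exact
#' CI, one-sided p and within-group rank from per-gene allele counts.
#'
#' @param counts data.frame with columns `gene`, `cohort`, `lof_alleles`,
#'   `total_alleles` (long format, one row per gene x cohort) and optionally
#'   `group`.
#' @param case_cohort name of the case cohort in `counts`.
#' @param control_cohorts control cohort names; defaults to all non-case
#'   cohorts.
#' @param haldane passed to [fisher_enrichment()].
#' @return data.frame with one row per gene x control cohort: counts, AF%,
#'   OR, CI, one-sided p and rank (within group and control cohort).
#' @export
burden_table <- function(counts, case_cohort = "cases",
                         control_cohorts = NULL, haldane = FALSE) {
  if (!case_cohort %in% counts$cohort)
    stop("case cohort '", case_cohort, "' not present in counts")
  if (is.null(control_cohorts))
    control_cohorts <- setdiff(unique(counts$cohort), case_cohort)
  grp <- if ("group" %in% names(counts)) counts$group else
    rep("all", nrow(counts))
  out <- list()
  for (ctrl in control_cohorts) {
    cs <- counts[counts$cohort == case_cohort, , drop = FALSE]
    ct <- counts[counts$cohort == ctrl, , drop = FALSE]
    idx <- match(cs$gene, ct$gene)
    keep <- !is.na(idx)
    cs <- cs[keep, , drop = FALSE]
    ct <- ct[idx[keep], , drop = FALSE]
    res <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
      fisher_enrichment(cs$lof_alleles[i], cs$total_alleles[i],
                        ct$lof_alleles[i], ct$total_alleles[i],
                        gene = cs$gene[i], haldane = haldane)
    }))
    res <- cbind(
      res[, "gene", drop = FALSE],
      control_cohort = ctrl,
      a_case = cs$lof_alleles, n_case = cs$total_alleles,
      af_case_percent = 100 * cs$lof_alleles / cs$total_alleles,
      a_ctrl = ct$lof_alleles, n_ctrl = ct$total_alleles,
      af_ctrl_percent = 100 * ct$lof_alleles / ct$total_alleles,
      res[, setdiff(names(res), "gene"), drop = FALSE])
    res <- rank_genes(res, group = grp[counts$cohort == case_cohort][keep])
    out[[ctrl]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Published HGSOC case-control LoF allele counts
#'
#' Per-gene counts of rare (gnomAD AF <= 0.005) LoF variant alleles in 496
#' HGSOC cases versus three control cohorts -- gnomAD non-Finnish non-cancer
#' (n = 59,095), MGRB (n = 2572) and Lifepool (n = 1703) -- for six proposed
#' and 43 candidate predisposition genes, shipped as a plain-text fixture.
#' Returned in the long format expected by [burden_table()], including the
#' combined MGRB + Lifepool cohort (n = 4275). X-linked genes (for which the
#' published hemizygote denominators are approximate) carry `chrom_type = "X"`.
#'
#' @return data.frame with `gene`, `group`, `chrom_type`, `cohort`,
#'   `lof_alleles`, `total_alleles`.
#' @export
hgsoc_lof_counts <- function() {
  path <- system.file("extdata", "hgsoc_lof_counts.tsv",
                      package = "twohitscan", mustWork = TRUE)
  wide <- read.delim(path, stringsAsFactors = FALSE)
  sizes <- c(cases = 496, gnomad = 59095, mgrb = 2572, lifepool = 1703,
             combined = 4275)
  wide$a_combined <- wide$a_mgrb + wide$a_lifepool
  long <- do.call(rbind, lapply(names(sizes), function(ch) {
    data.frame(gene = wide$gene, group = wide$group,
               chrom_type = wide$chrom_type, cohort = ch,
               lof_alleles = wide[[paste0("a_", ch)]],
               total_alleles = 2L * sizes[[ch]],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
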