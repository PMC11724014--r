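#' @keywords internal
.status_categories <- c("WT_LOST", "VARIANT_LOST", "HETEROZYGOUS",
                        "HET_WITH_SOMATIC_HIT_PHASE_UNKNOWN",
                        "WT_LOST_BY_SOMATIC_HIT",
                        "VARIANT_LOST_WT_METHYLATED", "HET_WT_METHYLATED",
                        "HET_ONE_ALLELE_METHYLATED", "AMBIGUOUS")

#' Allelic-status classification configuration
#'
#' @param bf_min minimum Bayes factor of the best over the runner-up
#'   hypothesis for a confident call; below it the call is `AMBIGUOUS` rather
#'   than forced (ambiguous tumours were resolved orthogonally, e.g. by Sanger
#'   sequencing, modelled here as an override input). Default `exp(2)`, i.e.
#'   2 natural-log units.
#' @param phase_unknown_biallelic count "heterozygous with somatic second hit,
#'   phase unknown" as biallelic (default), assuming the somatic hit lies on
#'   the wildtype allele; `FALSE` gives the strict policy.
#' @param cadd_min,revel_min thresholds above which a somatic missense variant
#'   qualifies as a second hit (both annotations must be present and pass).
#' @param min_purity purity floor below which classification refuses to call
#'   (tumours are dissected to at least this purity).
#' @param lof_classes somatic consequence classes that always qualify as a
#'   second hit.
#' @return list of class `status_config`.
#' @export
status_config <- function(bf_min = exp(2), phase_unknown_biallelic = TRUE,
                          cadd_min = 20, revel_min = 0.5, min_purity = 0.3,
                          lof_classes = c("stop_gain", "frameshift",
                                          "splice_essential")) {
  structure(list(bf_min = bf_min,
                 phase_unknown_biallelic = phase_unknown_biallelic,
                 cadd_min = cadd_min, revel_min = revel_min,
                 min_purity = min_purity, lof_classes = lof_classes),
            class = "status_config")
}

#' Score allelic-fate hypotheses for a germline variant in a tumour
#'
#' For each hypothesis in [vaf_hypotheses()] the expected VAF is computed by
#' the purity forward model and the observed alternate-read count is scored
#' with a binomial log-likelihood at that expected VAF. Hypotheses
#' incompatible with the segment's copy-number state are flagged but still
#' scored.
#'
#' @param alt_reads,ref_reads read counts of the germline variant in the
#'   tumour specimen (depth must be positive).
#' @param segment one-row data.frame (or list) with `total_cn`, `minor_cn`;
#'   `NULL` scores all hypotheses as compatible.
#' @param purity tumour purity in (0, 1].
#' @return list with `loglik`, `expected_vafs` (named per hypothesis),
#'   `compatible` (named logical) and `hypotheses` (the scored table).
#' @export
score_hypotheses <- function(alt_reads, ref_reads, segment, purity) {
  depth <- alt_reads + ref_reads
  if (is.na(depth) || depth <= 0) stop("zero depth: cannot score hypotheses")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  h <- if (is.null(segment)) vaf_hypotheses() else
    vaf_hypotheses(segment$total_cn, segment$minor_cn)
  h$expected_vaf <- expected_vaf(h$m_v, h$n_t, purity, germline = TRUE)
  h$loglik <- dbinom(alt_reads, depth, h$expected_vaf, log = TRUE)
  list(loglik = setNames(h$loglik, h$label),
       expected_vafs = setNames(h$expected_vaf, h$label),
       compatible = setNames(h$compatible, h$label),
       hypotheses = h)
}

#' @keywords internal
.is_second_hit <- function(somatic_hits, cfg) {
  if (is.null(somatic_hits) || nrow(somatic_hits) == 0)
    return(somatic_hits[0, , drop = FALSE])
  lof <- somatic_hits$consequence %in% cfg$lof_classes
  mis <- somatic_hits$consequence == "missense" &
    !is.na(somatic_hits$cadd_phred) & somatic_hits$cadd_phred >= cfg$cadd_min &
    !is.na(somatic_hits$revel) & somatic_hits$revel >= cfg$revel_min
  somatic_hits[lof | mis, , drop = FALSE]
}

#' Classify the two-hit (allelic) status of a gene of interest in one tumour
#'
#' Joint interrogation of the germline variant's tumour VAF, the local
#' allele-specific copy-number state, qualifying somatic second hits, and
#' promoter methylation:
#'
#' 1. Hypotheses are scored by binomial likelihood at their purity-adjusted
#'    expected VAFs; the winner is chosen among hypotheses *compatible* with
#'    the segment copy-number state (the copy-number corroboration the VAF
#'    evidence must agree with), requiring a Bayes factor of at least
#'    `cfg$bf_min` over the compatible runner-up, else `AMBIGUOUS`.
#' 2. If an incompatible hypothesis beats every compatible one by
#'    `cfg$bf_min`, the VAF and copy-number evidence conflict: `AMBIGUOUS`.
#' 3. A `VARIANT_LOST` call is upgraded to `WT_LOST_BY_SOMATIC_HIT` when a
#'    qualifying somatic hit is present (the remaining allele is the wildtype
#'    and it carries the somatic hit), or to `VARIANT_LOST_WT_METHYLATED`
#'    when the remaining wildtype allele's promoter is methylated.
#' 4. A `HETEROZYGOUS` call with a qualifying somatic hit becomes
#'    `HET_WITH_SOMATIC_HIT_PHASE_UNKNOWN`; with wildtype-allele promoter
#'    methylation it becomes `HET_WT_METHYLATED`; with methylation of an
#'    undetermined allele, `HET_ONE_ALLELE_METHYLATED`.
#'
#' @param germline_obs one-row variant table of the germline variant of
#'   interest observed in the tumour.
#' @param segment one-row segment (from the tumour's [segment_profile()])
#'   covering the variant, or `NULL` if no copy-number data is available.
#' @param purity tumour purity in (0, 1].
#' @param somatic_hits filtered somatic variants in the gene (candidate
#'   second hits); LoF classes always qualify, missense only with CADD and
#'   REVEL above the configured thresholds.
#' @param methylation a [methylation_call()] for the gene, or `NULL`.
#' @param cfg a [status_config()].
#' @param override optional category string from orthogonal evidence (e.g.
#'   Sanger adjudication); replaces an `AMBIGUOUS` call.
#' @return object of class `allelic_status_call`: `sample_id`, `gene`,
#'   `category`, `biallelic`, `loglik`, `expected_vafs`, `segment_used`,
#'   `somatic_hits`, `methylation`.
#' @export
classify_allelic_status <- function(germline_obs, segment, purity,
                                    somatic_hits = NULL, methylation = NULL,
                                    cfg = status_config(), override = NULL) {
  if (purity < cfg$min_purity)
    stop(sprintf("purity %.2f below classification floor %.2f",
                 purity, cfg$min_purity))
  sc <- score_hypotheses(germline_obs$alt_reads, germline_obs$ref_reads,
                         segment, purity)
  ll <- sc$loglik
  comp <- sc$compatible
  log_bf_min <- log(cfg$bf_min)

  hyp_category <- c(balanced_het = "HETEROZYGOUS",
                    wt_lost_deletion = "WT_LOST",
                    wt_lost_cnloh = "WT_LOST",
                    variant_lost = "VARIANT_LOST")
  comp_ll <- ll[comp]
  if (!length(comp_ll)) {
    category <- "AMBIGUOUS"
  } else {
    best <- names(comp_ll)[which.max(comp_ll)]
    category <- hyp_category[[best]]
    # runner-up comparison only across hypotheses implying a different
    # verdict: deletion vs CN-LOH both mean the wildtype allele is gone
    rivals <- comp_ll[hyp_category[names(comp_ll)] != category]
    if (length(rivals) && comp_ll[best] - max(rivals) < log_bf_min)
      category <- "AMBIGUOUS"
    # VAF / copy-number conflict: an incompatible hypothesis with a
    # *different* verdict decisively beats everything the CN state allows
    incomp <- ll[!comp][hyp_category[names(ll[!comp])] != category]
    if (length(incomp) && max(incomp) - comp_ll[best] >= log_bf_min)
      category <- "AMBIGUOUS"
  }

  hits <- .is_second_hit(somatic_hits, cfg)
  has_hit <- !is.null(hits) && nrow(hits) > 0
  meth_status <- if (is.null(methylation)) "unknown" else methylation$status
  meth_allele <- if (is.null(methylation)) "unknown" else
    methylation$methylated_allele
  wt_methylated <- meth_status == "homozygous_methylated" ||
    (meth_status == "heterozygous_methylated" && meth_allele == "wildtype")

  if (category == "VARIANT_LOST") {
    if (has_hit) category <- "WT_LOST_BY_SOMATIC_HIT"
    else if (wt_methylated) category <- "VARIANT_LOST_WT_METHYLATED"
  } else if (category == "HETEROZYGOUS") {
    if (has_hit) category <- "HET_WITH_SOMATIC_HIT_PHASE_UNKNOWN"
    else if (wt_methylated) category <- "HET_WT_METHYLATED"
    else if (meth_status == "heterozygous_methylated")
      category <- "HET_ONE_ALLELE_METHYLATED"
  }
  if (category == "AMBIGUOUS" && !is.null(override)) {
    stopifnot(override %in% .status_categories)
    category <- override
  }

  biallelic <- category %in% c("WT_LOST", "WT_LOST_BY_SOMATIC_HIT",
                               "VARIANT_LOST_WT_METHYLATED",
                               "HET_WT_METHYLATED") ||
    (category == "HET_WITH_SOMATIC_HIT_PHASE_UNKNOWN" &&
       cfg$phase_unknown_biallelic)

  structure(list(
    sample_id = if ("sample_id" %in% names(germline_obs))
      germline_obs$sample_id else NA_character_,
    gene = germline_obs$gene,
    category = category, biallelic = biallelic,
    loglik = ll, expected_vafs = sc$expected_vafs,
    compatible = comp, segment_used = segment,
    somatic_hits = hits, methylation = methylation),
    class = "allelic_status_call")
}

#' @method print allelic_status_call
#' @export
print.allelic_status_call <- function(x, ...) {
  cat(sprintf("%s / %s: %s (biallelic: %s)\n",
              x$sample_id, x$gene, x$category,
              ifelse(x$biallelic, "YES", "NO")))
  invisible(x)
}

#' Summarise allelic-status calls across the tumours of one gene
#'
#' @param calls list of [classify_allelic_status()] calls for one gene.
#' @return list with counts (`n_tumours`, `n_biallelic`, `n_wt_lost`,
#'   `n_variant_lost`, `n_het`) and `pattern`: `consistent_biallelic` when
#'   every tumour shows biallelic inactivation, `variant_loss_observed` when
#'   any tumour lost the variant allele without a rescue of the call,
#'   `heterozygous_only` when every tumour stayed heterozygous, else
#'   `partial`.
#' @export
summarize_gene <- function(calls) {
  if (!length(calls)) stop("no calls to summarise")
  cats <- vapply(calls, function(x) x$category, "")
  bi <- vapply(calls, function(x) x$biallelic, TRUE)
  n_wt_lost <- sum(cats %in% c("WT_LOST", "WT_LOST_BY_SOMATIC_HIT"))
  n_variant_lost <- sum(cats %in% c("VARIANT_LOST",
                                    "VARIANT_LOST_WT_METHYLATED"))
  het_like <- c("HETEROZYGOUS", "HET_WITH_SOMATIC_HIT_PHASE_UNKNOWN",
                "HET_WT_METHYLATED", "HET_ONE_ALLELE_METHYLATED")
  n_het <- sum(cats %in% het_like)
  pattern <- if (all(bi)) "consistent_biallelic"
  else if (any(cats == "VARIANT_LOST")) "variant_loss_observed"
  else if (all(cats %in% c("HETEROZYGOUS", "HET_ONE_ALLELE_METHYLATED")))
    "heterozygous_only"
  else "partial"
  list(n_tumours = length(calls), n_biallelic = sum(bi),
       n_wt_lost = n_wt_lost, n_variant_lost = n_variant_lost,
       n_het = n_het, pattern = pattern)
}
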