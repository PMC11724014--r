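#' Somatic variant filter configuration
#'
#' Defaults model the final filtering stage of an FFPE tumour-exome somatic
#' pipeline: population-frequency removal at gnomAD AF > 1e-4, restriction to
#' capture targets extended by 150 bp at either end, minimum depth and
#' alternate-read support, and a purity-adjusted VAF cut-off
#' `max(vaf_floor, vaf_purity_factor * p / 2)` -- i.e. a variant must reach a
#' configurable fraction of the expected clonal heterozygous VAF `p/2`. The
#' `stringent` profile (for unpaired tumours where residual germline variants
#' must be excluded) requires absence from gnomAD, 8 alternate reads and
#' VAF >= 0.10.
#'
#' @param max_gnomad_af maximum gnomAD AF (missing AF is treated as 0).
#' @param target_extension_bp extension added to each side of each target
#'   interval; the boundary is inclusive.
#' @param min_depth,min_alt_reads read-support thresholds.
#' @param vaf_floor absolute VAF floor.
#' @param vaf_purity_factor multiple of the expected clonal-het VAF `p/2`
#'   required.
#' @param stringent use the stringent unpaired-sample profile.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(max_gnomad_af = 1e-4, target_extension_bp = 150,
                          min_depth = 10, min_alt_reads = 4,
                          vaf_floor = 0.03, vaf_purity_factor = 0.2,
                          stringent = FALSE) {
  if (stringent) {
    max_gnomad_af <- 0
    min_alt_reads <- max(min_alt_reads, 8)
    vaf_floor <- max(vaf_floor, 0.10)
  }
  cfg <- list(max_gnomad_af = max_gnomad_af,
              target_extension_bp = target_extension_bp,
              min_depth = min_depth, min_alt_reads = min_alt_reads,
              vaf_floor = vaf_floor, vaf_purity_factor = vaf_purity_factor,
              stringent = stringent)
  if (any(unlist(cfg[1:6]) < 0)) stop("filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Filter somatic variants with a purity-adjusted VAF cut-off
#'
#' Applies the filter rules in a fixed order -- gnomAD AF, target region,
#' depth, alternate reads, VAF -- attributing each removed variant to the
#' first failing rule, so the audit counts always sum to the number removed.
#' A variant passes the VAF rule if
#' `vaf >= max(vaf_floor, vaf_purity_factor * purity / 2)`. A variant passes
#' the target rule if it lies within `target_extension_bp` of a target
#' interval (inclusive boundary). Input order is preserved in the kept set,
#' and the filter is idempotent.
#'
#' @param variants somatic variant table.
#' @param purity tumour purity in (0, 1].
#' @param targets data.frame of target intervals (`chrom`, `start`, `end`,
#'   1-based inclusive, e.g. from [read_targets()]); `NULL` skips the target
#'   rule.
#' @param cfg a [filter_config()].
#' @return list with `kept` (filtered variant table) and `audit` (named
#'   integer vector of per-rule removal counts).
#' @export
filter_somatic <- function(variants, purity, targets = NULL,
                           cfg = filter_config()) {
  if (length(purity) != 1 || is.na(purity) || purity <= 0 || purity > 1)
    stop("purity must be a single value in (0, 1]")
  rules <- c("gnomad_af", "target", "depth", "alt_reads", "vaf")
  audit <- setNames(integer(length(rules)), rules)
  n <- nrow(variants)
  if (n == 0) return(list(kept = variants, audit = audit))

  af <- ifelse(is.na(variants$gnomad_af), 0, variants$gnomad_af)
  fail_af <- af > cfg$max_gnomad_af

  if (is.null(targets)) {
    fail_target <- rep(FALSE, n)
  } else {
    fail_target <- rep(TRUE, n)
    for (ch in unique(variants$chrom)) {
      vi <- which(variants$chrom == ch)
      ti <- which(targets$chrom == ch)
      if (!length(ti)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = variants$pos[vi], width = 1L),
        IRanges::IRanges(
          start = targets$start[ti] - cfg$target_extension_bp,
          end = targets$end[ti] + cfg$target_extension_bp))
      fail_target[vi[unique(S4Vectors::queryHits(hits))]] <- FALSE
    }
  }

  depth <- variants$alt_reads + variants$ref_reads
  fail_depth <- is.na(depth) | depth < cfg$min_depth
  fail_alt <- is.na(variants$alt_reads) |
    variants$alt_reads < cfg$min_alt_reads
  vaf_cut <- max(cfg$vaf_floor, cfg$vaf_purity_factor * purity / 2)
  fail_vaf <- is.na(variants$vaf) | variants$vaf < vaf_cut

  fails <- cbind(gnomad_af = fail_af, target = fail_target,
                 depth = fail_depth, alt_reads = fail_alt, vaf = fail_vaf)
  first_fail <- apply(fails, 1, function(r)
    if (any(r)) which(r)[1] else NA_integer_)
  removed <- !is.na(first_fail)
  tab <- table(factor(rules[first_fail[removed]], levels = rules))
  audit[names(tab)] <- as.integer(tab)
  list(kept = variants[!removed, , drop = FALSE], audit = audit)
}

#' Pool unique single-base substitutions across tumours
#'
#' Takes filtered somatic variant tables from tumours sharing biallelic
#' inactivation of the same gene, keeps single-nucleotide REF/ALT records
#' only, and deduplicates on `(chrom, pos, ref, alt)` so that a substitution
#' shared by several tumours is counted once in the pooled catalogue.
#'
#' @param samples named list of somatic variant tables (one per tumour).
#' @return list with `pooled` (deduplicated SBS variant table) and `audit`
#'   (counts of `non_sbs` and `duplicate` records dropped).
#' @export
pool_unique_sbs <- function(samples) {
  if (!length(samples)) stop("no samples to pool")
  all <- do.call(rbind, unname(samples))
  snv <- nchar(all$ref) == 1 & nchar(all$alt) == 1 &
    all$ref %in% c("A", "C", "G", "T") & all$alt %in% c("A", "C", "G", "T")
  audit <- c(non_sbs = sum(!snv))
  all <- all[snv, , drop = FALSE]
  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = "\r")
  dup <- duplicated(key)
  audit["duplicate"] <- sum(dup)
  pooled <- all[!dup, , drop = FALSE]
  rownames(pooled) <- NULL
  list(pooled = pooled, audit = audit)
}
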