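#' Expected variant allele fraction under a purity / copy-number hypothesis
#'
#' Forward model for the VAF of a variant observed in a tumour specimen of
#' purity `p`. Tumour cells carry `m_v` variant copies out of `n_t` total
#' copies at the locus; admixed normal cells are diploid and carry one variant
#' copy for a germline heterozygous variant and none for a somatic variant:
#' \deqn{v = \frac{p\,m_v + (1-p)\,g}{p\,n_t + (1-p)\,2},}
#' with \eqn{g = 1} (germline het) or \eqn{g = 0} (somatic).
#'
#' @param m_v variant copies per tumour cell (0 <= m_v <= n_t).
#' @param n_t total copies per tumour cell at the locus.
#' @param purity tumour purity p in (0, 1].
#' @param germline logical; germline heterozygous variant (TRUE) or somatic
#'   variant (FALSE).
#' @return expected VAF in \[0, 1\]. Vectorised over all arguments.
#' @export
expected_vaf <- function(m_v, n_t, purity, germline = TRUE) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(m_v < 0) || any(m_v > n_t)) stop("need 0 <= m_v <= n_t")
  g <- as.numeric(germline)
  (purity * m_v + (1 - purity) * g) / (purity * n_t + (1 - purity) * 2)
}

#' Allelic-fate hypotheses for a germline variant on a copy-number segment
#'
#' The four canonical hypotheses scored when classifying the allelic status of
#' a germline heterozygous variant: `balanced_het` (m_v = 1, n_t = 2),
#' `wt_lost_deletion` (1, 1), `wt_lost_cnloh` (2, 2), and `variant_lost`
#' (m_v = 0 with n_t taken from the segment's total copy number, so that a
#' one-copy deletion segment gives the expected VAF (1-p)/(2-p)). Each
#' hypothesis is marked compatible or not with the segment's allele-specific
#' copy-number state.
#'
#' @param total_cn,minor_cn segment copy-number state (may be `NA`, in which
#'   case every hypothesis is considered compatible).
#' @return data.frame with `label`, `m_v`, `n_t`, `compatible`.
#' @export
vaf_hypotheses <- function(total_cn = NA, minor_cn = NA) {
  n_vl <- if (is.na(total_cn)) 1 else max(total_cn, 1)
  h <- data.frame(
    label = c("balanced_het", "wt_lost_deletion", "wt_lost_cnloh",
              "variant_lost"),
    m_v = c(1, 1, 2, 0),
    n_t = c(2, 1, 2, n_vl),
    stringsAsFactors = FALSE)
  if (is.na(total_cn) || is.na(minor_cn)) {
    h$compatible <- TRUE
  } else {
    h$compatible <- c(minor_cn >= 1,
                      total_cn == 1 && minor_cn == 0,
                      total_cn == 2 && minor_cn == 0,
                      minor_cn == 0)
  }
  h
}

#' Construct a purity estimate
#'
#' @param value purity in (0, 1].
#' @param method one of `cn_fit`, `visual_cn`, `somatic_vaf`, `consensus`.
#' @param n_support number of observations supporting the estimate.
#' @param detail free-text provenance.
#' @return object of class `purity_estimate`.
#' @export
purity_estimate <- function(value, method = c("cn_fit", "visual_cn",
                                              "somatic_vaf", "consensus"),
                            n_support = 1L, detail = "") {
  method <- match.arg(method)
  if (!is.finite(value) || value <= 0 || value > 1)
    stop("purity estimate must be in (0, 1]")
  structure(list(value = value, method = method,
                 n_support = as.integer(n_support), detail = detail),
            class = "purity_estimate")
}

#' @method print purity_estimate
#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("purity %.3f (%s, n = %d)%s\n", x$value, x$method, x$n_support,
              if (nzchar(x$detail)) paste0(" - ", x$detail) else ""))
  invisible(x)
}

#' Estimate tumour purity from somatic VAFs on single-copy LOH segments
#'
#' For a clonal somatic variant sitting on a segment with total copy number 1
#' and minor copy number 0 (the wildtype allele lost), the expected VAF is
#' \eqn{v = p / (2 - p)}; inverting gives a per-variant purity estimate
#' \eqn{\hat p = 2v / (1 + v)}. The estimator is the depth-weighted mean of
#' the per-variant estimates, clipped to (0, 1]. TP53 variants are the typical
#' input.
#'
#' @param variants somatic variant table with `alt_reads`, `ref_reads`.
#' @param profile optional [segment_profile()]; when supplied, each variant is
#'   checked to lie on a `total_cn = 1, minor_cn = 0` segment and offending
#'   variants are rejected.
#' @return a [purity_estimate()] with method `"somatic_vaf"`.
#' @export
purity_from_somatic_vaf <- function(variants, profile = NULL) {
  if (is.null(variants) || nrow(variants) == 0)
    stop("no informative variants")
  depth <- variants$alt_reads + variants$ref_reads
  if (any(is.na(depth) | depth <= 0))
    stop("informative variants require positive depth")
  if (!is.null(profile)) {
    seg <- profile$segments
    for (i in seq_len(nrow(variants))) {
      j <- which(seg$chrom == variants$chrom[i] &
                   seg$start <= variants$pos[i] & seg$end >= variants$pos[i])
      if (length(j) != 1 || seg$total_cn[j] != 1 || seg$minor_cn[j] != 0)
        stop("variant ", variants$chrom[i], ":", variants$pos[i],
             " does not lie on a single-copy LOH segment")
    }
  }
  v <- variants$alt_reads / depth
  p_hat <- 2 * v / (1 + v)
  est <- sum(p_hat * depth) / sum(depth)
  est <- min(max(est, .Machine$double.eps), 1)
  purity_estimate(est, method = "somatic_vaf", n_support = nrow(variants),
                  detail = "depth-weighted mean of 2v/(1+v)")
}

#' Consensus purity as the unweighted mean of available estimators
#'
#' Mirrors the study design in which a copy-number model fit, a visual
#' copy-number estimate and a somatic-VAF estimate are averaged. Estimates are
#' combined by an unweighted arithmetic mean regardless of their `n_support`.
#'
#' @param estimates list of [purity_estimate()] objects (or bare numerics).
#' @return a [purity_estimate()] with method `"consensus"` and `n_support`
#'   equal to the number of estimators averaged.
#' @export
consensus_purity <- function(estimates) {
  if (length(estimates) == 0) stop("no purity estimates to combine")
  vals <- vapply(estimates, function(e)
    if (inherits(e, "purity_estimate")) e$value else as.numeric(e), 0)
  purity_estimate(mean(vals), method = "consensus",
                  n_support = length(vals),
                  detail = "unweighted mean of estimator values")
}
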