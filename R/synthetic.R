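#' Miniature genome arm definitions for simulation
#'
#' A configurable miniature genome: `n_chrom` autosomes of `chrom_len` bp with
#' a centromere at 40-42 Mb -- large enough to host the > 15 Mb / >= 10 Mb
#' scar events the HRD counters look for, small enough for fast tests.
#'
#' @param n_chrom number of autosomes (`chr1` ... `chrN`).
#' @param chrom_len chromosome length in bp.
#' @param cen_start,cen_end centromere bounds in bp.
#' @return chromosome-arm data.frame (see [read_arms()]).
#' @export
mini_genome_arms <- function(n_chrom = 3, chrom_len = 100e6,
                             cen_start = 40e6, cen_end = 42e6) {
  validate_arms(data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    chrom_start = 1, cen_start = cen_start, cen_end = cen_end,
    chrom_end = chrom_len, stringsAsFactors = FALSE))
}

#' Simulate a rare-LoF case-control cohort with known odds ratios
#'
#' Control carrier chromosomes are drawn as Binomial(2 n_controls, f) per
#' gene; case chromosomes as Binomial(2 n_cases, f') where the carrier odds
#' are multiplied by the gene's true odds ratio.
#'
#' @param n_cases,n_controls cohort sizes (individuals).
#' @param genes gene symbols.
#' @param base_carrier_freq per-chromosome carrier frequency f in (0, 1);
#'   recycled across genes.
#' @param or_per_gene true odds ratio per gene (> 0); recycled.
#' @param seed optional RNG seed.
#' @return list with `case` and `control` burden count data.frames (columns
#'   as in [gene_burden()]) and `truth` (per-gene f and true OR).
#' @export
gen_cohort <- function(n_cases, n_controls, genes, base_carrier_freq,
                       or_per_gene = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- rep_len(base_carrier_freq, length(genes))
  or <- rep_len(or_per_gene, length(genes))
  if (any(f < 0 | f >= 1)) stop("base_carrier_freq must be in [0, 1)")
  if (any(or <= 0)) stop("odds ratios must be > 0")
  odds_case <- f / (1 - f) * or
  f_case <- odds_case / (1 + odds_case)
  if (any(f_case >= 1)) stop("case carrier odds exceed 1")
  a_ctrl <- rbinom(length(genes), 2L * n_controls, f)
  a_case <- rbinom(length(genes), 2L * n_cases, f_case)
  make <- function(a, n, cohort) data.frame(
    gene = genes, cohort = cohort, lof_alleles = a,
    total_alleles = 2L * n, af_percent = 100 * a / (2 * n),
    stringsAsFactors = FALSE)
  list(case = make(a_case, n_cases, "cases"),
       control = make(a_ctrl, n_controls, "controls"),
       truth = list(base_carrier_freq = setNames(f, genes),
                    cohort_or_true = setNames(or, genes)))
}

# Fixed within-arm layouts for planted events (1-based bp on the mini genome).
# Every event is isolated from its neighbours by >= 4 Mb of unprofiled
# sequence so that no planted event creates adjacencies countable as LST, and
# each event satisfies exactly one counter's rule.
.slot_layout <- function(arm, a) {
  if (arm == "p") list(
    loh = c(11e6 + 1, 31e6),
    tai = c(a$chrom_start, 15e6),
    lst = rbind(c(9e6 + 1, 21e6), c(21e6 + 1, 33e6)),
    gene = c(11e6 + 1, 21e6))
  else list(
    loh = c(50e6 + 1, 70e6),
    tai = c(85e6 + 1, a$chrom_end),
    lst = rbind(c(50e6 + 1, 62e6), c(62e6 + 1, 74e6)),
    gene = c(50e6 + 1, 60e6))
}

#' @keywords internal
.rpois_min <- function(n, lambda, min = 0) {
  x <- rpois(n, lambda)
  while (any(x < min)) x[x < min] <- rpois(sum(x < min), lambda)
  pmax(x, 1L)
}

#' Simulate one tumour with a planted allelic fate and planted HRD scars
#'
#' Emulates the observed regime of an FFPE tumour-exome study: dissection to
#' purity >= 30%, mean depth around 90x, and on the order of 68 somatic SBS
#' per exome. The tumour carries a germline heterozygous variant of interest
#' whose allelic fate (`WT_LOST`, `VARIANT_LOST` or `HETEROZYGOUS`) is
#' realised by a 10 Mb copy-number segment (short enough never to perturb the
#' scar counters), read counts drawn binomially at the purity-adjusted
#' expected VAF. Scar events are planted one per chromosome arm with 4 Mb
#' unprofiled buffers so each planted event is counted exactly once by
#' exactly one HRD counter; the remaining genome is a balanced (2,1)
#' baseline. Clonal somatic SNVs are placed on baseline segments with
#' VAF ~ Binomial(depth, p/2), and `n_informative` TP53-like somatic variants
#' are placed on a dedicated single-copy LOH segment for purity estimation.
#'
#' @param purity tumour purity in (0, 1].
#' @param depth_mean mean sequencing depth (Poisson).
#' @param gene_fate planted allelic fate of the gene of interest.
#' @param scar_spec named integer vector `c(loh =, tai =, lst =)` of planted
#'   scar events.
#' @param n_somatic number of clonal somatic passenger SNVs.
#' @param seed optional RNG seed.
#' @param gene gene symbol of the variant of interest.
#' @param sample_id sample identifier.
#' @param wt_loss_mechanism how `WT_LOST` is realised: one-copy deletion
#'   (total 1, minor 0) or copy-neutral LOH (total 2, minor 0).
#' @param gene_total_cn,gene_minor_cn optional explicit copy-number state for
#'   the gene segment; a state contradicting the planted fate (e.g. a fate of
#'   `WT_LOST` on a balanced segment) is an error.
#' @param somatic_second_hit also plant a somatic stop-gain second hit in the
#'   gene of interest.
#' @param methylation optional [methylation_call()] attached to the sample.
#' @param n_informative number of TP53-like purity-informative variants.
#' @param depth_min lower truncation of the per-variant Poisson depth.
#' @param arms optional arm table; by default a [mini_genome_arms()] genome
#'   just large enough for the requested events (at least 3 autosomes).
#' @return list with `sample` (`sample_id`, `purity`, `profile`,
#'   `germline_variant`, `somatic`, `purity_informative`, `methylation`) and
#'   `truth` (purity, gene_fate, scar_counts, expected VAF and copy state of
#'   the variant).
#' @export
gen_tumor <- function(purity, depth_mean = 90,
                      gene_fate = c("WT_LOST", "VARIANT_LOST",
                                    "HETEROZYGOUS"),
                      scar_spec = c(loh = 0, tai = 0, lst = 0),
                      n_somatic = 68, seed = NULL, gene = "GENE1",
                      sample_id = "SIM-TUMOR",
                      wt_loss_mechanism = c("deletion", "cnloh"),
                      gene_total_cn = NULL, gene_minor_cn = NULL,
                      somatic_second_hit = FALSE, methylation = NULL,
                      n_informative = 2, depth_min = 0, arms = NULL) {
  gene_fate <- match.arg(gene_fate)
  wt_loss_mechanism <- match.arg(wt_loss_mechanism)
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  scar_spec <- scar_spec[c("loh", "tai", "lst")]
  scar_spec[is.na(scar_spec)] <- 0
  names(scar_spec) <- c("loh", "tai", "lst")

  n_slots <- sum(scar_spec) + 1L + (n_informative > 0)
  if (is.null(arms))
    arms <- mini_genome_arms(n_chrom = max(3, ceiling(n_slots / 2)))
  slots <- data.frame(chrom = rep(arms$chrom, each = 2),
                      arm = rep(c("p", "q"), nrow(arms)),
                      stringsAsFactors = FALSE)
  if (nrow(slots) < n_slots)
    stop("not enough chromosome arms for the requested events")

  # slot 1 (chr1 q): gene of interest; slot 2 (chr1 p): purity-informative
  gene_state <- switch(gene_fate,
    WT_LOST = if (wt_loss_mechanism == "deletion")
      c(total = 1, minor = 0, m_v = 1) else c(total = 2, minor = 0, m_v = 2),
    VARIANT_LOST = c(total = 1, minor = 0, m_v = 0),
    HETEROZYGOUS = c(total = 2, minor = 1, m_v = 1))
  if (!is.null(gene_total_cn)) {
    need_loh <- gene_fate %in% c("WT_LOST", "VARIANT_LOST")
    if ((need_loh && gene_minor_cn != 0) ||
        (!need_loh && gene_minor_cn == 0))
      stop("contradictory specification: fate ", gene_fate,
           " on a segment with minor_cn = ", gene_minor_cn)
    gene_state["total"] <- gene_total_cn
    gene_state["minor"] <- gene_minor_cn
  }

  events <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), total_cn = numeric(),
                       minor_cn = numeric(), stringsAsFactors = FALSE)
  add_event <- function(chrom, start, end, total, minor)
    rbind(events, data.frame(chrom = chrom, start = start, end = end,
                             total_cn = total, minor_cn = minor,
                             stringsAsFactors = FALSE))

  q1 <- .slot_layout("q", arms[1, ])
  events <- add_event("chr1", q1$gene[1], q1$gene[2],
                      gene_state[["total"]], gene_state[["minor"]])
  gene_pos <- (q1$gene[1] + q1$gene[2]) / 2
  used <- "chr1.q"
  informative_loc <- NULL
  if (n_informative > 0) {
    p1 <- .slot_layout("p", arms[1, ])
    events <- add_event("chr1", p1$gene[1], p1$gene[2], 1, 0)
    informative_loc <- c(p1$gene[1], p1$gene[2])
    used <- c(used, "chr1.p")
  }
  free <- slots[!paste(slots$chrom, slots$arm, sep = ".") %in% used, ,
                drop = FALSE]
  slot_i <- 1L
  for (type in c("loh", "tai", "lst")) {
    for (e in seq_len(scar_spec[[type]])) {
      sl <- free[slot_i, ]
      a <- .arm_row(arms, sl$chrom)
      lay <- .slot_layout(sl$arm, a)
      if (type == "loh") {
        events <- add_event(sl$chrom, lay$loh[1], lay$loh[2], 1, 0)
      } else if (type == "tai") {
        events <- add_event(sl$chrom, lay$tai[1], lay$tai[2], 3, 1)
      } else {
        events <- add_event(sl$chrom, lay$lst[1, 1], lay$lst[1, 2], 2, 1)
        events <- add_event(sl$chrom, lay$lst[2, 1], lay$lst[2, 2], 3, 1)
      }
      slot_i <- slot_i + 1L
    }
  }

  # balanced (2,1) baseline fills the rest, with 4 Mb buffers around events
  buffer <- 4e6
  base <- list()
  for (ci in seq_len(nrow(arms))) {
    ch <- arms$chrom[ci]
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    bounds <- c(arms$chrom_start[ci],
                rbind(ev$start - 1, ev$end + 1), arms$chrom_end[ci])
    for (g in seq_len(nrow(ev) + 1)) {
      lo <- bounds[2 * g - 1]; hi <- bounds[2 * g]
      if (g > 1) lo <- lo + buffer              # buffer after an event
      if (g <= nrow(ev)) hi <- hi - buffer      # buffer before an event
      if (hi - lo + 1 >= 3e6)
        base[[length(base) + 1]] <- data.frame(
          chrom = ch, start = lo, end = hi, total_cn = 2, minor_cn = 1,
          stringsAsFactors = FALSE)
    }
  }
  seg <- rbind(events, do.call(rbind, base))
  profile <- segment_profile(seg, sample_id = sample_id,
                             genome_build = "mini")

  # germline variant of interest
  d <- .rpois_min(1, depth_mean, depth_min)
  ev_vaf <- expected_vaf(gene_state[["m_v"]],
                         max(gene_state[["total"]], 1), purity,
                         germline = TRUE)
  alt <- rbinom(1, d, ev_vaf)
  germline_variant <- variant_table(data.frame(
    sample_id = sample_id, chrom = "chr1", pos = gene_pos, ref = "C",
    alt = "T", gene = gene, consequence = "stop_gain", origin = "germline",
    alt_reads = alt, ref_reads = d - alt, stringsAsFactors = FALSE))

  # clonal somatic passengers on baseline (expected VAF p/2)
  basedf <- do.call(rbind, base)
  somatic <- NULL
  if (n_somatic > 0) {
    pick <- sample(nrow(basedf), n_somatic, replace = TRUE)
    pos <- floor(runif(n_somatic, basedf$start[pick], basedf$end[pick]))
    ref <- sample(c("A", "C", "G", "T"), n_somatic, replace = TRUE)
    alt_base <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    ds <- .rpois_min(n_somatic, depth_mean, depth_min)
    as_ <- rbinom(n_somatic, ds, purity / 2)
    somatic <- variant_table(data.frame(
      sample_id = sample_id, chrom = basedf$chrom[pick], pos = pos,
      ref = ref, alt = alt_base, gene = NA_character_,
      consequence = "other", origin = "somatic", alt_reads = as_,
      ref_reads = ds - as_, stringsAsFactors = FALSE))
  }
  if (somatic_second_hit) {
    dh <- .rpois_min(1, depth_mean, depth_min)
    vh <- expected_vaf(1, max(gene_state[["total"]], 1), purity,
                       germline = FALSE)
    ah <- rbinom(1, dh, vh)
    hit <- variant_table(data.frame(
      sample_id = sample_id, chrom = "chr1", pos = gene_pos + 100,
      ref = "G", alt = "A", gene = gene, consequence = "stop_gain",
      origin = "somatic", alt_reads = ah, ref_reads = dh - ah,
      stringsAsFactors = FALSE))
    somatic <- if (is.null(somatic)) hit else rbind(somatic, hit)
  }

  purity_informative <- NULL
  if (n_informative > 0) {
    di <- .rpois_min(n_informative, depth_mean, depth_min)
    vi <- expected_vaf(1, 1, purity, germline = FALSE)  # p / (2 - p)
    ai <- rbinom(n_informative, di, vi)
    purity_informative <- variant_table(data.frame(
      sample_id = sample_id, chrom = "chr1",
      pos = seq(informative_loc[1] + 1e6, by = 1e6,
                length.out = n_informative),
      ref = "G", alt = "T", gene = "TP53", consequence = "missense",
      origin = "somatic", alt_reads = ai, ref_reads = di - ai,
      stringsAsFactors = FALSE))
  }

  list(sample = list(sample_id = sample_id, purity = purity,
                     profile = profile, arms = arms,
                     germline_variant = germline_variant,
                     somatic = somatic,
                     purity_informative = purity_informative,
                     methylation = methylation),
       truth = list(purity = purity, gene_fate = gene_fate,
                    scar_counts = scar_spec,
                    expected_vaf = ev_vaf,
                    m_v = gene_state[["m_v"]],
                    total_cn = gene_state[["total"]],
                    minor_cn = gene_state[["minor"]]))
}

#' Simulate an SBS96 catalogue from a known signature mixture
#'
#' Counts are drawn as Multinomial(`n_mutations`, M p) where M is the
#' signature matrix and p the true mixture proportions.
#'
#' @param signatures a [signature_set()].
#' @param proportions mixture proportions (must sum to 1).
#' @param n_mutations catalogue size.
#' @param seed optional RNG seed.
#' @return list with `catalog` (a [mutational_catalog()]) and `truth`
#'   (`exposures_true` = proportions).
#' @export
gen_catalog <- function(signatures, proportions, n_mutations, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(proportions) != length(signatures$names))
    stop("one proportion per signature required")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  prob <- as.vector(signatures$matrix %*% proportions)
  counts <- if (n_mutations > 0)
    as.vector(rmultinom(1, n_mutations, prob)) else numeric(96)
  cat <- mutational_catalog(setNames(counts, signatures$channels),
                            label = "simulated")
  list(catalog = cat,
       truth = list(exposures_true = setNames(proportions,
                                              signatures$names)))
}
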