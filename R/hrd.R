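#' @keywords internal
.sex_chroms <- c("chrX", "chrY", "X", "Y")

#' @keywords internal
.seg_len <- function(seg) seg$end - seg$start + 1

#' Smooth a segment profile for scar counting
#'
#' Iteratively merges the shortest segment below `min_len_bp` into its longer
#' adjacent neighbour on the same chromosome, the merged span adopting the
#' neighbour's copy-number state; afterwards, contiguous segments with
#' identical `(total_cn, minor_cn)` are coalesced. The operation is
#' idempotent; single-segment chromosomes pass through unchanged.
#'
#' @param profile a [segment_profile()].
#' @param min_len_bp minimum segment length retained without merging.
#' @return a smoothed [segment_profile()].
#' @export
smooth_segments <- function(profile, min_len_bp = 3e6) {
  seg <- profile$segments
  out <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    repeat {
      len <- .seg_len(s)
      small <- which(len < min_len_bp)
      if (!length(small) || nrow(s) == 1) break
      i <- small[which.min(len[small])]
      left <- if (i > 1) len[i - 1] else -Inf
      right <- if (i < nrow(s)) len[i + 1] else -Inf
      j <- if (left >= right) i - 1 else i + 1
      s$start[j] <- min(s$start[i], s$start[j])
      s$end[j] <- max(s$end[i], s$end[j])
      s <- s[-i, , drop = FALSE]
    }
    # coalesce contiguous runs of identical state
    if (nrow(s) > 1) {
      keep <- rep(TRUE, nrow(s))
      for (i in 2:nrow(s)) {
        prev <- max(which(keep[1:(i - 1)]))
        if (s$start[i] - s$end[prev] <= 1 &&
            s$total_cn[i] == s$total_cn[prev] &&
            s$minor_cn[i] == s$minor_cn[prev]) {
          s$end[prev] <- s$end[i]
          keep[i] <- FALSE
        }
      }
      s <- s[keep, , drop = FALSE]
    }
    out[[ch]] <- s
  }
  segment_profile(do.call(rbind, out), sample_id = profile$sample_id,
                  genome_build = profile$genome_build)
}

#' @keywords internal
.arm_row <- function(arms, ch) {
  i <- which(arms$chrom == ch)
  if (length(i) != 1) stop("no arm definition for chromosome ", ch)
  arms[i, , drop = FALSE]
}

#' @keywords internal
.autosomes <- function(seg, exclude_sex) {
  if (exclude_sex) seg[!(seg$chrom %in% .sex_chroms), , drop = FALSE] else seg
}

#' Count HRD-LOH events
#'
#' Counts segments with loss of heterozygosity (`minor_cn = 0`, at least one
#' copy retained) that are strictly longer than `min_len_bp` and do not span
#' the entire chromosome.
#'
#' @param profile a smoothed [segment_profile()].
#' @param arms chromosome-arm table (see [read_arms()]).
#' @param min_len_bp length threshold (strictly greater than; default 15 Mb).
#' @param exclude_sex drop sex chromosomes before counting.
#' @return integer count.
#' @export
count_hrd_loh <- function(profile, arms, min_len_bp = 15e6,
                          exclude_sex = TRUE) {
  seg <- .autosomes(profile$segments, exclude_sex)
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    if (seg$minor_cn[i] != 0 || seg$total_cn[i] < 1) next
    if (.seg_len(seg[i, ]) <= min_len_bp) next
    a <- .arm_row(arms, seg$chrom[i])
    whole <- seg$start[i] <= a$chrom_start && seg$end[i] >= a$chrom_end
    if (!whole) n <- n + 1L
  }
  n
}

#' Count telomeric allelic imbalances (TAI)
#'
#' Counts segments in allelic imbalance (`minor_cn != total_cn - minor_cn`)
#' whose span reaches a chromosome end within `telomere_tol_bp`, stays on one
#' arm (does not cross the centromere) and is at least `min_len_bp` long.
#'
#' @inheritParams count_hrd_loh
#' @param min_len_bp minimum length (inclusive; default 11 Mb).
#' @param telomere_tol_bp tolerance for "reaching" the chromosome end.
#' @return integer count.
#' @export
count_tai <- function(profile, arms, min_len_bp = 11e6,
                      telomere_tol_bp = 1e4, exclude_sex = TRUE) {
  seg <- .autosomes(profile$segments, exclude_sex)
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    if (seg$minor_cn[i] == seg$total_cn[i] - seg$minor_cn[i]) next
    if (.seg_len(seg[i, ]) < min_len_bp) next
    a <- .arm_row(arms, seg$chrom[i])
    at_p <- seg$start[i] - a$chrom_start <= telomere_tol_bp
    at_q <- a$chrom_end - seg$end[i] <= telomere_tol_bp
    if (!at_p && !at_q) next
    on_one_arm <- (at_p && seg$end[i] < a$cen_start) ||
      (at_q && seg$start[i] > a$cen_end)
    if (on_one_arm) n <- n + 1L
  }
  n
}

#' Count large-scale state transitions (LST)
#'
#' Per chromosome arm, counts breakpoints between consecutive segments in
#' different copy-number states where both flanking segments are at least
#' `min_seg_bp` long and the unprofiled gap between them is at most
#' `max_gap_bp`. Segments are assigned to arms by their midpoint. The profile
#' is expected to be smoothed at 3 Mb (see [smooth_segments()]).
#'
#' @inheritParams count_hrd_loh
#' @param min_seg_bp minimum flanking-segment length (default 10 Mb).
#' @param max_gap_bp maximum inter-segment gap (default 3 Mb).
#' @return integer count.
#' @export
count_lst <- function(profile, arms, min_seg_bp = 10e6, max_gap_bp = 3e6,
                      exclude_sex = TRUE) {
  seg <- .autosomes(profile$segments, exclude_sex)
  n <- 0L
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    a <- .arm_row(arms, ch)
    mid <- (s$start + s$end) / 2
    arm <- ifelse(mid < a$cen_start, "p",
                  ifelse(mid > a$cen_end, "q", "cen"))
    for (i in seq_len(nrow(s) - 1)) {
      if (arm[i] != arm[i + 1] || arm[i] == "cen") next
      gap <- s$start[i + 1] - s$end[i] - 1
      if (gap > max_gap_bp) next
      if (.seg_len(s[i, ]) < min_seg_bp || .seg_len(s[i + 1, ]) < min_seg_bp)
        next
      if (s$total_cn[i] != s$total_cn[i + 1] ||
          s$minor_cn[i] != s$minor_cn[i + 1]) n <- n + 1L
    }
  }
  n
}

#' Genomic-scar HRD score (LOH + TAI + LST)
#'
#' The unweighted sum of the three scar counts, with no ploidy adjustment; a
#' total of at least `threshold` (default 63) classifies the tumour as
#' HRD-high.
#'
#' @inheritParams count_hrd_loh
#' @param threshold positivity threshold on the total score.
#' @param smooth smooth the profile at `smooth_min_len_bp` before counting.
#' @param smooth_min_len_bp smoothing length (default 3 Mb).
#' @return object of class `hrd_result` with `loh_count`, `tai_count`,
#'   `lst_count`, `total`, `hrd_high`, `threshold_used`.
#' @export
hrd_score <- function(profile, arms, threshold = 63, smooth = TRUE,
                      smooth_min_len_bp = 3e6, exclude_sex = TRUE) {
  if (smooth && nrow(profile$segments))
    profile <- smooth_segments(profile, smooth_min_len_bp)
  loh <- count_hrd_loh(profile, arms, exclude_sex = exclude_sex)
  tai <- count_tai(profile, arms, exclude_sex = exclude_sex)
  lst <- count_lst(profile, arms, exclude_sex = exclude_sex)
  total <- loh + tai + lst
  structure(list(loh_count = loh, tai_count = tai, lst_count = lst,
                 total = total, hrd_high = total >= threshold,
                 threshold_used = threshold),
            class = "hrd_result")
}

#' @method print hrd_result
#' @export
print.hrd_result <- function(x, ...) {
  cat(sprintf("HRD score %d (LOH %d + TAI %d + LST %d): %s (threshold %d)\n",
              x$total, x$loh_count, x$tai_count, x$lst_count,
              if (x$hrd_high) "HRD-high" else "HRD-low", x$threshold_used))
  invisible(x)
}
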