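#' Construct an allele-specific copy-number segment profile
#'
#' A segment profile holds the allele-specific copy-number state of one tumour:
#' a `data.frame` of segments (`chrom`, `start`, `end` in 1-based inclusive bp,
#' integer `total_cn`, integer `minor_cn`, optional `baf`, `log2`) plus sample
#' metadata. Construction validates the profile: `start <= end`,
#' `minor_cn <= total_cn - minor_cn`, segments sorted by `(chrom, start)` and
#' non-overlapping within a chromosome.
#'
#' @param segments data.frame with at least `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`.
#' @param sample_id sample identifier.
#' @param genome_build free-text genome build tag.
#' @return object of class `segment_profile`.
#' @export
segment_profile <- function(segments, sample_id = "sample",
                            genome_build = "GRCh37") {
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segment table lacks required columns: ", paste(miss, collapse = ", "))
  for (col in c("baf", "log2"))
    if (!col %in% names(segments))
      segments[[col]] <- rep(NA_real_, nrow(segments))
  segments <- segments[, c(need, "baf", "log2")]
  segments$chrom <- as.character(segments$chrom)
  for (col in c("start", "end", "total_cn", "minor_cn"))
    segments[[col]] <- as.numeric(segments[[col]])
  if (any(segments$start > segments$end))
    stop("segment with start > end at row ",
         which(segments$start > segments$end)[1])
  if (any(segments$total_cn < 0 | segments$minor_cn < 0))
    stop("negative copy number")
  bad <- which(segments$minor_cn > segments$total_cn - segments$minor_cn)
  if (length(bad))
    stop("minor_cn exceeds total_cn - minor_cn at row ", bad[1],
         " (", segments$chrom[bad[1]], ":", segments$start[bad[1]], ")")
  if (any(!is.na(segments$baf) & (segments$baf < 0 | segments$baf > 0.5)))
    stop("baf outside [0, 0.5]")
  ord <- order(segments$chrom, segments$start)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1) {
    same <- segments$chrom[-1] == segments$chrom[-nrow(segments)]
    olap <- same & segments$start[-1] <= segments$end[-nrow(segments)]
    if (any(olap)) {
      i <- which(olap)[1]
      stop("overlapping segments on ", segments$chrom[i], ": [",
           segments$start[i], ", ", segments$end[i], "] and [",
           segments$start[i + 1], ", ", segments$end[i + 1], "]")
    }
  }
  structure(list(sample_id = sample_id, genome_build = genome_build,
                 segments = segments),
            class = "segment_profile")
}

#' @method print segment_profile
#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile:", x$sample_id, "(", x$genome_build, "),",
      nrow(x$segments), "segments\n")
  print(utils::head(x$segments, 10))
  invisible(x)
}

#' Read a SEG-like allele-specific copy-number table
#'
#' Expects a delimited file with a header naming at least
#' `chrom`/`start`/`end`/`total_cn`/`minor_cn` (optionally `baf`, `log2`,
#' `sample_id`). Internal coordinates are 1-based inclusive; inputs in 0-based
#' half-open convention declare it via `coords = "zero_half_open"` and are
#' converted on read (`start + 1`).
#'
#' @param path file path.
#' @param sample_id sample id; defaults to a `sample_id` column if present,
#'   else the file name.
#' @param genome_build build tag stored on the profile.
#' @param coords coordinate convention of the input file.
#' @param chr_style see [read_variants()].
#' @return a [segment_profile()].
#' @export
read_segments <- function(path, sample_id = NULL, genome_build = "GRCh37",
                          coords = c("one_based", "zero_half_open"),
                          chr_style = c("keep", "strip", "add")) {
  coords <- match.arg(coords)
  chr_style <- match.arg(chr_style)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(df) && nrow(df))
      df$sample_id[1] else tools::file_path_sans_ext(basename(path))
  }
  if (coords == "zero_half_open") df$start <- df$start + 1
  df$chrom <- .normalise_chrom(as.character(df$chrom), chr_style)
  segment_profile(df, sample_id = sample_id, genome_build = genome_build)
}

#' Write a segment profile as TSV (1-based inclusive coordinates)
#'
#' @param profile a [segment_profile()].
#' @param path output path.
#' @param coords coordinate convention to write.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profile, path,
                           coords = c("one_based", "zero_half_open")) {
  coords <- match.arg(coords)
  seg <- profile$segments
  if (coords == "zero_half_open") seg$start <- seg$start - 1
  seg <- cbind(sample_id = profile$sample_id, seg)
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a chromosome-arm definition table
#'
#' Tab-delimited with columns `chrom`, `chrom_start`, `cen_start`, `cen_end`,
#' `chrom_end` (1-based bp). Each row must satisfy
#' `chrom_start < cen_start < cen_end < chrom_end`.
#'
#' @param path file path.
#' @param chr_style see [read_variants()].
#' @return validated data.frame of arm definitions.
#' @export
read_arms <- function(path, chr_style = c("keep", "strip", "add")) {
  chr_style <- match.arg(chr_style)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$chrom <- .normalise_chrom(as.character(df$chrom), chr_style)
  validate_arms(df)
}

#' @rdname read_arms
#' @param arms data.frame of arm definitions to validate.
#' @export
validate_arms <- function(arms) {
  need <- c("chrom", "chrom_start", "cen_start", "cen_end", "chrom_end")
  miss <- setdiff(need, names(arms))
  if (length(miss))
    stop("arm table lacks required columns: ", paste(miss, collapse = ", "))
  ok <- arms$chrom_start < arms$cen_start & arms$cen_start < arms$cen_end &
    arms$cen_end < arms$chrom_end
  if (any(!ok))
    stop("invalid arm definition for ", arms$chrom[which(!ok)[1]],
         ": need chrom_start < cen_start < cen_end < chrom_end")
  if (anyDuplicated(arms$chrom))
    stop("duplicate chromosome in arm table: ",
         arms$chrom[duplicated(arms$chrom)][1])
  arms
}

#' Read a BED file of target intervals
#'
#' BED is 0-based half-open; intervals are converted to the package-internal
#' 1-based inclusive convention (`start + 1`, `end` unchanged).
#'
#' @param path BED file (first three columns used).
#' @param chr_style see [read_variants()].
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_targets <- function(path, chr_style = c("keep", "strip", "add")) {
  chr_style <- match.arg(chr_style)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = .normalise_chrom(as.character(df[[1]]), chr_style),
                    start = as.numeric(df[[2]]) + 1,
                    end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("empty or inverted BED interval")
  out
}
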