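#' @keywords internal
.consequence_levels <- c("stop_gain", "frameshift", "splice_essential",
                         "missense", "other")

#' @keywords internal
.variant_columns <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                      "origin", "alt_reads", "ref_reads", "vaf", "gnomad_af",
                      "cadd_phred", "revel", "filter_flags")

#' Construct and validate a variant table
#'
#' The central variant container is a plain `data.frame` with one row per
#' observed variant allele and the columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, `gene`, `consequence` (one of `r paste(.consequence_levels,
#' collapse = ", ")`), `origin` (`germline`/`somatic`), `alt_reads`,
#' `ref_reads`, `vaf`, `gnomad_af`, `cadd_phred`, `revel` and `filter_flags`.
#' Missing annotation columns are added as `NA`; extra columns (e.g.
#' `sample_id`, `n_alt_alleles`) are preserved after the canonical set;
#' `vaf` is (re)computed as
#' `alt_reads / (alt_reads + ref_reads)` wherever depth is positive, and rows
#' with zero depth get `vaf = NA` plus a `no_depth` flag.
#'
#' @param df data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return validated variant data.frame with the full column set.
#' @export
variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table lacks required columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(.variant_columns, names(df))) {
    df[[col]] <- rep(switch(col,
      gene = NA_character_, consequence = "other", origin = NA_character_,
      alt_reads = NA_integer_, ref_reads = NA_integer_,
      filter_flags = "", NA_real_), nrow(df))
  }
  extras <- setdiff(names(df), .variant_columns)
  df <- df[, c(.variant_columns, extras)]
  df$filter_flags <- as.character(df$filter_flags)
  df$filter_flags[is.na(df$filter_flags)] <- ""
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  bad <- which(!(df$consequence %in% .consequence_levels))
  if (length(bad))
    stop("unknown consequence class '", df$consequence[bad[1]],
         "' (row ", bad[1], "); legal values: ",
         paste(.consequence_levels, collapse = ", "))
  if (any(!is.na(df$gnomad_af) & (df$gnomad_af < 0 | df$gnomad_af > 1)))
    stop("gnomad_af outside [0, 1]")
  if (any(!is.na(df$alt_reads) & df$alt_reads < 0) ||
      any(!is.na(df$ref_reads) & df$ref_reads < 0))
    stop("negative read counts")
  depth <- df$alt_reads + df$ref_reads
  has_depth <- !is.na(depth) & depth > 0
  df$vaf[has_depth] <- df$alt_reads[has_depth] / depth[has_depth]
  no_depth <- !is.na(depth) & depth == 0
  df$vaf[no_depth] <- NA_real_
  df$filter_flags[no_depth] <- ifelse(
    df$filter_flags[no_depth] == "", "no_depth",
    paste(df$filter_flags[no_depth], "no_depth", sep = ";"))
  rownames(df) <- NULL
  df
}

#' Read a variant table from VCF or TSV
#'
#' The VCF dialect is a deliberately minimal read-only subset: `CHROM`, `POS`,
#' `REF`, `ALT`, the INFO keys `GENE`, `CSQ` (consequence class), `ORIGIN`,
#' `GNOMAD_AF`, `CADD`, `REVEL`, and a single sample with `AD` (and optionally
#' `DP`) FORMAT fields. Multi-allelic rows are split into biallelic records,
#' allele `i` taking `AD[1]` as reference reads and `AD[i + 1]` as alternate
#' reads. Unparseable gnomAD AF values become missing, never zero.
#'
#' @param path file path.
#' @param dialect `"tsv"` (tab-delimited with a header naming the variant-table
#'   columns) or `"vcf"`.
#' @param chr_style chromosome-name normalisation: `"keep"`, `"strip"` (drop a
#'   `chr` prefix) or `"add"`. Mixed naming within one file is an error.
#' @return a validated variant table (see [variant_table()]).
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf"),
                          chr_style = c("keep", "strip", "add")) {
  dialect <- match.arg(dialect)
  chr_style <- match.arg(chr_style)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (dialect == "tsv") .read_variants_tsv(path) else .read_variants_vcf(path)
  df$chrom <- .normalise_chrom(df$chrom, chr_style)
  variant_table(df)
}

.read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(df))
  if (length(miss))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$pos))
  if (any(is.na(pos) & !is.na(df$pos)))
    stop("parse error at line ",
         which(is.na(pos) & !is.na(df$pos))[1] + 1L, ": non-numeric pos")
  df$pos <- pos
  for (col in c("alt_reads", "ref_reads", "gnomad_af", "cadd_phred", "revel")) {
    if (col %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      df[[col]] <- v  # unparseable values become missing, not zero
    }
  }
  df
}

.read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  }
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("VCF lacks a sample column with depth fields; required FORMAT fields: AD")
  fmt <- strsplit(gt[, 1], ":")
  smp <- strsplit(gt[, 2], ":")
  get_field <- function(i, key) {
    j <- match(key, fmt[[i]])
    if (is.na(j) || j > length(smp[[i]])) NA_character_ else smp[[i]][j]
  }
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ad_raw <- get_field(i, "AD")
    if (is.na(ad_raw))
      stop("VCF record at line-of-body ", i,
           " lacks depth fields; required FORMAT fields: AD")
    ad <- suppressWarnings(as.integer(strsplit(ad_raw, ",", fixed = TRUE)[[1]]))
    if (length(ad) < length(alts) + 1L || anyNA(ad))
      stop("malformed AD field in VCF body record ", i, ": ", ad_raw)
    info <- fix[i, "INFO"]
    af <- suppressWarnings(as.numeric(info_get(info, "GNOMAD_AF")))
    csq <- info_get(info, "CSQ")
    out[[i]] <- data.frame(
      chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"], alt = alts,
      gene = info_get(info, "GENE"),
      consequence = if (is.na(csq)) "other" else csq,
      origin = info_get(info, "ORIGIN"),
      alt_reads = ad[seq_along(alts) + 1L], ref_reads = ad[1L],
      gnomad_af = af,
      cadd_phred = suppressWarnings(as.numeric(info_get(info, "CADD"))),
      revel = suppressWarnings(as.numeric(info_get(info, "REVEL"))),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

.normalise_chrom <- function(chrom, chr_style) {
  if (length(chrom)) {
    has <- grepl("^chr", chrom)
    if (any(has) && !all(has))
      stop("mixed chromosome naming ('chr' prefix) within one file")
  }
  switch(chr_style,
         keep = chrom,
         strip = sub("^chr", "", chrom),
         add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)))
}

#' Write a variant table as TSV
#'
#' @param x variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
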