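#' SBS96 channel names in COSMIC lexicographic order
#'
#' The 96 single-base-substitution channels `X[R>A]Y` on the pyrimidine strand
#' (reference base C or T), sorted lexicographically as in COSMIC signature
#' matrices.
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  ch <- as.vector(outer(
    bases, as.vector(outer(subs, bases,
                           function(s, b3) paste0("[", s, "]", b3))),
    paste0))
  sort(ch, method = "radix")
}

#' Construct a signature set
#'
#' A signature set is a 96 x k non-negative matrix of channel probabilities,
#' one column per signature, rows in COSMIC SBS96 channel order. Columns are
#' renormalised to sum to 1.
#'
#' @param mat numeric matrix, 96 rows (channels) x k columns (signatures).
#'   Rownames, if present, must be SBS96 channel names and are used to reorder
#'   rows into canonical order.
#' @param names signature names; defaults to `colnames(mat)`.
#' @return object of class `signature_set` with elements `names`, `matrix`,
#'   `channels`.
#' @export
signature_set <- function(mat, names = colnames(mat)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 96)
    stop("expected 96 channels, got ", nrow(mat))
  if (any(mat < 0)) stop("negative entries in signature matrix")
  channels <- sbs96_channels()
  if (!is.null(rownames(mat))) {
    idx <- match(channels, rownames(mat))
    if (anyNA(idx))
      stop("unrecognised channel names; first missing: ",
           channels[which(is.na(idx))[1]])
    mat <- mat[idx, , drop = FALSE]
  }
  rownames(mat) <- channels
  if (is.null(names)) names <- paste0("sig", seq_len(ncol(mat)))
  colsum <- colSums(mat)
  if (any(colsum <= 0)) stop("signature column sums to zero")
  mat <- sweep(mat, 2, colsum, "/")
  colnames(mat) <- names
  structure(list(names = names, matrix = mat, channels = channels),
            class = "signature_set")
}

#' Read a COSMIC-style signature matrix
#'
#' Tab-delimited, first column the SBS96 channel label, remaining columns one
#' signature each. With `transpose = TRUE` the file carries signatures in rows
#' and channels in columns.
#'
#' @param path file path.
#' @param transpose logical; transpose the matrix after reading.
#' @return a [signature_set()].
#' @export
read_signature_set <- function(path, transpose = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rn <- as.character(df[[1]])
  if (transpose) {
    mat <- t(mat)
    rownames(mat) <- colnames(df)[-1]
    colnames(mat) <- rn
  } else {
    rownames(mat) <- rn
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric entries in signature matrix")
  signature_set(mat)
}

#' Read promoter-methylation calls
#'
#' Tab-delimited with columns `sample_id`, `gene`, `status` (one of
#' `unmethylated`, `heterozygous_methylated`, `homozygous_methylated`,
#' `unknown`) and optional `methylated_allele` (`wildtype`, `variant`,
#' `unknown`). The methylated allele may only be named when the status implies
#' a single methylated allele (heterozygous methylation).
#'
#' @param path file path.
#' @return data.frame of validated methylation calls.
#' @export
read_methylation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("methylation table lacks required columns: ",
         paste(miss, collapse = ", "))
  if (!"methylated_allele" %in% names(df)) df$methylated_allele <- "unknown"
  for (i in seq_len(nrow(df)))
    methylation_call(df$sample_id[i], df$gene[i], df$status[i],
                     df$methylated_allele[i])
  df
}

#' Construct a single promoter-methylation call
#'
#' @param sample_id sample identifier.
#' @param gene gene symbol.
#' @param status methylation status.
#' @param methylated_allele which allele carries the methylation, when a
#'   single allele is methylated.
#' @return named list of class `methylation_call`.
#' @export
methylation_call <- function(sample_id, gene,
                             status = c("unmethylated",
                                        "heterozygous_methylated",
                                        "homozygous_methylated", "unknown"),
                             methylated_allele = c("unknown", "wildtype",
                                                   "variant")) {
  status <- match.arg(status)
  methylated_allele <- match.arg(methylated_allele)
  if (status != "heterozygous_methylated" && methylated_allele != "unknown")
    stop("methylated_allele can only be named for heterozygous methylation")
  structure(list(sample_id = sample_id, gene = gene, status = status,
                 methylated_allele = methylated_allele),
            class = "methylation_call")
}
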