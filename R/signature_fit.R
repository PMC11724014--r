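#' Construct an SBS96 mutational catalogue
#'
#' @param counts numeric vector of 96 non-negative counts, optionally named by
#'   channel; unnamed vectors are assumed to be in canonical channel order.
#' @param label catalogue label.
#' @return object of class `mutational_catalog` with `counts` (named, in
#'   COSMIC order), `total`, `label`.
#' @export
mutational_catalog <- function(counts, label = "catalog") {
  channels <- sbs96_channels()
  if (length(counts) != 96) stop("expected 96 channels, got ", length(counts))
  if (any(counts < 0)) stop("negative channel counts")
  if (!is.null(names(counts))) {
    idx <- match(channels, names(counts))
    if (anyNA(idx)) stop("unrecognised channel names in catalogue")
    counts <- counts[idx]
  }
  counts <- setNames(as.numeric(counts), channels)
  structure(list(counts = counts, total = sum(counts), label = label),
            class = "mutational_catalog")
}

#' @method print mutational_catalog
#' @export
print.mutational_catalog <- function(x, ...) {
  cat("mutational_catalog:", x$label, "-", x$total, "substitutions\n")
  invisible(x)
}

#' Build an SBS96 catalogue from single-base substitutions and a reference
#'
#' Each substitution is mapped to one of the 96 trinucleotide channels using
#' the pyrimidine-strand convention: when the reference base is a purine the
#' trinucleotide context and the alternate base are reverse-complemented.
#'
#' @param variants variant table of single-nucleotide substitutions.
#' @param reference genome sequence: a [Biostrings::DNAStringSet] named by
#'   chromosome, a named character vector of sequences, or a FASTA file path.
#' @param label catalogue label.
#' @return a [mutational_catalog()]; the total equals the number of input
#'   substitutions.
#' @export
build_catalog <- function(variants, reference, label = "catalog") {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  channels <- sbs96_channels()
  counts <- setNames(numeric(96), channels)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(variants))) {
    ch <- variants$chrom[i]; pos <- variants$pos[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (nchar(ref) != 1 || nchar(alt) != 1)
      stop("not a single-base substitution: ", ch, ":", pos, " ", ref, ">", alt)
    j <- match(ch, names(reference))
    if (is.na(j)) stop("chromosome ", ch, " absent from reference")
    if (pos < 2 || pos > Biostrings::width(reference)[j] - 1)
      stop("position at contig edge: ", ch, ":", pos)
    tri <- as.character(Biostrings::subseq(reference[[j]], pos - 1, pos + 1))
    if (substr(tri, 2, 2) != ref)
      stop("reference mismatch at ", ch, ":", pos, ": expected ", ref,
           ", reference has ", substr(tri, 2, 2))
    if (ref %in% c("A", "G")) {
      tri <- paste(rev(comp[strsplit(tri, "")[[1]]]), collapse = "")
      ref <- comp[[ref]]; alt <- comp[[alt]]
    }
    key <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                  substr(tri, 3, 3))
    counts[key] <- counts[key] + 1
  }
  mutational_catalog(counts, label = label)
}

#' Non-negative least-squares signature exposures
#'
#' Solves \eqn{\min_{e \ge 0} \| c - M e \|_2} where `c` is the catalogue and
#' `M` the channels-by-signatures matrix. Deterministic.
#'
#' @param catalog a [mutational_catalog()].
#' @param signatures a [signature_set()] with matching channel order.
#' @return named numeric vector of exposures (mutation units).
#' @export
fit_exposures <- function(catalog, signatures) {
  if (!identical(names(catalog$counts), signatures$channels))
    stop("catalogue and signature set channel order mismatch")
  e <- pracma::lsqnonneg(signatures$matrix, catalog$counts)$x
  setNames(e, signatures$names)
}

#' Signature refitting with a bootstrap sparsity filter
#'
#' `B` bootstrap catalogues are drawn multinomially (size = catalogue total,
#' probabilities proportional to the observed channel counts) and refit by
#' non-negative least squares. A signature is *called* if the fraction of
#' bootstrap replicates in which its exposure proportion falls at or below
#' `threshold` is smaller than `alpha`; signatures failing the filter are
#' removed and the point fit is recomputed on the called subset.
#'
#' @param catalog a [mutational_catalog()] with positive total.
#' @param signatures a [signature_set()].
#' @param B number of bootstrap replicates.
#' @param threshold sparsity threshold on the exposure proportion.
#' @param alpha tolerated fraction of below-threshold replicates.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `signature_fit` with `exposures` (called subset
#'   refit; uncalled signatures at 0), `proportions`, `called`,
#'   `bootstrap_summary` (per-signature median and 95% interval of the
#'   bootstrap proportions), and `config`.
#' @export
fit_with_sparsity <- function(catalog, signatures, B = 1000,
                              threshold = 0.01, alpha = 0.05, seed = NULL) {
  if (catalog$total <= 0) stop("catalogue total must be positive")
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k <- length(signatures$names)
  prob <- catalog$counts / catalog$total
  boot <- rmultinom(B, size = catalog$total, prob = prob)
  props <- matrix(0, nrow = k, ncol = B,
                  dimnames = list(signatures$names, NULL))
  for (b in seq_len(B)) {
    e <- pracma::lsqnonneg(signatures$matrix, boot[, b])$x
    s <- sum(e)
    if (s > 0) props[, b] <- e / s
  }
  frac_below <- rowMeans(props <= threshold)
  called <- signatures$names[frac_below < alpha]
  exposures <- setNames(numeric(k), signatures$names)
  if (length(called)) {
    sub <- signature_set(
      signatures$matrix[, called, drop = FALSE], names = called)
    exposures[called] <- fit_exposures(catalog, sub)
  }
  tot <- sum(exposures)
  proportions <- if (tot > 0) exposures / tot else exposures
  bootstrap_summary <- data.frame(
    signature = signatures$names,
    median = apply(props, 1, median),
    lower95 = apply(props, 1, quantile, probs = 0.025),
    upper95 = apply(props, 1, quantile, probs = 0.975),
    frac_below_threshold = frac_below,
    called = signatures$names %in% called,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(exposures = exposures, proportions = proportions,
                 called = called, bootstrap_summary = bootstrap_summary,
                 config = list(B = B, sparsity_threshold = threshold,
                               alpha = alpha, seed = seed)),
            class = "signature_fit")
}

#' @method print signature_fit
#' @export
print.signature_fit <- function(x, ...) {
  cat("signature_fit:", length(x$called), "of",
      length(x$exposures), "signatures called\n")
  print(x$bootstrap_summary)
  invisible(x)
}
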