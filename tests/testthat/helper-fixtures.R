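# Shared fixtures, all built in code at test time.

# Block-structured synthetic signatures: k signatures concentrated on
# disjoint channel blocks, so mixtures are well identified.
make_block_signatures <- function(k = 3, seed = 42) {
  set.seed(seed)
  m <- matrix(0, 96, k)
  block <- cut(seq_len(96), k, labels = FALSE)
  for (j in seq_len(k)) m[block == j, j] <- runif(sum(block == j), 0.5, 1)
  signature_set(m, names = paste0("SIG", seq_len(k)))
}

# One-row germline observation for classifier tests.
make_obs <- function(alt, ref, gene = "GENE1", sample_id = "S1") {
  variant_table(data.frame(
    sample_id = sample_id, chrom = "chr1", pos = 55e6, ref = "C", alt = "T",
    gene = gene, consequence = "stop_gain", origin = "germline",
    alt_reads = alt, ref_reads = ref, stringsAsFactors = FALSE))
}

make_segment <- function(total_cn, minor_cn, chrom = "chr1",
                         start = 50e6 + 1, end = 60e6) {
  data.frame(chrom = chrom, start = start, end = end,
             total_cn = total_cn, minor_cn = minor_cn,
             baf = NA_real_, log2 = NA_real_, stringsAsFactors = FALSE)
}

# Independent exact-tail oracle: binomial-coefficient enumeration of all 2x2
# tables with the margins fixed (never calls phyper).
hyper_tail_oracle <- function(a_case, n_case, a_ctrl, n_ctrl) {
  K <- a_case + a_ctrl
  N <- n_case + n_ctrl
  xs <- max(0, K - n_ctrl):min(K, n_case)
  probs <- choose(K, xs) * choose(N - K, n_case - xs) / choose(N, n_case)
  sum(probs[xs >= a_case])
}

# Small mini-genome single-tumour VCF written to a temp file.
write_test_vcf <- function(path, body_lines) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"gnomAD AF\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"))
  writeLines(c(header, body_lines), path)
  path
}
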