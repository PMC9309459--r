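# Shared fixture builders (everything generated in code at test time).

# Tiny genotype matrix with explicit dosages; rows SNPs, cols samples.
toy_gm <- function(geno, pos = NULL, chrom = NULL, ref = NULL, alt = NULL,
                   contigs = NULL) {
  m <- nrow(geno)
  toy <- genotype_matrix(
    chrom %||% rep("chr1", m),
    pos %||% seq(100L, by = 100L, length.out = m),
    ref %||% rep("A", m), alt %||% rep("G", m),
    geno, contigs = contigs)
  toy
}
`%||%` <- function(a, b) if (is.null(a)) b else a

two_pop_map <- function(nA, nB, gm = NULL) {
  ids <- if (!is.null(gm)) samples(gm) else
    c(sprintf("a%02d", seq_len(nA)), sprintf("b%02d", seq_len(nB)))
  stats::setNames(c(rep("A", nA), rep("B", nB)), ids)
}

# Write a small VCF with given body records (header for `samples`).
write_test_vcf <- function(path, body, samples = c("s1", "s2"),
                           contigs = c(chr1 = 100000L)) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

# A neutral two-population simulation shared by several tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_neutral(sim_params(
        n_pops = 2, n_per_pop = 50, seq_len = 1e6, drift_var = 0.2,
        snp_density = 1e-3, seed = 42))
    cache
  }
})
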