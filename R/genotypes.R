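#' Genotype matrix container
#'
#' Container for biallelic SNP genotypes: per-SNP chromosome, 1-based
#' position, ref/alt alleles, and a SNP x sample matrix of alt-allele
#' dosages (0, 1, 2 or \code{NA} for missing). Positions are strictly
#' increasing within a chromosome.
#'
#' @param chrom character vector of chromosome ids, one per SNP.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base ref and alt alleles.
#' @param geno integer matrix (SNP x sample) of alt dosages in
#'   \code{c(0, 1, 2, NA)}; column names are sample ids.
#' @param contigs optional named vector of chromosome lengths (bp). When
#'   missing, lengths default to the largest observed position per
#'   chromosome.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, contigs = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, nrow(geno) == n,
            length(ref) == n, length(alt) == n)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%03d", seq_len(ncol(geno)))
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stopf("genotype dosages must be 0, 1, 2 or NA")
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- as.integer(pos[ord])
  ref <- ref[ord]; alt <- alt[ord]
  geno <- geno[ord, , drop = FALSE]
  if (anyDuplicated(paste(chrom, pos)))
    stopf("duplicated chrom/pos records in genotype matrix")
  if (is.null(contigs)) {
    contigs <- tapply(pos, chrom, max)
    contigs <- stats::setNames(as.numeric(contigs), names(contigs))
  }
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 geno = geno, contigs = contigs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d samples on %d chromosome(s)\n",
              n_snps(x), n_samples(x), length(unique(x$chrom))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a \code{genotype_matrix}.
#' @export
n_snps <- function(gm) length(gm$pos)

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) ncol(gm$geno)

#' @rdname genotype_matrix
#' @export
samples <- function(gm) colnames(gm$geno)

# subset SNPs (logical or integer index), preserving metadata
subset_snps <- function(gm, idx) {
  structure(list(chrom = gm$chrom[idx], pos = gm$pos[idx],
                 ref = gm$ref[idx], alt = gm$alt[idx],
                 geno = gm$geno[idx, , drop = FALSE],
                 contigs = gm$contigs),
            class = "genotype_matrix")
}

#' Sample ids belonging to one or more subpopulations
#'
#' @param popmap named character vector mapping sample id to subpopulation
#'   label, as returned by [read_population_map()].
#' @param pops one or more subpopulation labels; their sample sets are
#'   pooled.
#' @return character vector of sample ids.
#' @export
pop_samples <- function(popmap, pops) {
  unknown <- setdiff(pops, unique(popmap))
  if (length(unknown))
    stopf("unknown subpopulation label(s): %s", paste(unknown, collapse = ", "))
  names(popmap)[popmap %in% pops]
}

#' Per-SNP alternate allele frequencies within a sample set
#'
#' Frequency is the alt-dosage sum over twice the number of non-missing
#' individuals; SNPs with no non-missing call get \code{NA} (flagged
#' undefined, never 0).
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of sample ids, or a subpopulation label
#'   resolved through `popmap`.
#' @param popmap optional population map (required when `samples` is a
#'   label).
#' @return data.frame with columns \code{p} (alt frequency) and \code{n}
#'   (non-missing allele count, 2 x individuals).
#' @export
allele_frequencies <- function(gm, samples, popmap = NULL) {
  if (!is.null(popmap) && all(samples %in% popmap))
    samples <- pop_samples(popmap, samples)
  miss <- setdiff(samples, colnames(gm$geno))
  if (length(miss))
    stopf("sample(s) not in genotype matrix: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  g <- gm$geno[, samples, drop = FALSE]
  nonmiss <- rowSums(!is.na(g))
  n <- 2L * nonmiss
  p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
  data.frame(p = p, n = n)
}
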