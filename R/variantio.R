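# Variant and interval I/O plus SNP-level filtering.

.gt_dosage_map <- local({
  m <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  m
})

# Map VCF GT strings to alt dosages; phased separators normalized, any
# genotype containing "." (incl. half-calls) -> NA.
gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  d <- unname(.gt_dosage_map[gt])
  d[is.na(d) & !grepl(".", gt, fixed = TRUE) & gt != ""] <- NA_integer_
  d
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Only biallelic SNP records are retained; indels and multi-allelic
#' records are skipped and their counts reported in the
#' \code{"skip_report"} attribute. Genotypes become alt dosages; half
#' calls and \code{./.} become missing.
#'
#' @param path path to an (uncompressed) VCF 4.x file.
#' @param region optional \code{"chrom"} or \code{"chrom:from-to"}
#'   (1-based, inclusive) restriction.
#' @return a [genotype_matrix()] with a \code{skip_report} attribute
#'   (counts of skipped indel / multi-allelic records).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stopf("%s: no #CHROM header line", path)
  hdr <- hdr[1]
  head_fields <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)[[1]]
  if (length(head_fields) < 10L)
    stopf("%s: VCF has no sample columns", path)
  samp <- head_fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body)) stopf("%s: VCF contains no records", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(head_fields))
  if (length(bad))
    stopf("%s: malformed record at line %d (%d fields, expected %d)",
          path, hdr + bad[1], nf[bad[1]], length(head_fields))
  rec <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  chrom <- rec[, 1]; pos <- suppressWarnings(as.integer(rec[, 2]))
  if (anyNA(pos))
    stopf("%s: non-numeric POS at line %d", path, hdr + which(is.na(pos))[1])
  ref <- rec[, 4]; alt <- rec[, 5]
  is_snp <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  alt1 <- !multi & nchar(alt) == 1L & alt %in% c("A", "C", "G", "T")
  keep <- is_snp & alt1
  skip_report <- list(n_records = nrow(rec),
                      n_multiallelic = sum(multi),
                      n_indel_or_other = sum(!keep & !multi),
                      n_kept = sum(keep))
  if (!is.null(region)) {
    m <- regmatches(region,
      regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(m)) stopf("bad region spec: %s", region)
    keep <- keep & chrom == m[2]
    if (nzchar(m[3]))
      keep <- keep & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  if (!any(keep)) stopf("%s: no biallelic SNP records retained", path)
  idx <- which(keep)
  gt <- rec[idx, -(1:9), drop = FALSE]
  geno <- matrix(gt_to_dosage(gt), nrow = length(idx),
                 dimnames = list(NULL, samp))
  contigs <- .parse_contig_lengths(lines[seq_len(hdr - 1L)])
  gm <- genotype_matrix(chrom[idx], pos[idx], ref[idx], alt[idx], geno,
                        contigs = contigs)
  attr(gm, "skip_report") <- skip_report
  gm
}

.parse_contig_lengths <- function(meta) {
  m <- grep("^##contig=", meta, value = TRUE)
  if (!length(m)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", m)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", m)))
  if (anyNA(len)) return(NULL)
  stats::setNames(len, id)
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param ann optional character vector (one per SNP) of SnpEff-style ANN
#'   INFO values; \code{NA} entries get \code{INFO = "."}.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, ann = NULL) {
  n <- n_snps(gm)
  if (!is.null(ann)) stopifnot(length(ann) == n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(gm$contigs),
                       as.integer(gm$contigs)),
               paste0("##INFO=<ID=ANN,Number=.,Type=String,",
                      "Description=\"Functional annotations\">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples(gm)), collapse = "\t")), con)
  gtc <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n, n_samples(gm))
  ok <- !is.na(gm$geno)
  gt[ok] <- gtc[gm$geno[ok] + 1L]
  info <- if (is.null(ann)) rep(".", n) else
    ifelse(is.na(ann), ".", paste0("ANN=", ann))
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", info,
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a sample-to-subpopulation map
#'
#' Two-column headerless TSV: sample id, subpopulation label.
#'
#' @param path TSV path.
#' @return named character vector (names = sample ids, values = labels).
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stopf("population map not found: %s", path)
  d <- data.table::fread(path, header = FALSE, sep = "\t",
                         colClasses = "character", data.table = FALSE)
  if (ncol(d) < 2L) stopf("%s: expected two tab-separated columns", path)
  if (any(!nzchar(d[[2]]))) stopf("%s: empty subpopulation label", path)
  stats::setNames(d[[2]], d[[1]])
}

#' Read genomic intervals (BED, GFF3 or BED-like TSV)
#'
#' All formats are converted to the package-internal 0-based half-open
#' convention: BED passes through, GFF3 1-based closed coordinates become
#' \code{(start - 1, end)}. TSV expects a header with at least
#' \code{chrom}, \code{start}, \code{end} (already 0-based half-open) and
#' keeps any extra columns (e.g. \code{trait_id}, \code{source},
#' \code{candidate_genes} for QTL tables).
#'
#' @param path input path.
#' @param fmt one of \code{"BED"}, \code{"GFF3"}, \code{"TSV"}.
#' @param feature for GFF3, restrict to this feature type (default
#'   \code{"gene"}; \code{NULL} keeps all).
#' @return data.frame with chrom, start, end, name (+ extra columns).
#' @export
read_intervals <- function(path, fmt = c("BED", "GFF3", "TSV"),
                           feature = "gene") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stopf("interval file not found: %s", path)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character())
  if (fmt == "BED") {
    if (!length(readLines(path, n = 1L))) return(empty)
    d <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE)
    out <- data.frame(chrom = as.character(d[[1]]), start = as.numeric(d[[2]]),
                      end = as.numeric(d[[3]]),
                      name = if (ncol(d) >= 4) as.character(d[[4]]) else
                        sprintf("iv%d", seq_len(nrow(d))))
    if (ncol(d) >= 5) out$score <- d[[5]]
  } else if (fmt == "GFF3") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) return(empty)
    d <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                           data.table = FALSE)
    if (!is.null(feature)) d <- d[d[[3]] %in% feature, , drop = FALSE]
    id <- sub(".*ID=([^;]+).*", "\\1", d[[9]])
    out <- data.frame(chrom = as.character(d[[1]]),
                      start = as.numeric(d[[4]]) - 1,
                      end = as.numeric(d[[5]]), name = id)
  } else {
    d <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(d)))
      stopf("%s: TSV needs columns %s", path, paste(need, collapse = ", "))
    out <- d
    out$chrom <- as.character(out$chrom)
    if (!"name" %in% names(out))
      out$name <- sprintf("iv%d", seq_len(nrow(out)))
  }
  if (any(out$start >= out$end)) stopf("%s: interval with start >= end", path)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Parse SnpEff-style ANN annotations from a VCF
#'
#' Splits each record's \code{ANN=} INFO entry on \code{","} (multiple
#' annotations) then \code{"|"}; impact is at the standard third field,
#' gene id at the fifth (falling back to the gene-name field when empty).
#'
#' @param path VCF path.
#' @return data.frame of effect records: chrom, pos, ref, alt, gene_id,
#'   impact (HIGH/MODERATE/LOW/MODIFIER), consequence.
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    info <- f[8]
    m <- regmatches(info, regexec("(?:^|;)ANN=([^;]+)", info))[[1]]
    if (length(m) < 2L) next
    for (a in strsplit(m[2], ",", fixed = TRUE)[[1]]) {
      p <- strsplit(a, "|", fixed = TRUE)[[1]]
      if (length(p) < 3L) next
      gene <- if (length(p) >= 5L && nzchar(p[5])) p[5] else
        if (length(p) >= 4L) p[4] else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
        gene_id = gene, impact = p[3], consequence = p[2])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene_id = character(), impact = character(),
                      consequence = character()))
  res <- do.call(rbind, out)
  vocab <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  bad <- setdiff(unique(res$impact), vocab)
  if (length(bad)) warnf("non-standard impact value(s): %s",
                         paste(bad, collapse = ", "))
  res
}

#' SNP-level filter parameters
#'
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param het_max maximum per-SNP heterozygous-call fraction among
#'   non-missing calls (default 0.591, the study's empirical
#'   heterozygosity cutoff; site-specific, so exposed as a parameter).
#' @param max_missing maximum fraction of missing calls (default 0.5).
#' @return list of class \code{filter_params}.
#' @export
filter_params <- function(maf_min = 0.05, het_max = 0.591, max_missing = 0.5) {
  stopifnot(maf_min >= 0, maf_min <= 1, het_max >= 0, het_max <= 1,
            max_missing >= 0, max_missing <= 1)
  structure(list(maf_min = maf_min, het_max = het_max,
                 max_missing = max_missing), class = "filter_params")
}

#' Apply per-SNP filters (MAF, heterozygosity, missingness)
#'
#' Drops SNPs with minor allele frequency below \code{maf_min} (computed
#' over non-missing calls of all samples in `gm`), heterozygous-call
#' fraction above \code{het_max}, or missingness above
#' \code{max_missing}. SNP order is preserved and a per-rule report is
#' attached as attribute \code{"filter_report"} (a SNP failing several
#' rules is counted under each).
#'
#' @param gm a [genotype_matrix()].
#' @param fp a [filter_params()] object.
#' @return filtered genotype_matrix with a \code{filter_report} attribute.
#' @export
apply_filters <- function(gm, fp = filter_params()) {
  g <- gm$geno
  nonmiss <- rowSums(!is.na(g))
  p <- ifelse(nonmiss > 0, rowSums(g, na.rm = TRUE) / (2 * nonmiss), NA_real_)
  maf <- pmin(p, 1 - p)
  het <- ifelse(nonmiss > 0,
                rowSums(g == 1L, na.rm = TRUE) / nonmiss, NA_real_)
  fmiss <- 1 - nonmiss / ncol(g)
  fail_maf <- is.na(maf) | maf < fp$maf_min
  fail_het <- !is.na(het) & het > fp$het_max
  fail_mis <- fmiss > fp$max_missing
  keep <- !(fail_maf | fail_het | fail_mis)
  out <- subset_snps(gm, keep)
  attr(out, "filter_report") <- list(
    n_input = n_snps(gm), n_fail_maf = sum(fail_maf),
    n_fail_het = sum(fail_het), n_fail_missing = sum(fail_mis),
    n_kept = sum(keep))
  if (!any(keep)) warnf("all SNPs removed by filters")
  out
}
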