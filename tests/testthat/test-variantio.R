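# VCF / interval / map readers and the SNP-level filters.

test_that("read_vcf keeps only biallelic SNPs and maps dosages", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.",
    "chr1\t200\t.\tA\tAT\t.\tPASS\t.\tGT\t0/0\t1/1",   # indel
    "chr1\t300\t.\tC\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2",  # triallelic
    "chr1\t400\t.\tG\tC\t.\tPASS\t.\tGT\t1|1\t0/."))
  gm <- read_vcf(f)
  expect_equal(n_snps(gm), 2L)
  rep <- attr(gm, "skip_report")
  expect_equal(rep$n_multiallelic, 1L)
  expect_equal(rep$n_indel_or_other, 1L)
  # dosage encoding: 0/1 -> 1, ./. -> NA, 1|1 -> 2, half call -> NA
  expect_equal(unname(gm$geno[1, ]), c(1L, NA_integer_))
  expect_equal(unname(gm$geno[2, ]), c(2L, NA_integer_))
  expect_equal(unname(gm$contigs["chr1"]), 100000)
})

test_that("malformed records raise a format error naming the line", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, c("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"))
  expect_error(read_vcf(f), "line 6")
})

test_that("a 1000-SNP VCF round-trips to an identical matrix", {
  s <- simulate_neutral(sim_params(n_pops = 2, n_per_pop = 10,
                                   seq_len = 1e6, snp_density = 1e-3,
                                   seed = 11))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(s$gm, f1)
  gm1 <- read_vcf(f1)
  write_vcf(gm1, f2)
  gm2 <- read_vcf(f2)
  for (fld in c("chrom", "pos", "ref", "alt", "geno"))
    expect_identical(gm1[[fld]], gm2[[fld]])
  expect_identical(gm1$geno, s$gm$geno)
})

test_that("reader agrees with VariantAnnotation on a fixture", {
  # independent route: Bioconductor's reference VCF parser
  s <- simulate_neutral(sim_params(n_pops = 2, n_per_pop = 5,
                                   seq_len = 5e4, snp_density = 1e-3,
                                   seed = 12))
  f <- tempfile(fileext = ".vcf")
  write_vcf(s$gm, f)
  gm <- read_vcf(f)
  va <- suppressWarnings(VariantAnnotation::readVcf(f, genome = "toy"))
  gt <- VariantAnnotation::geno(va)$GT
  map <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  expect_equal(unname(gm$geno),
               matrix(unname(map[gt]), nrow = nrow(gt)))
  expect_equal(gm$pos, unname(BiocGenerics::start(va)))
})

test_that("population map and interval readers honor conventions", {
  pm_f <- tempfile(); writeLines(c("s1\tI1", "s2\tJ4"), pm_f)
  pm <- read_population_map(pm_f)
  expect_identical(pm, c(s1 = "I1", s2 = "J4"))
  expect_identical(pop_samples(pm, c("I1", "J4")), c("s1", "s2"))
  expect_error(pop_samples(pm, "I9"), "unknown")

  # GFF3 1-based closed 101..200 -> internal (100, 200)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1"), gff)
  iv <- read_intervals(gff, "GFF3")
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 200)
  expect_equal(iv$name, "g1")

  # BED passes through; empty BED is fine
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tg1", bed)
  expect_equal(read_intervals(bed, "BED")$start, 100)
  writeLines(character(0), bed)
  expect_equal(nrow(read_intervals(bed, "BED")), 0L)
})

test_that("coordinate conventions round-trip BED and GFF3", {
  gff <- tempfile(fileext = ".gff3")
  set.seed(13)
  st <- sort(sample.int(1e5, 20)); en <- st + sample(50:500, 20, TRUE)
  writeLines(c("##gff-version 3",
               sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=g%d",
                       st, en, 1:20)), gff)
  iv <- read_intervals(gff, "GFF3")
  # write back as GFF3 (internal 0-based half-open -> 1-based closed)
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       iv$start + 1L, iv$end, iv$name)), gff2)
  expect_equal(read_intervals(gff2, "GFF3"), iv)
})

test_that("SnpEff-style ANN entries parse into effect records", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, paste0(
    "chr10\t19086000\t.\tC\tT\t.\tPASS\t",
    "ANN=T|stop_gained|HIGH|LOC_Os10g35604|LOC_Os10g35604|transcript|x|c|p,",
    "T|upstream_gene_variant|MODIFIER|g2|g2|transcript|x|c|p\tGT\t0/1\t1/1"))
  eff <- read_effects(f)
  expect_equal(nrow(eff), 2L)
  expect_equal(eff$impact[1], "HIGH")
  expect_equal(eff$consequence[1], "stop_gained")
  expect_equal(eff$gene_id[1], "LOC_Os10g35604")
})

test_that("apply_filters drops by MAF, heterozygosity and missingness", {
  # 100 samples; three designed violations plus one clean SNP
  n <- 100
  het70 <- c(rep(1L, 70), rep(0L, 15), rep(2L, 15))        # het 0.70
  rare  <- c(rep(1L, 4), rep(0L, 96))                      # MAF 0.02
  ok6   <- c(rep(1L, 12), rep(0L, 88))                     # MAF 0.06
  holey <- c(rep(NA_integer_, 60), rep(0L, 20), rep(2L, 20)) # miss 0.6
  gm <- toy_gm(rbind(het70, rare, ok6, holey))
  out <- apply_filters(gm, filter_params())  # maf 0.05, het 0.591, miss 0.5
  rep <- attr(out, "filter_report")
  expect_equal(n_snps(out), 1L)
  expect_equal(out$pos, gm$pos[3])
  expect_equal(rep$n_fail_het, 1L)
  expect_equal(rep$n_fail_maf, 1L)
  expect_equal(rep$n_fail_missing, 1L)
  # idempotence
  out2 <- apply_filters(out, filter_params())
  expect_identical(out$geno, out2$geno)
})

test_that("allele_frequencies: arithmetic, degenerate and pooling", {
  g <- rbind(c(0L, 1L, 2L, 2L, 1L),
             rep(NA_integer_, 5))
  gm <- toy_gm(g)
  pm <- stats::setNames(c("A", "A", "A", "B", "B"), samples(gm))
  all5 <- allele_frequencies(gm, samples(gm))
  expect_equal(all5$p[1], 0.6)
  expect_equal(all5$n[1], 10)
  expect_true(is.na(all5$p[2]))   # flagged undefined, not 0
  expect_equal(all5$n[2], 0)
  # union of disjoint populations = pooled frequency weighted by n
  fA <- allele_frequencies(gm, "A", pm)
  fB <- allele_frequencies(gm, "B", pm)
  pooled <- (fA$p[1] * fA$n[1] + fB$p[1] * fB$n[1]) / (fA$n[1] + fB$n[1])
  expect_equal(pooled, all5$p[1])
  expect_error(allele_frequencies(gm, "zZ"), "not in genotype matrix")
})

test_that("simulated population frequency sits in the binomial interval", {
  set.seed(14)
  n <- 100  # diploids -> 200 alleles at p = 0.3
  g <- matrix(rbinom(n, 2, 0.3), 1)
  gm <- toy_gm(g)
  f <- allele_frequencies(gm, samples(gm))
  half <- qnorm(0.995) * sqrt(0.3 * 0.7 / 200)
  expect_lt(abs(f$p - 0.3), half + 1e-12)
})
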