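# Region annotation: gene membership, QTL overlap, candidate calling,
# allele counts, GO enrichment.

mk_regions <- function(s, e, names = sprintf("R%d", seq_along(s)),
                       chrom = "chr1") {
  structure(data.frame(chrom = chrom, start = s, end = e, name = names),
            class = c("region_set", "data.frame"))
}

test_that("genes_in_regions uses the >=1 bp overlap rule", {
  regions <- mk_regions(c(1e5, 5e5), c(3e5, 6e5))
  genes <- data.frame(chrom = "chr1",
                      start = c(150000, 299999, 300000, 700000),
                      end = c(160000, 310000, 310000, 710000),
                      name = c("inside", "straddle", "outside", "far"))
  out <- genes_in_regions(regions, genes)
  expect_setequal(out$members$gene_id[out$members$region == "R1"],
                  c("inside", "straddle"))
  expect_equal(out$counts$n_genes, c(2L, 0L))
  # strict containment drops the boundary-straddling gene
  out2 <- genes_in_regions(regions, genes, contained = TRUE)
  expect_equal(out2$members$gene_id, "inside")
})

test_that("planted gene membership is reproduced exactly", {
  set.seed(50)
  nreg <- 10
  rs <- seq(0, by = 1e6, length.out = nreg)
  regions <- mk_regions(rs, rs + 5e5)
  n_in <- sample(3:12, nreg, replace = TRUE)
  genes <- do.call(rbind, lapply(seq_len(nreg), function(i) {
    st <- rs[i] + sort(sample.int(4e5, n_in[i]))
    data.frame(chrom = "chr1", start = st, end = st + 1000,
               name = sprintf("g%d_%d", i, seq_len(n_in[i])))
  }))
  # plus genes in the gaps, belonging to no region
  gap <- data.frame(chrom = "chr1", start = rs + 6e5, end = rs + 6.1e5,
                    name = sprintf("gap%d", seq_len(nreg)))
  out <- genes_in_regions(regions, rbind(genes, gap))
  expect_equal(out$counts$n_genes, n_in)
})

test_that("qtl_overlap reports pairs, lengths and empty sets", {
  regions <- mk_regions(c(1e5, 9e5), c(3e5, 9.5e5))
  qtls <- data.frame(chrom = "chr1", start = c(1e5, 2.5e5, 5e5),
                     end = c(3e5, 4e5, 6e5),
                     name = c("q1", "q2", "q3"),
                     trait_id = c("GL", "PBN", "DRP"),
                     source = "study")
  out <- qtl_overlap(regions, qtls)
  r1 <- out[out$region == "R1" & !is.na(out$qtl), ]
  expect_setequal(r1$qtl, c("q1", "q2"))
  expect_equal(r1$overlap_bp[r1$qtl == "q1"], 2e5)  # exact match length
  expect_equal(r1$overlap_bp[r1$qtl == "q2"], 5e4)
  # disjoint QTL absent; region with no QTL listed with empty traits
  expect_false("q3" %in% out$qtl[!is.na(out$qtl)])
  r2 <- out[out$region == "R2", ]
  expect_true(is.na(r2$trait_id))
  # symmetry: total overlap is the same viewed from either side
  swapped <- qtl_overlap(
    mk_regions(qtls$start, qtls$end, qtls$name),
    data.frame(chrom = regions$chrom, start = regions$start,
               end = regions$end, name = regions$name,
               trait_id = "x", source = "y"))
  expect_equal(sum(out$overlap_bp), sum(swapped$overlap_bp))
})

test_that("candidate_genes fires the three criteria independently", {
  membership <- data.frame(region = c("R1", "R2", "R2", "R3"),
                           gene_id = c("gA", "gB", "gC", "gD"))
  region_fst <- c(R1 = 0.64, R2 = 0.28, R3 = 0.1)
  gene_fst <- c(gA = 0.3, gB = 0.788, gC = 0.2, gD = 0.1)
  effects <- data.frame(gene_id = "gB", impact = "HIGH",
                        consequence = "stop_gained")
  out <- candidate_genes(membership, region_fst, gene_fst, effects,
                         qtl_candidates = NULL)
  # region F_ST 0.64 -> gA candidate via criterion 1
  expect_true("gA" %in% out$gene_id)
  expect_match(out$rationale[out$gene_id == "gA"], "fst")
  # HIGH impact in a 0.28 region -> gB candidate via criterion 2 (its
  # own gene F_ST 0.788 also fires criterion 1)
  expect_match(out$rationale[out$gene_id == "gB"], "high_impact")
  # nothing fires for gD
  expect_false("gD" %in% out$gene_id)
  # criterion 3 via the QTL's named candidate
  out3 <- candidate_genes(membership, region_fst, gene_fst, effects,
                          qtl_candidates = data.frame(region = "R3",
                                                      gene_id = "gD"))
  expect_match(out3$rationale[out3$gene_id == "gD"], "qtl")
  # rationale completeness: no inputs -> no candidates
  none <- candidate_genes(membership,
                          c(R1 = 0.1, R2 = 0.1, R3 = 0.1),
                          gene_fst * 0, NULL, NULL)
  expect_equal(nrow(none), 0L)
  expect_true(all(nzchar(out$rationale)))
  # enriched-gene restriction narrows the gene-level clause
  outE <- candidate_genes(membership, region_fst, gene_fst, NULL, NULL,
                          enriched_genes = character(0))
  expect_false("gB" %in% outE$gene_id)
})

test_that("allele_count_table tabulates bases with IUPAC het codes", {
  g <- rbind(c(0L, 0L, 2L, 2L, 1L, rep(0L, 3)),
             c(2L, 2L, 2L, 2L, 2L, rep(0L, 3)))
  gm <- toy_gm(g, ref = c("G", "C"), alt = c("A", "T"))
  pm <- stats::setNames(c(rep("I5", 5), rep("I1", 3)), samples(gm))
  out <- allele_count_table(gm, pm, data.frame(chrom = "chr1",
                                               pos = gm$pos))
  r <- out[out$pos == gm$pos[1] & out$subpop == "I5", ]
  expect_equal(r$n_ref_hom, 2L)  # G:2
  expect_equal(r$n_alt_hom, 2L)  # A:2
  expect_equal(r$n_het, 1L)      # R:1
  expect_equal(r$het_code, "R")
  # allele private to one subpopulation
  p2 <- out[out$pos == gm$pos[2], ]
  expect_equal(p2$n_alt_hom[p2$subpop == "I5"], 5L)
  expect_equal(p2$n_alt_hom[p2$subpop == "I1"], 0L)
  # conservation: counts + missing = subpopulation size
  gm$geno[1, 1] <- NA
  out2 <- allele_count_table(gm, pm, data.frame(chrom = "chr1",
                                                pos = gm$pos[1]))
  with(out2, expect_equal(n_ref_hom + n_alt_hom + n_het + n_missing,
                          c(5L, 3L)[match(subpop, c("I5", "I1"))]))
  expect_error(allele_count_table(gm, pm,
                                  data.frame(chrom = "chrX", pos = 1)),
               "not present")
})

test_that("go_enrichment equals the exact hypergeometric tail", {
  # 100 region genes, 10 annotated; background 10,000 with 100 annotated
  bg <- sprintf("g%05d", 1:10000)
  region <- bg[1:100]
  ann <- c(bg[1:10], bg[101:190])  # 10 in region, 90 outside -> K = 100
  go <- data.frame(gene_id = ann, term = "T")
  out <- go_enrichment(region, go, bg)
  expect_equal(out$p, hyper_tail_oracle(10, 100, 10000, 100),
               tolerance = 1e-12)
  # saturation: region = background -> p = 1
  sat <- go_enrichment(bg, go, bg)
  expect_equal(sat$p, 1)
  # terms with no region gene are not tested
  go2 <- rbind(go, data.frame(gene_id = bg[500:520], term = "U"))
  out2 <- go_enrichment(region, go2, bg)
  expect_false("U" %in% out2$term)
  # empty region gene list -> empty result
  expect_equal(nrow(go_enrichment(character(0), go, bg)), 0L)
})

test_that("BH-FDR is monotone non-decreasing in p-value rank", {
  set.seed(51)
  bg <- sprintf("g%04d", 1:2000)
  region <- sample(bg, 150)
  go <- do.call(rbind, lapply(1:12, function(i)
    data.frame(gene_id = sample(bg, sample(20:200, 1)),
               term = sprintf("T%02d", i))))
  out <- go_enrichment(region, go, bg)
  expect_true(all(out$p > 0 & out$p <= 1))
  expect_true(all(diff(out$fdr[order(out$p)]) >= -1e-15))
})
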