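# Annotation of selected regions: gene membership, QTL overlap,
# candidate-gene criteria, allele-count tables, GO enrichment.

#' Genes overlapping selected regions
#'
#' A gene belongs to a region when their intervals overlap by at least
#' 1 bp (set `contained = TRUE` for strict containment instead).
#'
#' @param regions a \code{region_set}.
#' @param genes gene interval data.frame (chrom, start, end, name).
#' @param contained require the gene to lie entirely inside the region.
#' @return list: \code{members} (data.frame region, gene_id) and
#'   \code{counts} (per-region gene counts, zero-filled).
#' @export
genes_in_regions <- function(regions, genes, contained = FALSE) {
  pairs <- overlap_pairs(regions, genes)
  if (contained && nrow(pairs)) {
    keep <- genes$start[pairs$yi] >= regions$start[pairs$xi] &
      genes$end[pairs$yi] <= regions$end[pairs$xi]
    pairs <- pairs[keep, , drop = FALSE]
  }
  members <- data.frame(region = regions$name[pairs$xi],
                        gene_id = genes$name[pairs$yi])
  counts <- data.frame(region = regions$name,
                       n_genes = as.integer(
                         table(factor(members$region,
                                      levels = regions$name))))
  list(members = members, counts = counts)
}

#' Overlap of selected regions with QTL intervals
#'
#' Every (region, QTL) pair overlapping by >= 1 bp, with the overlap
#' length and the QTL's trait; regions without any overlap are listed
#' with an empty trait set.
#'
#' @param regions a \code{region_set}.
#' @param qtls QTL table (chrom, start, end, name, trait_id, source,
#'   optionally candidate_genes), e.g. from
#'   \code{read_intervals(fmt = "TSV")}.
#' @return data.frame: region, qtl, trait_id, source, overlap_bp (one
#'   row per overlapping pair; regions with no overlap get one row with
#'   \code{NA} qtl fields).
#' @export
qtl_overlap <- function(regions, qtls) {
  pairs <- overlap_pairs(regions, qtls)
  hit <- data.frame(region = regions$name[pairs$xi],
                    qtl = qtls$name[pairs$yi],
                    trait_id = qtls$trait_id[pairs$yi],
                    source = if ("source" %in% names(qtls))
                      qtls$source[pairs$yi] else NA_character_,
                    overlap_bp = pairs$overlap_bp)
  none <- setdiff(regions$name, hit$region)
  if (length(none))
    hit <- rbind(hit, data.frame(region = none, qtl = NA_character_,
                                 trait_id = NA_character_,
                                 source = NA_character_, overlap_bp = 0))
  hit[order(match(hit$region, regions$name)), , drop = FALSE]
}

#' Candidate genes within selected regions
#'
#' A gene is a candidate when at least one of three criteria fires:
#' \enumerate{
#'   \item differentiation: its region's mean F_ST exceeds
#'     `fst_threshold`, or its own mean F_ST does (restricted to genes
#'     in `enriched_genes` when that set is supplied);
#'   \item impact: it carries at least one HIGH-impact effect;
#'   \item QTL: it is a named candidate gene of a QTL overlapping its
#'     region.
#' }
#' The rationale records every criterion that fired. Genes without an
#' F_ST value (no SNPs) are evaluable on criteria 2-3 only.
#'
#' @param membership \code{members} data.frame from
#'   [genes_in_regions()].
#' @param region_fst named numeric: region name -> mean F_ST.
#' @param gene_fst named numeric: gene id -> mean F_ST (may be
#'   incomplete).
#' @param effects effect records ([read_effects()]); HIGH impacts drive
#'   criterion 2.
#' @param qtl_candidates data.frame(region, gene_id) of QTL-named
#'   candidates per region (e.g. from the QTL table's candidate_genes
#'   column restricted to overlapping pairs); may be \code{NULL}.
#' @param enriched_genes optional character vector of genes annotated
#'   with a term enriched in their region (narrows criterion 1's
#'   gene-level clause).
#' @param fst_threshold default 0.5.
#' @return data.frame of class \code{candidate_genes}: gene_id, region,
#'   gene_fst, region_fst, high_impact, qtl_named, rationale.
#' @export
candidate_genes <- function(membership, region_fst, gene_fst = NULL,
                            effects = NULL, qtl_candidates = NULL,
                            enriched_genes = NULL, fst_threshold = 0.5) {
  if (!nrow(membership))
    return(data.frame(gene_id = character(), region = character(),
                      gene_fst = numeric(), region_fst = numeric(),
                      high_impact = logical(), qtl_named = logical(),
                      rationale = character()))
  g <- membership
  g$region_fst <- unname(region_fst[g$region])
  g$gene_fst <- if (is.null(gene_fst)) NA_real_ else
    unname(gene_fst[g$gene_id])
  hi_genes <- if (is.null(effects)) character(0) else
    unique(effects$gene_id[effects$impact == "HIGH"])
  g$high_impact <- g$gene_id %in% hi_genes
  g$qtl_named <- FALSE
  if (!is.null(qtl_candidates) && nrow(qtl_candidates))
    g$qtl_named <- paste(g$region, g$gene_id) %in%
      paste(qtl_candidates$region, qtl_candidates$gene_id)
  gene_clause <- !is.na(g$gene_fst) & g$gene_fst > fst_threshold
  if (!is.null(enriched_genes))
    gene_clause <- gene_clause & g$gene_id %in% enriched_genes
  c1 <- (!is.na(g$region_fst) & g$region_fst > fst_threshold) | gene_clause
  c2 <- g$high_impact
  c3 <- g$qtl_named
  fired <- c1 | c2 | c3
  rat <- apply(cbind(c1, c2, c3), 1L, function(z)
    paste(c("fst", "high_impact", "qtl")[z], collapse = ","))
  out <- data.frame(gene_id = g$gene_id, region = g$region,
                    gene_fst = g$gene_fst, region_fst = g$region_fst,
                    high_impact = c2, qtl_named = c3,
                    rationale = rat)[fired, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_genes", "data.frame"))
}

.iupac <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
            AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M")

#' Per-subpopulation allele count table at chosen SNPs
#'
#' For each SNP and subpopulation, the counts of homozygous-reference,
#' homozygous-alternate and heterozygous calls, labelled by base (het as
#' the IUPAC ambiguity code of ref/alt); missing calls are excluded from
#' the counts but reported.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map.
#' @param keys data.frame(chrom, pos) of SNPs to tabulate.
#' @return data.frame: chrom, pos, subpop, ref_base, alt_base, het_code,
#'   n_ref_hom, n_alt_hom, n_het, n_missing.
#' @export
allele_count_table <- function(gm, popmap, keys) {
  idx <- match(paste(keys$chrom, keys$pos), paste(gm$chrom, gm$pos))
  if (anyNA(idx))
    stopf("SNP key(s) not present in genotype matrix: %s",
          paste(utils::head(paste(keys$chrom, keys$pos)[is.na(idx)], 3),
                collapse = "; "))
  pops <- unique(popmap)
  out <- list()
  for (j in seq_along(idx)) {
    i <- idx[j]
    het <- .iupac[paste0(gm$ref[i], gm$alt[i])]
    for (pp in pops) {
      g <- gm$geno[i, pop_samples(popmap, pp)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = gm$chrom[i], pos = gm$pos[i], subpop = pp,
        ref_base = gm$ref[i], alt_base = gm$alt[i],
        het_code = unname(het),
        n_ref_hom = sum(g == 0L, na.rm = TRUE),
        n_alt_hom = sum(g == 2L, na.rm = TRUE),
        n_het = sum(g == 1L, na.rm = TRUE),
        n_missing = sum(is.na(g)))
    }
  }
  do.call(rbind, out)
}

#' GO-term enrichment of region genes by hypergeometric test
#'
#' For each term annotating at least one region gene, the one-sided
#' hypergeometric upper-tail probability of observing at least k
#' annotated genes among the n region genes given K annotated among the
#' N background genes; Benjamini-Hochberg FDR across the region's
#' tested terms.
#'
#' @param region_genes character vector of gene ids in the region (must
#'   be a subset of `background_genes`).
#' @param go_map data.frame(gene_id, term).
#' @param background_genes character vector of background gene ids.
#' @param fdr FDR threshold for the \code{enriched} flag (default 0.05).
#' @return data.frame of class \code{enrichment_result}: term,
#'   n_region (k), n_background (K), p, fdr, enriched.
#' @export
go_enrichment <- function(region_genes, go_map, background_genes,
                          fdr = 0.05) {
  empty <- structure(
    data.frame(term = character(), n_region = integer(),
               n_background = integer(), p = numeric(), fdr = numeric(),
               enriched = logical()),
    class = c("enrichment_result", "data.frame"))
  region_genes <- unique(region_genes)
  background_genes <- unique(background_genes)
  if (!length(region_genes)) return(empty)
  extra <- setdiff(region_genes, background_genes)
  if (length(extra))
    stopf("region genes absent from background: %s",
          paste(utils::head(extra, 3), collapse = ", "))
  gm2 <- go_map[go_map$gene_id %in% background_genes, , drop = FALSE]
  N <- length(background_genes)
  n <- length(region_genes)
  terms <- unique(gm2$term[gm2$gene_id %in% region_genes])
  if (!length(terms)) return(empty)
  k <- vapply(terms, function(t)
    length(intersect(gm2$gene_id[gm2$term == t], region_genes)), 0L)
  K <- vapply(terms, function(t)
    length(unique(gm2$gene_id[gm2$term == t])), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = terms, n_region = k, n_background = K,
                    p = p, fdr = padj, enriched = padj < fdr)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
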