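# Synthetic-data generators: neutral drift simulator, sweep injection,
# and toy annotation fixtures. Everything is a pure function of
# (parameters, seed).

#' Simulation parameters for the neutral drift generator
#'
#' The generator draws an ancestral allele frequency per SNP, perturbs it
#' independently per population by a censored Normal drift kernel, and
#' samples diploid genotypes binomially. `drift_var` is the *pairwise*
#' drift-variance coefficient omega targeted between any two populations
#' (Var(p1 - p2) = drift_var * p(1-p)), so each branch receives variance
#' drift_var/2 * p(1-p); this makes [estimate_omega()] recover
#' `drift_var` directly.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population (>= 2).
#' @param seq_len chromosome length in bp.
#' @param n_chroms number of chromosomes.
#' @param drift_var pairwise drift variance coefficient in (0, 1);
#'   default 0.4 puts two-population Weir-Cockerham F_ST near 0.2,
#'   matching the subpopulation differentiation of the rice panels this
#'   generator stands in for (mean F_ST roughly 0.15-0.25).
#' @param snp_density SNPs per bp (default 1e-3, i.e. one SNP/kb).
#' @param recomb_rate cM per Mb used for the bp -> Morgan conversion
#'   (default 1.0, same convention as the scan).
#' @param anc_range range of the uniform ancestral-frequency
#'   distribution; default c(0.05, 0.95) so the 5% MAF filter is mostly
#'   non-binding.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_pops = 2, n_per_pop = 50, seq_len = 5e6,
                       n_chroms = 1, drift_var = 0.4, snp_density = 1e-3,
                       recomb_rate = 1.0, anc_range = c(0.05, 0.95),
                       seed = 1) {
  if (n_per_pop < 2) stopf("n_per_pop must be >= 2")
  if (seq_len <= 0 || n_chroms < 1 || n_pops < 1)
    stopf("population/chromosome sizes must be positive")
  if (drift_var < 0 || drift_var >= 1)
    stopf("drift_var must be in [0, 1)")
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, seq_len = seq_len,
                 n_chroms = n_chroms, drift_var = drift_var,
                 snp_density = snp_density, recomb_rate = recomb_rate,
                 anc_range = anc_range, seed = seed),
            class = "sim_params")
}

#' Simulate neutral drift-structured genotypes
#'
#' Per SNP: ancestral frequency ~ Uniform(anc_range); each population's
#' frequency is the ancestral one plus Normal(0, drift_var/2 * p(1-p))
#' noise, censored to [0, 1] (mass outside piles at the bounds, matching
#' the scan's drift kernel); genotypes are Binomial(2, p_pop) per
#' individual. Positions are uniform draws (without replacement) along
#' each chromosome.
#'
#' @param params a [sim_params()] object.
#' @param pop_labels optional labels (default "P1", "P2", ...).
#' @return list with \code{gm} (a [genotype_matrix()]), \code{popmap}
#'   (named character vector) and \code{anc_freq} (ancestral frequency
#'   per SNP).
#' @export
simulate_neutral <- function(params, pop_labels = NULL) {
  stopifnot(inherits(params, "sim_params"))
  labs <- pop_labels %||% sprintf("P%d", seq_len(params$n_pops))
  stopifnot(length(labs) == params$n_pops)
  with_seed(params$seed, {
    n_snp_chr <- max(1L, round(params$seq_len * params$snp_density))
    bases <- c("A", "C", "G", "T")
    chroms <- sprintf("chr%d", seq_len(params$n_chroms))
    chrom <- rep(chroms, each = n_snp_chr)
    pos <- unlist(lapply(chroms, function(ch)
      sort(sample.int(params$seq_len, n_snp_chr))))
    m <- n_snp_chr * params$n_chroms
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    p_anc <- stats::runif(m, params$anc_range[1], params$anc_range[2])
    sd_branch <- sqrt(params$drift_var / 2 * p_anc * (1 - p_anc))
    nind <- params$n_per_pop
    geno <- matrix(NA_integer_, m, nind * params$n_pops)
    ids <- character(0)
    for (k in seq_len(params$n_pops)) {
      pk <- pmin(1, pmax(0, p_anc + stats::rnorm(m, 0, sd_branch)))
      cols <- (k - 1L) * nind + seq_len(nind)
      geno[, cols] <- stats::rbinom(m * nind, 2L, pk)
      ids <- c(ids, sprintf("%s_%02d", labs[k], seq_len(nind)))
    }
    colnames(geno) <- ids
    popmap <- stats::setNames(rep(labs, each = nind), ids)
    contigs <- stats::setNames(rep(params$seq_len, params$n_chroms), chroms)
    gm <- genotype_matrix(chrom, pos, unname(ref), unname(alt), geno,
                          contigs = contigs)
    list(gm = gm, popmap = popmap, anc_freq = p_anc)
  })
}

#' Sweep specification
#'
#' @param pop target population label.
#' @param chrom chromosome id.
#' @param position focal bp of the beneficial mutation.
#' @param strength sweep scale sigma_s in Morgans (> 0); larger values
#'   drag a wider flanking region.
#' @param kind \code{"hard"} (single founding haplotype) or \code{"soft"}
#'   (standing variation).
#' @param soft_init_freq initial frequency of the beneficial allele for
#'   soft sweeps (required iff kind = "soft").
#' @return list of class \code{sweep_spec}.
#' @export
sweep_spec <- function(pop, chrom, position, strength, kind = c("hard", "soft"),
                       soft_init_freq = NULL) {
  kind <- match.arg(kind)
  if (strength <= 0) stopf("sweep strength must be > 0")
  if (kind == "soft") {
    if (is.null(soft_init_freq) || soft_init_freq <= 0 || soft_init_freq >= 1)
      stopf("soft sweeps need soft_init_freq in (0, 1)")
  }
  structure(list(pop = pop, chrom = chrom, position = position,
                 strength = strength, kind = kind,
                 soft_init_freq = soft_init_freq), class = "sweep_spec")
}

#' Inject a selective sweep into a simulated genotype matrix
#'
#' In the target population only, each SNP at genetic distance d Morgans
#' from the focal position hitchhikes with probability 1 - c, where
#' c = 1 - exp(-d / strength) is the escape probability (the same model
#' the scan's likelihood uses). A hitchhiking SNP's population frequency
#' is redrawn from the allele spectrum of the founding swept haplotypes:
#' one founder for hard sweeps (frequency jumps to 0 or 1), and
#' \code{round(soft_init_freq * 2 * n)} founders for soft sweeps;
#' genotypes are then re-sampled binomially. SNPs with c >= 0.999 and all
#' other populations are untouched.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map covering `spec$pop`.
#' @param spec a [sweep_spec()].
#' @param seed integer seed.
#' @param recomb_rate cM/Mb for the bp -> Morgan conversion (default 1).
#' @return list with \code{gm} (modified matrix) and \code{truth}
#'   (class \code{sweep_truth}): the spec, realized post-sweep frequency
#'   at the focal SNP, and the per-SNP hitchhike indicator.
#' @export
inject_sweep <- function(gm, popmap, spec, seed, recomb_rate = 1.0) {
  stopifnot(inherits(spec, "sweep_spec"))
  samp <- pop_samples(popmap, spec$pop)
  cols <- match(samp, colnames(gm$geno))
  on_chr <- which(gm$chrom == spec$chrom)
  if (!length(on_chr)) stopf("no SNPs on chromosome %s", spec$chrom)
  d <- abs(gm$pos[on_chr] - spec$position) * recomb_rate * 1e-8  # Morgans
  cesc <- 1 - exp(-d / spec$strength)
  with_seed(seed, {
    eligible <- cesc < 0.999
    hh <- eligible & (stats::runif(length(on_chr)) < (1 - cesc))
    g <- gm$geno
    nind <- length(cols)
    m_found <- if (spec$kind == "hard") 1L else
      max(1L, round(spec$soft_init_freq * 2L * nind))
    for (j in which(hh)) {
      row <- on_chr[j]
      gj <- g[row, cols]
      nm <- sum(!is.na(gj))
      if (nm == 0L) { hh[j] <- FALSE; next }
      p_cur <- sum(gj, na.rm = TRUE) / (2 * nm)
      p_new <- stats::rbinom(1L, m_found, p_cur) / m_found
      g[row, cols] <- stats::rbinom(nind, 2L, p_new)
    }
    out <- gm
    out$geno <- g
    focal <- on_chr[which.min(abs(gm$pos[on_chr] - spec$position))]
    gfo <- g[focal, cols]
    truth <- structure(list(
      spec = spec,
      focal_pos = gm$pos[focal],
      focal_freq = sum(gfo, na.rm = TRUE) / (2 * sum(!is.na(gfo))),
      hitchhiked_pos = gm$pos[on_chr][hh],
      n_hitchhiked = sum(hh)), class = "sweep_truth")
    list(gm = out, truth = truth)
  })
}

#' Generate toy annotation fixtures
#'
#' Writes deterministic, internally consistent annotation files for the
#' simulated chromosomes: non-overlapping gene models (GFF3 + BED), a GO
#' map at controlled term frequencies, a QTL interval table, one 200-kb
#' centromere interval per chromosome, and a SnpEff-style VCF ANN effect
#' table with HIGH-impact entries at chosen genes.
#'
#' @param contigs named vector of chromosome lengths (bp).
#' @param out_dir output directory (created if needed).
#' @param n_genes_per_chrom genes tiled per chromosome.
#' @param go_terms named integer vector: GO id -> number of genes
#'   annotated with it.
#' @param n_qtls_per_chrom QTL intervals per chromosome.
#' @param high_impact_genes gene names to receive a HIGH-impact
#'   (stop_gained / start_lost) effect record; default picks two per
#'   chromosome.
#' @param seed integer seed (fixed seed => byte-identical files).
#' @return list of file paths (genes_gff3, genes_bed, qtls, go_map,
#'   centromeres, effects) plus the in-memory tables.
#' @export
make_toy_annotation <- function(contigs, out_dir,
                                n_genes_per_chrom = 100,
                                go_terms = c("GO:0008150" = 40,
                                             "GO:0009058" = 10,
                                             "GO:0006950" = 5),
                                n_qtls_per_chrom = 3,
                                high_impact_genes = NULL,
                                seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    genes <- list()
    for (ch in names(contigs)) {
      L <- contigs[[ch]]
      slot <- floor(L / n_genes_per_chrom)
      gene_len <- max(200L, floor(slot * 0.4))
      start <- (seq_len(n_genes_per_chrom) - 1L) * slot +
        sample.int(max(1L, slot - gene_len), n_genes_per_chrom,
                   replace = TRUE) - 1L
      genes[[ch]] <- data.frame(
        chrom = ch, start = start, end = start + gene_len,
        name = sprintf("%s_g%04d", ch, seq_len(n_genes_per_chrom)))
    }
    genes <- do.call(rbind, genes)
    rownames(genes) <- NULL

    total_genes <- nrow(genes)
    if (any(go_terms > total_genes)) stopf("go_terms counts exceed gene count")
    go <- do.call(rbind, lapply(names(go_terms), function(term)
      data.frame(gene_id = sample(genes$name, go_terms[[term]]), term = term)))

    qtls <- list()
    for (ch in names(contigs)) {
      L <- contigs[[ch]]
      # QTL lengths 4-12% of the chromosome (a few hundred kb at the
      # 5-Mb scale of the bundled fixtures)
      qlen <- sample(round(0.04 * L):round(0.12 * L), n_qtls_per_chrom,
                     replace = TRUE)
      qs <- sort(vapply(qlen, function(ql)
        sample.int(max(1L, L - ql), 1L), 1L))
      qtls[[ch]] <- data.frame(
        chrom = ch, start = qs, end = pmin(L, qs + qlen),
        name = sprintf("q%s_%d", sub("chr", "", ch),
                       seq_len(n_qtls_per_chrom)),
        trait_id = sample(c("GL", "PBN", "DRP", "TIL", "SHL"),
                          n_qtls_per_chrom, replace = TRUE),
        source = "toy_study",
        candidate_genes = "")
      qtls[[ch]] <- qtls[[ch]][order(qtls[[ch]]$start), ]
    }
    qtls <- do.call(rbind, qtls)
    rownames(qtls) <- NULL
    # name a candidate gene for the first QTL of each chromosome
    for (ch in names(contigs)) {
      i <- which(qtls$chrom == ch)[1]
      hit <- genes$chrom == ch & genes$start < qtls$end[i] &
        genes$end > qtls$start[i]
      if (any(hit)) qtls$candidate_genes[i] <- genes$name[which(hit)[1]]
    }

    cent <- data.frame(chrom = names(contigs),
                       start = floor(unlist(contigs) / 2) - 100000,
                       end = floor(unlist(contigs) / 2) + 100000,
                       name = paste0(names(contigs), "_cen"))
    rownames(cent) <- NULL

    hi <- high_impact_genes %||%
      genes$name[unlist(tapply(seq_len(nrow(genes)), genes$chrom,
                               function(i) i[1:2]))]
    gidx <- match(hi, genes$name)
    eff_pos <- floor((genes$start[gidx] + genes$end[gidx]) / 2) + 1L
    effects <- data.frame(
      chrom = genes$chrom[gidx], pos = eff_pos, ref = "G", alt = "A",
      gene_id = hi,
      impact = "HIGH",
      consequence = rep(c("stop_gained", "start_lost"), length.out = length(hi)))

    paths <- list(
      genes_gff3 = file.path(out_dir, "genes.gff3"),
      genes_bed = file.path(out_dir, "genes.bed"),
      qtls = file.path(out_dir, "qtls.tsv"),
      go_map = file.path(out_dir, "go_map.tsv"),
      centromeres = file.path(out_dir, "centromeres.bed"),
      effects = file.path(out_dir, "effects.tsv"))

    writeLines(c("##gff-version 3",
                 sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                         genes$chrom, genes$start + 1L, genes$end,
                         genes$name)), paths$genes_gff3)
    writeLines(sprintf("%s\t%d\t%d\t%s", genes$chrom, genes$start,
                       genes$end, genes$name), paths$genes_bed)
    utils::write.table(qtls, paths$qtls, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(sprintf("%s\t%s", go$gene_id, go$term), paths$go_map)
    writeLines(sprintf("%s\t%d\t%d\t%s", cent$chrom, cent$start, cent$end,
                       cent$name), paths$centromeres)
    utils::write.table(effects, paths$effects, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    c(paths, list(genes = genes, go = go, qtl_table = qtls,
                  centromere_table = cent, effect_table = effects))
  })
}
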