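# End-to-end orchestration: filter -> ordered pairwise scans within each
# group -> cutoffs -> per-comparison region calls -> per-subpopulation
# consensus -> F_ST / pi cross-validation -> annotation, candidates,
# enrichment -> summary tables.

#' Pipeline configuration
#'
#' @param vcf,popmap,genes,qtls,centromeres,go_map input file paths
#'   (VCF; sample->subpopulation TSV; GFF3 or BED gene models; BED-like
#'   QTL TSV; centromere BED; gene->GO TSV). `genes` format is inferred
#'   from the extension (.gff3/.gff vs .bed).
#' @param gmap optional genetic map TSV (chrom, bp, cM).
#' @param groups named list of subpopulation groups scanned against each
#'   other, e.g. \code{list(Indica = c("I1","I5"), Japonica = ...)}.
#' @param min_support named integer per group: comparisons required for
#'   consensus (e.g. \code{c(Indica = 3, Japonica = 2)}).
#' @param filter,scan,call parameter objects ([filter_params()],
#'   [scan_params()], [region_call_params()]; `call$min_support` is
#'   overridden per group).
#' @param out_dir output directory for stage TSVs and the manifest.
#' @param seed integer seed recorded in the manifest.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(vcf, popmap, genes = NULL, qtls = NULL,
                            centromeres = NULL, go_map = NULL, gmap = NULL,
                            groups, min_support,
                            filter = filter_params(),
                            scan = scan_params(),
                            call = region_call_params(),
                            out_dir = tempfile("sweepscan_"), seed = 1) {
  structure(list(vcf = vcf, popmap = popmap, genes = genes, qtls = qtls,
                 centromeres = centromeres, go_map = go_map, gmap = gmap,
                 groups = groups, min_support = min_support,
                 filter = filter, scan = scan, call = call,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Ordered pairwise comparisons within a subpopulation group
#'
#' Scans are directional, so a group of k subpopulations yields
#' k * (k - 1) ordered (test, ref) pairs.
#'
#' @param pops character vector of subpopulation labels.
#' @return data.frame with columns test, ref and id ("test_vs_ref").
#' @export
comparison_pairs <- function(pops) {
  out <- expand.grid(ref = pops, test = pops, stringsAsFactors = FALSE)
  out <- out[out$test != out$ref, c("test", "ref")]
  out$id <- sprintf("%s_vs_%s", out$test, out$ref)
  out <- out[order(out$test, out$ref), ]
  rownames(out) <- NULL
  out
}

#' Validate a pipeline configuration
#'
#' Checks file existence, population-map coverage and group /
#' min_support consistency; all structural problems are enumerated in
#' one report rather than raised one at a time.
#'
#' @param config a [pipeline_config()].
#' @return list with character vectors \code{errors} and
#'   \code{warnings}.
#' @export
validate_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  need <- c("vcf", "popmap")
  for (f in need)
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      errors <- c(errors, sprintf("missing required input: %s", f))
  for (f in c("genes", "qtls", "centromeres", "go_map", "gmap"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      errors <- c(errors, sprintf("configured %s file not found: %s",
                                  f, config[[f]]))
  if (!length(config$groups) || is.null(names(config$groups)))
    errors <- c(errors, "groups must be a named list")
  pm <- if (!is.null(config$popmap) && file.exists(config$popmap))
    read_population_map(config$popmap) else NULL
  for (grp in names(config$groups)) {
    pops <- config$groups[[grp]]
    ms <- config$min_support[[grp]]
    if (is.null(ms)) {
      errors <- c(errors, sprintf("no min_support for group %s", grp))
    } else if (ms > length(pops) - 1L) {
      errors <- c(errors, sprintf(
        "group %s: min_support %d exceeds the %d comparisons per subpopulation",
        grp, ms, length(pops) - 1L))
    }
    if (!is.null(pm)) {
      missing <- setdiff(pops, unique(pm))
      if (length(missing))
        errors <- c(errors, sprintf("group %s: subpopulation(s) absent from popmap: %s",
                                    grp, paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(pm) && !is.null(config$vcf) && file.exists(config$vcf)) {
    hdr <- grep("^#CHROM", readLines(config$vcf, n = 500L), value = TRUE)
    if (length(hdr)) {
      vs <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-(1:9)]
      orphan <- setdiff(names(pm), vs)
      if (length(orphan))
        warnings <- c(warnings, sprintf("popmap sample(s) absent from VCF: %s",
                                        paste(utils::head(orphan, 5),
                                              collapse = ", ")))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full selection-scan pipeline
#'
#' @param config a [pipeline_config()].
#' @param resume when TRUE, per-comparison scan tracks already present
#'   in `out_dir/scans/` are reloaded instead of recomputed.
#' @param quiet suppress progress messages.
#' @return list: filtered genotypes, per-comparison tracks, cutoffs,
#'   per-comparison and consensus region sets, F_ST / pi tracks,
#'   per-region annotation (genes, QTLs, enrichment, candidates),
#'   summary table, and the run manifest (config snapshot + output
#'   checksums), all also written under `out_dir`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  chk <- validate_config(config)
  if (length(chk$errors))
    stopf("invalid configuration:\n  - %s",
          paste(chk$errors, collapse = "\n  - "))
  for (w in chk$warnings) warnf("%s", w)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(file.path(config$out_dir, "scans"), showWarnings = FALSE,
             recursive = TRUE)

  say("reading inputs")
  pm <- read_population_map(config$popmap)
  gm0 <- read_vcf(config$vcf)
  genes <- if (!is.null(config$genes))
    read_intervals(config$genes,
                   fmt = if (grepl("\\.gff3?$", config$genes)) "GFF3"
                   else "BED") else NULL
  qtls <- if (!is.null(config$qtls))
    read_intervals(config$qtls, fmt = "TSV") else NULL
  cent <- if (!is.null(config$centromeres))
    read_intervals(config$centromeres, fmt = "BED") else NULL
  gomap <- if (!is.null(config$go_map)) {
    d <- data.table::fread(config$go_map, header = FALSE, sep = "\t",
                           data.table = FALSE)
    stats::setNames(d[, 1:2], c("gene_id", "term"))
  } else NULL
  gmap <- if (!is.null(config$gmap))
    data.table::fread(config$gmap, header = TRUE, data.table = FALSE)
  else NULL

  say("filtering %d SNPs", n_snps(gm0))
  gm <- apply_filters(gm0, config$filter)
  say("kept %d SNPs", n_snps(gm))

  genome_bp <- sum(gm$contigs)
  tracks <- list(); track_subpop <- character(0)
  for (grp in names(config$groups)) {
    cp <- comparison_pairs(config$groups[[grp]])
    for (j in seq_len(nrow(cp))) {
      test <- cp$test[j]; ref <- cp$ref[j]; id <- cp$id[j]
      cache <- file.path(config$out_dir, "scans", paste0(id, ".tsv"))
      if (resume && file.exists(cache)) {
        say("scan %s (cached)", id)
        d <- data.table::fread(cache, data.table = FALSE, na.strings = "NA")
        tr <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                         focal = d$focal_bp, n_snps = d$n_snps,
                         score = d$score, sigma_hat = d$sigma_hat,
                         partial = (d$end - d$start) < config$scan$window_bp)
        tr <- structure(tr, class = c("score_track", "data.frame"),
                        stat = "xpclr", test = test, ref = ref,
                        contigs = gm$contigs)
      } else {
        say("scan %s", id)
        tr <- xpclr_scan(gm, pm, test, ref, config$scan, gmap = gmap)
        write_track(tr, cache)
      }
      if (!is.null(cent)) tr <- mask_centromeres(tr, cent)
      tracks[[id]] <- tr
      track_subpop[id] <- test
    }
  }

  say("cutoffs and region calls")
  cut <- percentile_cutoff(tracks, subpop_of = track_subpop)
  calls <- list()
  for (id in names(tracks))
    calls[[id]] <- call_regions(tracks[[id]], cut$cutoff[track_subpop[id]],
                                config$call)

  consensus <- list(); fst_snp <- list(); fst_track <- list()
  pi_track <- list(); region_fst <- list(); annot <- list()
  summary_rows <- list()
  for (grp in names(config$groups)) {
    pops <- config$groups[[grp]]
    params_g <- config$call
    params_g$min_support <- config$min_support[[grp]]
    for (sp in pops) {
      ids <- names(track_subpop)[track_subpop == sp]
      cons <- consensus_regions(calls[ids], params_g)
      if (nrow(cons)) cons$name <- sprintf("%s_%d", sp, seq_len(nrow(cons)))
      consensus[[sp]] <- cons
      say("%s: %d consensus region(s)", sp, nrow(cons))

      others <- setdiff(pops, sp)
      fst <- wc_fst(gm, pm, sp, others)
      fst_snp[[sp]] <- fst
      fst_track[[sp]] <- windowed_fst(fst, config$scan$window_bp,
                                      config$scan$step_bp, gm$contigs)
      pi_track[[sp]] <- nucleotide_diversity(gm, pm, sp,
                                             config$scan$window_bp,
                                             config$scan$step_bp)
      if (nrow(cons)) {
        rf <- mean_stat_over_intervals(fst, cons)
        region_fst[[sp]] <- stats::setNames(rf$mean_value, rf$name)
      } else region_fst[[sp]] <- stats::setNames(numeric(0), character(0))

      if (!is.null(genes) && nrow(cons)) {
        gr <- genes_in_regions(cons, genes)
        gf <- mean_stat_over_intervals(fst, genes)
        gene_fst <- stats::setNames(gf$mean_value, gf$name)
        qo <- if (!is.null(qtls)) qtl_overlap(cons, qtls) else NULL
        qc <- NULL
        if (!is.null(qo) && "candidate_genes" %in% names(qtls)) {
          qq <- qo[!is.na(qo$qtl), , drop = FALSE]
          cg <- qtls$candidate_genes[match(qq$qtl, qtls$name)]
          qc <- data.frame(region = qq$region, gene_id = cg)
          qc <- qc[!is.na(qc$gene_id) & nzchar(qc$gene_id), , drop = FALSE]
        }
        enr <- NULL; enriched_gene_set <- NULL
        if (!is.null(gomap)) {
          enr <- list()
          for (rg in cons$name) {
            rg_genes <- gr$members$gene_id[gr$members$region == rg]
            enr[[rg]] <- go_enrichment(rg_genes, gomap, genes$name)
          }
          enriched_gene_set <- unique(unlist(lapply(names(enr), function(rg) {
            terms <- enr[[rg]]$term[enr[[rg]]$enriched]
            rg_genes <- gr$members$gene_id[gr$members$region == rg]
            intersect(rg_genes, gomap$gene_id[gomap$term %in% terms])
          })))
        }
        effects <- tryCatch(read_effects(config$vcf),
                            error = function(e) NULL)
        cand <- candidate_genes(gr$members, region_fst[[sp]], gene_fst,
                                effects, qc,
                                enriched_genes = enriched_gene_set)
        annot[[sp]] <- list(genes = gr, gene_fst = gene_fst,
                            qtl_overlap = qo, enrichment = enr,
                            candidates = cand)
      }
      sm <- region_summary(cons, genome_bp)
      sm$subpop <- sp
      sm$cutoff <- unname(cut$cutoff[sp])
      sm$n_genes <- if (!is.null(annot[[sp]]))
        sum(annot[[sp]]$genes$counts$n_genes) else NA_integer_
      summary_rows[[sp]] <- sm
    }
  }
  summary_tab <- do.call(rbind, summary_rows)
  summary_tab <- summary_tab[, c("subpop", "cutoff", "n_regions",
                                 "mean_length", "total_length",
                                 "pct_genome", "n_genes")]
  rownames(summary_tab) <- NULL

  # write stage outputs + manifest
  utils::write.table(summary_tab, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in names(consensus))
    if (nrow(consensus[[sp]]))
      write_regions(consensus[[sp]],
                    file.path(config$out_dir, sprintf("regions_%s.bed", sp)))
  outs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed,
    omega = lapply(tracks, function(t) {
      o <- attr(t, "omega"); if (is.null(o)) NA_real_ else o$omega
    }),
    cutoffs = as.list(cut$cutoff),
    per_comparison_q99 = as.list(cut$per_comparison),
    checksums = as.list(tools::md5sum(outs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(gm = gm, popmap = pm, tracks = tracks, cutoffs = cut,
       calls = calls, consensus = consensus, fst_snp = fst_snp,
       fst_track = fst_track, pi_track = pi_track,
       region_fst = region_fst, annotation = annot,
       summary = summary_tab, manifest = manifest)
}

#' Generate the bundled demonstration dataset
#'
#' A simulated stand-in for a multi-subpopulation rice panel: 9
#' subpopulations (I1-I5 Indica-like, J1-J4 Japonica-like) on 2
#' chromosomes of 5 Mb, with three planted hard sweeps (in I5 on chr1,
#' I2 on chr2 and J4 on chr2) plus toy annotation fixtures, written to
#' `dir` in standard formats so the pipeline's real readers are
#' exercised.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_per_pop diploid individuals per subpopulation (default 16).
#' @param snp_density SNPs per bp (default 5e-4).
#' @return list: file paths, the [pipeline_config()], and the truth
#'   (list of \code{sweep_truth}).
#' @export
make_demo_dataset <- function(dir, seed = 1, n_per_pop = 16,
                              snp_density = 5e-4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- c(sprintf("I%d", 1:5), sprintf("J%d", 1:4))
  sp <- sim_params(n_pops = 9, n_per_pop = n_per_pop, seq_len = 5e6,
                   n_chroms = 2, drift_var = 0.4,
                   snp_density = snp_density, seed = seed)
  sim <- simulate_neutral(sp, pop_labels = labs)
  sweeps <- list(
    sweep_spec("I5", "chr1", 1.5e6, strength = 0.02),
    sweep_spec("I2", "chr2", 3.5e6, strength = 0.02),
    sweep_spec("J4", "chr2", 1.0e6, strength = 0.02))
  truth <- list()
  gm <- sim$gm
  for (i in seq_along(sweeps)) {
    inj <- inject_sweep(gm, sim$popmap, sweeps[[i]], seed = seed + i)
    gm <- inj$gm
    truth[[i]] <- inj$truth
  }
  vcf <- file.path(dir, "demo.vcf")
  write_vcf(gm, vcf)
  pmf <- file.path(dir, "popmap.tsv")
  writeLines(sprintf("%s\t%s", names(sim$popmap), sim$popmap), pmf)
  ann <- make_toy_annotation(gm$contigs, dir, seed = seed)
  cfg <- pipeline_config(
    vcf = vcf, popmap = pmf, genes = ann$genes_gff3, qtls = ann$qtls,
    centromeres = ann$centromeres, go_map = ann$go_map,
    groups = list(Indica = sprintf("I%d", 1:5),
                  Japonica = sprintf("J%d", 1:4)),
    min_support = c(Indica = 3, Japonica = 2),
    out_dir = file.path(dir, "out"), seed = seed)
  list(vcf = vcf, popmap = pmf, annotation = ann, config = cfg,
       truth = truth)
}
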