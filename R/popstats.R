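# Weir & Cockerham (1984) F_ST variance components and windowed
# nucleotide diversity.

#' Per-SNP Weir-Cockerham F_ST between two populations
#'
#' Computes the two-population variance components a (among populations),
#' b (among individuals within populations) and c (within individuals)
#' from per-population sample sizes, allele frequencies and observed
#' heterozygote frequencies, with per-SNP non-missing counts. SNPs
#' monomorphic across the pooled pair are removed; theta = a/(a+b+c) is
#' reported raw and clamped at 0 (the clamped value is what downstream
#' summaries use). Either side may be a single label or several labels
#' pooled into one population (e.g. one subpopulation vs the union of
#' the rest).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map.
#' @param popA,popB subpopulation label(s); sets must be disjoint.
#' @return data.frame of class \code{fst_components}: chrom, pos, a, b,
#'   c, theta, theta_clamped; attribute \code{fst_report} counts removed
#'   SNPs, attribute \code{contigs} carries chromosome lengths.
#' @export
wc_fst <- function(gm, popmap, popA, popB) {
  sA <- pop_samples(popmap, popA)
  sB <- pop_samples(popmap, popB)
  if (length(intersect(sA, sB))) stopf("popA and popB share samples")
  sA <- intersect(sA, samples(gm)); sB <- intersect(sB, samples(gm))
  if (!length(sA) || !length(sB)) stopf("empty population sample set")
  gA <- gm$geno[, sA, drop = FALSE]
  gB <- gm$geno[, sB, drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))
  pA <- ifelse(nA > 0, rowSums(gA, na.rm = TRUE) / (2 * nA), NA_real_)
  pB <- ifelse(nB > 0, rowSums(gB, na.rm = TRUE) / (2 * nB), NA_real_)
  hA <- ifelse(nA > 0, rowSums(gA == 1L, na.rm = TRUE) / nA, NA_real_)
  hB <- ifelse(nB > 0, rowSums(gB == 1L, na.rm = TRUE) / nB, NA_real_)

  r <- 2
  nbar <- (nA + nB) / r
  # pooled monomorphic sites are removed
  pbar <- ifelse(nA + nB > 0, (nA * pA + nB * pB) / (r * nbar), NA_real_)
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1 & nA >= 1 & nB >= 1 & nbar > 1
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  keep <- poly & !is.na(denom) & denom != 0
  theta <- a[keep] / denom[keep]
  out <- data.frame(chrom = gm$chrom[keep], pos = gm$pos[keep],
                    a = a[keep], b = b[keep], c = cc[keep],
                    theta = theta, theta_clamped = pmax(theta, 0))
  structure(out, class = c("fst_components", "data.frame"),
            fst_report = list(n_input = n_snps(gm),
                              n_monomorphic_removed = sum(!poly),
                              n_zero_denom = sum(poly & !keep),
                              n_kept = sum(keep)),
            contigs = gm$contigs, popA = paste(popA, collapse = "+"),
            popB = paste(popB, collapse = "+"))
}

#' Windowed F_ST (ratio of sums)
#'
#' Per window, the weighted Weir-Cockerham estimate
#' sum(a) / sum(a + b + c) over in-window SNPs, clamped at 0. Windows
#' without SNPs are flagged missing (\code{NA}).
#'
#' @param fst output of [wc_fst()].
#' @param window_bp,step_bp sliding-window geometry (defaults 100 kb /
#'   10 kb).
#' @param contigs named chromosome lengths; defaults to the attribute
#'   carried by `fst`.
#' @return a \code{score_track} with \code{score} = windowed F_ST.
#' @export
windowed_fst <- function(fst, window_bp = 1e5, step_bp = 1e4,
                         contigs = NULL) {
  contigs <- contigs %||% attr(fst, "contigs")
  if (is.null(contigs))
    contigs <- tapply(fst$pos, fst$chrom, max)
  res <- list()
  for (ch in names(contigs)) {
    L <- contigs[[ch]]
    starts <- seq(0, max(0, L - 1), by = step_bp)
    ends <- pmin(starts + window_bp, L)
    onch <- fst[fst$chrom == ch, , drop = FALSE]
    score <- rep(NA_real_, length(starts)); nsnp <- integer(length(starts))
    for (i in seq_along(starts)) {
      inw <- onch$pos > starts[i] & onch$pos <= ends[i]
      if (!any(inw)) next
      num <- sum(onch$a[inw])
      den <- sum(onch$a[inw] + onch$b[inw] + onch$c[inw])
      score[i] <- if (den != 0) max(0, num / den) else NA_real_
      nsnp[i] <- sum(inw)
    }
    res[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            focal = (starts + ends) / 2, n_snps = nsnp,
                            score = score, sigma_hat = NA_real_,
                            partial = (ends - starts) < window_bp)
  }
  track <- do.call(rbind, res)
  rownames(track) <- NULL
  structure(track, class = c("score_track", "data.frame"),
            stat = "fst", contigs = contigs)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per SNP site, pi_site = 2 n_alt n_ref / (n (n - 1)) with n the
#' non-missing allele count in the population; per window,
#' pi = sum(pi_site) / window width (monomorphic and unobserved sites
#' contribute 0).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map.
#' @param pop subpopulation label(s).
#' @param window_bp,step_bp sliding-window geometry.
#' @return a \code{score_track} with \code{score} = per-bp diversity.
#' @export
nucleotide_diversity <- function(gm, popmap, pop, window_bp = 1e5,
                                 step_bp = 1e4) {
  s <- intersect(pop_samples(popmap, pop), samples(gm))
  if (!length(s)) stopf("empty population sample set")
  g <- gm$geno[, s, drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  k <- rowSums(g, na.rm = TRUE)
  pi_site <- ifelse(n >= 2, 2 * k * (n - k) / (n * (n - 1)), NA_real_)
  res <- list()
  for (ch in names(gm$contigs)) {
    L <- gm$contigs[[ch]]
    starts <- seq(0, max(0, L - 1), by = step_bp)
    ends <- pmin(starts + window_bp, L)
    onch <- which(gm$chrom == ch)
    pos <- gm$pos[onch]; ps <- pi_site[onch]
    score <- numeric(length(starts)); nsnp <- integer(length(starts))
    for (i in seq_along(starts)) {
      inw <- pos > starts[i] & pos <= ends[i]
      vals <- ps[inw]
      if (length(vals) && all(is.na(vals))) {
        score[i] <- NA_real_   # sites present but unobserved in this pop
      } else {
        score[i] <- sum(vals, na.rm = TRUE) / (ends[i] - starts[i])
      }
      nsnp[i] <- sum(inw)
    }
    res[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            focal = (starts + ends) / 2, n_snps = nsnp,
                            score = score, sigma_hat = NA_real_,
                            partial = (ends - starts) < window_bp)
  }
  track <- do.call(rbind, res)
  rownames(track) <- NULL
  structure(track, class = c("score_track", "data.frame"),
            stat = "pi", contigs = gm$contigs, pop = paste(pop, collapse = "+"))
}

#' Mean of a per-SNP statistic over intervals
#'
#' Arithmetic mean of per-SNP values whose 1-based position falls inside
#' each 0-based half-open interval. Intervals without SNPs are flagged
#' missing (\code{NA}), never 0.
#'
#' @param stat data.frame with chrom, pos and a value column (e.g.
#'   \code{theta_clamped} from [wc_fst()]).
#' @param intervals interval data.frame (chrom, start, end, name).
#' @param value name of the value column (default "theta_clamped").
#' @return `intervals` with columns \code{mean_value} and \code{n_snps}.
#' @export
mean_stat_over_intervals <- function(stat, intervals,
                                     value = "theta_clamped") {
  stopifnot(value %in% names(stat))
  out <- intervals
  out$mean_value <- NA_real_
  out$n_snps <- 0L
  for (i in seq_len(nrow(intervals))) {
    inw <- stat$chrom == intervals$chrom[i] &
      stat$pos > intervals$start[i] & stat$pos <= intervals$end[i]
    if (any(inw)) {
      out$mean_value[i] <- mean(stat[[value]][inw])
      out$n_snps[i] <- sum(inw)
    }
  }
  out
}
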