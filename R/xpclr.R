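# Cross-population composite likelihood ratio (XP-CLR) sweep scan.
#
# Model: reference-population frequency p1 is observed; the test
# population's frequency drifts around p1 with variance omega * p1(1-p1)
# (Normal kernel censored to [0,1], tail mass as point masses at the
# bounds). Under a sweep of scale sigma_s centred at the window focal
# point, a SNP at genetic distance d escapes with probability
# c = 1 - exp(-d / sigma_s). With probability 1 - c the SNP hitchhikes:
# conditional on the (unobserved) allelic background that carried the
# beneficial mutation, its frequency is dragged to fixation of the alt
# (prior weight p1) or ref (weight 1 - p1) allele, with residual drift
# spread omega * p1(1-p1) around the fixed bound; with probability c it
# escapes and follows the neutral kernel unchanged. This is the same
# escape-event mixture the sweep injector of the fixtures module
# generates, so the scan statistic is the likelihood ratio of the
# generative model. Per-SNP likelihoods integrate the binomial sampling
# of the observed test-population allele counts over the kernel by
# fixed-node Gauss-Legendre quadrature; the window statistic is twice
# the LD-weighted composite log-likelihood ratio maximized over a
# sigma_s grid, with the neutral model always a candidate (c = 1
# recovers it exactly, so scores are non-negative).

#' Scan parameters for the XP-CLR sliding-window scan
#'
#' @param window_bp window length in bp (default 100000).
#' @param step_bp step between window starts (default 10000).
#' @param max_snps_per_window cap on SNPs scored per window (default
#'   200); larger windows are thinned to an evenly index-spaced subset.
#' @param corr_threshold genotype |r| above which two SNPs share an LD
#'   group for down-weighting (default 0.95).
#' @param sigma_grid grid of sweep scales sigma_s in Morgans; default 20
#'   log-spaced values from 1e-3 to 0.5. The lower end is the smallest
#'   scale a window with a central focal point can resolve (at
#'   sigma = 1e-3 a SNP at the 50-kb window edge still hitchhikes with
#'   probability ~0.6); sub-window scales would let a window explain
#'   only its central SNPs and mark the rest neutral, which destroys
#'   localization. The exact neutral model is always a candidate in the
#'   maximization regardless of the grid, so scores are non-negative.
#' @param recomb_rate_default cM/Mb used when no genetic map is supplied
#'   (default 1.0).
#' @param n_quad_nodes Gauss-Legendre nodes on (0,1) (default 60).
#' @param sweep_resid_frac residual drift of a hitchhiked lineage
#'   around its fixation bound, as a fraction of omega (default 0.05;
#'   a recent sweep leaves little post-sweep drift).
#' @return list of class \code{scan_params}.
#' @export
scan_params <- function(window_bp = 1e5, step_bp = 1e4,
                        max_snps_per_window = 200, corr_threshold = 0.95,
                        sigma_grid = exp(seq(log(1e-3), log(0.5),
                                             length.out = 20)),
                        recomb_rate_default = 1.0, n_quad_nodes = 60,
                        sweep_resid_frac = 0.05) {
  if (!(window_bp >= step_bp && step_bp > 0))
    stopf("need window_bp >= step_bp > 0")
  if (max_snps_per_window < 1) stopf("max_snps_per_window must be >= 1")
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 max_snps_per_window = max_snps_per_window,
                 corr_threshold = corr_threshold,
                 sigma_grid = sort(sigma_grid),
                 recomb_rate_default = recomb_rate_default,
                 n_quad_nodes = n_quad_nodes,
                 sweep_resid_frac = sweep_resid_frac),
            class = "scan_params")
}

#' Estimate the genome-wide drift variance coefficient omega
#'
#' omega scales the expected squared allele-frequency divergence of the
#' test population around the reference: Var(p2 | p1) = omega * p1(1-p1).
#' The estimator is the mean of (p1 - p2)^2 / (p1 (1 - p1)) over SNPs
#' polymorphic in the reference population. Because the denominator is
#' evaluated at the observed reference frequency, SNPs with p1 close to
#' a boundary make the ratio explode and bias the mean upward; the
#' estimator therefore restricts to reference frequencies inside
#' `p1_range` (default [0.05, 0.95], the same margin as the usual MAF
#' filter).
#'
#' @param p1 reference-population allele frequencies.
#' @param p2 test-population allele frequencies.
#' @param min_snps minimum usable SNPs (default 100).
#' @param p1_range closed interval of usable reference frequencies.
#' @return list of class \code{omega_estimate}: omega, n_snps_used.
#' @export
estimate_omega <- function(p1, p2, min_snps = 100,
                           p1_range = c(0.05, 0.95)) {
  stopifnot(length(p1) == length(p2))
  use <- !is.na(p1) & !is.na(p2) & p1 > 0 & p1 < 1 &
    p1 >= p1_range[1] & p1 <= p1_range[2]
  if (sum(use) < min_snps)
    stopf("omega calibration needs >= %d usable SNPs (have %d)",
          min_snps, sum(use))
  w <- (p1[use] - p2[use])^2 / (p1[use] * (1 - p1[use]))
  structure(list(omega = mean(w), n_snps_used = sum(use)),
            class = "omega_estimate")
}

#' LD down-weighting and window SNP thinning
#'
#' Each SNP j gets weight 1/k_j, where k_j counts the window SNPs
#' (including j) whose genotype correlation |r| with j exceeds
#' `corr_threshold` in the reference population. If the window holds more
#' than `max_snps` SNPs, an evenly index-spaced subset of exactly
#' `max_snps` is scored.
#'
#' @param g_ref reference-population genotype matrix (individuals x SNPs)
#'   restricted to the window.
#' @param corr_threshold |r| threshold.
#' @param max_snps SNP cap.
#' @return list: \code{idx} (column indices retained) and \code{w}
#'   (weights, one per retained SNP).
#' @export
ld_weights <- function(g_ref, corr_threshold = 0.95, max_snps = 200) {
  m <- ncol(g_ref)
  stopifnot(m >= 1)
  idx <- seq_len(m)
  if (m > max_snps)
    idx <- unique(round(seq(1, m, length.out = max_snps)))
  g <- g_ref[, idx, drop = FALSE]
  if (ncol(g) == 1L) return(list(idx = idx, w = 1))
  r <- suppressWarnings(
    if (anyNA(g)) stats::cor(g, use = "pairwise.complete.obs")
    else stats::cor(g))
  r[is.na(r)] <- 0
  diag(r) <- 1
  k <- rowSums(abs(r) > corr_threshold)
  list(idx = idx, w = 1 / k)
}

# Integral of Binom(k2; n2, p) against a Normal(mu, sd) kernel censored
# to [0,1] (point masses at the bounds). All arguments vectors of equal
# length except the quadrature rule. Returns the likelihood (not log).
tn_binom_integral <- function(mu, sd, k2, n2, quad) {
  L <- numeric(length(mu))
  # kernels narrower than the quadrature can resolve collapse to a
  # point mass at mu (the binomial factor varies on a much wider scale)
  deg <- sd <= 1e-3
  if (any(deg)) {
    mpin <- pmin(1, pmax(0, mu[deg]))
    L[deg] <- stats::dbinom(k2[deg], n2[deg], mpin)
  }
  if (any(!deg)) {
    i <- which(!deg)
    x <- quad$nodes; w <- quad$weights
    Z <- outer(x, mu[i], "-") / rep(sd[i], each = length(x))
    phi <- exp(-0.5 * Z * Z) / (sqrt(2 * pi) * rep(sd[i], each = length(x)))
    B <- matrix(vapply(x, function(xi) stats::dbinom(k2[i], n2[i], xi),
                       numeric(length(i))), nrow = length(i))
    # B is (snps x nodes); phi is (nodes x snps)
    L[i] <- colSums(phi * t(B) * w)
    L[i] <- L[i] +
      stats::pnorm(0, mu[i], sd[i]) * stats::dbinom(k2[i], n2[i], 0) +
      stats::pnorm(1, mu[i], sd[i], lower.tail = FALSE) *
        stats::dbinom(k2[i], n2[i], 1)
  }
  L
}

# Sigma-independent per-SNP likelihood pieces: neutral integral and the
# two hitchhiked-background integrals (kernel mean at the alt / ref
# fixation bound). A hitchhiked lineage has been dragged to fixation
# recently, so its residual drift spread is a small fraction
# `resid_frac` of the full divergence omega, not omega itself.
# Returns a list of vectors.
sweep_lik_pieces <- function(p1, k2, n2, omega, quad, resid_frac = 0.05) {
  v <- p1 * (1 - p1)
  sd <- sqrt(omega * v)
  sdf <- sqrt(resid_frac * omega * v)
  list(neu = tn_binom_integral(p1, sd, k2, n2, quad),
       fix1 = tn_binom_integral(rep(1, length(p1)), sdf, k2, n2, quad),
       fix0 = tn_binom_integral(rep(0, length(p1)), sdf, k2, n2, quad))
}

#' Per-SNP log-likelihoods under the neutral and sweep models
#'
#' Neutral: the censored-Normal drift kernel around p1 integrated
#' against the binomial sampling of the test-population counts.
#' Selected: the escape-event mixture
#' \deqn{L = (1-c) [p1 L_{fix(1)} + (1-p1) L_{fix(0)}] + c L_{neutral}}
#' where the fixation components use the same drift kernel centred at
#' the swept bound. At c = 1 the two models coincide exactly.
#'
#' @param p1 reference allele frequency (vector).
#' @param k2 observed alt allele count in the test population.
#' @param n2 number of sampled test alleles (2 x non-missing diploids).
#' @param omega drift variance coefficient.
#' @param c escape probability per SNP (vector, same length).
#' @param n_nodes Gauss-Legendre node count (default 60).
#' @param resid_frac residual drift fraction of the hitchhiked
#'   components (see [scan_params()]).
#' @return list with \code{neutral} and \code{selected} natural-log
#'   likelihood vectors. SNPs with \code{n2 == 0} return \code{NA}.
#' @export
snp_loglikelihoods <- function(p1, k2, n2, omega, c, n_nodes = 60,
                               resid_frac = 0.05) {
  m <- length(p1)
  stopifnot(length(k2) == m, length(n2) == m, length(c) == m)
  quad <- gauss_legendre(n_nodes)
  ok <- n2 > 0
  neu <- sel <- rep(NA_real_, m)
  if (any(ok)) {
    pc <- sweep_lik_pieces(p1[ok], k2[ok], n2[ok], omega, quad, resid_frac)
    Ls <- (1 - c[ok]) * (p1[ok] * pc$fix1 + (1 - p1[ok]) * pc$fix0) +
      c[ok] * pc$neu
    neu[ok] <- log(pmax(pc$neu, 1e-300))
    sel[ok] <- log(pmax(Ls, 1e-300))
  }
  list(neutral = neu, selected = sel)
}

#' Score one window
#'
#' Twice the LD-weighted composite log-likelihood ratio, maximized over
#' the sigma_s grid (the neutral model is always a candidate, so the
#' score is non-negative).
#'
#' @param p1,k2,n2 per-SNP reference frequency and test-population alt
#'   allele count / allele total for the window's usable SNPs.
#' @param d genetic distance (Morgans) of each SNP from the window focal
#'   point.
#' @param w LD weights (from [ld_weights()]).
#' @param omega drift coefficient.
#' @param params a [scan_params()].
#' @param pieces optional precomputed per-SNP likelihood components (an
#'   internal cache used by [xpclr_scan()]).
#' @param .force_c testing hook: a fixed escape probability overriding
#'   the distance model for every SNP and sigma.
#' @return list: score, sigma_hat (NA when the neutral model wins),
#'   n_snps.
#' @export
window_score <- function(p1, k2, n2, d, w, omega, params = scan_params(),
                         pieces = NULL, .force_c = NULL) {
  m <- length(p1)
  stopifnot(m >= 1)
  if (any(p1 <= 0) || any(p1 >= 1) || any(n2 <= 0))
    stopf("window_score expects usable SNPs (p1 in (0,1), n2 > 0)")
  if (is.null(pieces))
    pieces <- sweep_lik_pieces(p1, k2, n2, omega,
                               gauss_legendre(params$n_quad_nodes),
                               params$sweep_resid_frac)
  lneu <- log(pmax(pieces$neu, 1e-300))
  sig <- params$sigma_grid
  cmat <- if (is.null(.force_c)) 1 - exp(-outer(d, sig, "/")) else
    matrix(.force_c, m, length(sig))
  hh <- p1 * pieces$fix1 + (1 - p1) * pieces$fix0
  Lsel <- (1 - cmat) * hh + cmat * pieces$neu
  stat <- colSums(w * (log(pmax(Lsel, 1e-300)) - lneu))
  k <- which.max(stat)
  if (length(stat) && stat[k] > 0)
    list(score = 2 * stat[k], sigma_hat = sig[k], n_snps = m)
  else
    list(score = 0, sigma_hat = NA_real_, n_snps = m)
}

# interpolate genetic position (Morgans) at bp using a genetic map
# (data.frame chrom, bp, cM); linear in bp, constant-rate extrapolation
# by rule = 2 endpoints.
genetic_pos <- function(chrom, bp, gmap, rate_default) {
  if (is.null(gmap)) return(bp * rate_default * 1e-8)
  gi <- gmap[gmap$chrom == chrom, , drop = FALSE]
  if (nrow(gi) < 2L) return(bp * rate_default * 1e-8)
  stats::approx(gi$bp, gi$cM, xout = bp, rule = 2)$y / 100
}

#' XP-CLR sliding-window scan
#'
#' Tiles each chromosome with windows of `window_bp` starting every
#' `step_bp` from 0 (the trailing partial windows are kept and flagged),
#' estimates omega once genome-wide from reference-polymorphic SNPs, and
#' scores every window. Scores are directional: scanning (A vs B) and
#' (B vs A) are different analyses.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param popmap population map.
#' @param test,ref test and reference subpopulation labels (their sample
#'   sets must be disjoint).
#' @param params a [scan_params()].
#' @param gmap optional genetic map: data.frame(chrom, bp, cM).
#' @param omega optional fixed drift coefficient overriding the
#'   genome-wide estimate (useful when an external calibration is more
#'   trustworthy than the scanned region, e.g. small fixtures where a
#'   sweep spans much of the sequence).
#' @param .force_c testing hook passed through to [window_score()].
#' @return a \code{score_track} data.frame: chrom, start, end, focal,
#'   n_snps, score, sigma_hat, partial; attributes \code{omega},
#'   \code{test}, \code{ref}, \code{stat = "xpclr"}. Windows without
#'   usable SNPs have \code{NA} score.
#' @export
xpclr_scan <- function(gm, popmap, test, ref, params = scan_params(),
                       gmap = NULL, omega = NULL, .force_c = NULL) {
  s_test <- pop_samples(popmap, test)
  s_ref <- pop_samples(popmap, ref)
  if (length(intersect(s_test, s_ref)))
    stopf("test and reference populations share samples")
  s_test <- intersect(s_test, samples(gm))
  s_ref <- intersect(s_ref, samples(gm))
  if (!length(s_test) || !length(s_ref))
    stopf("test/reference samples absent from genotype matrix")
  fr_ref <- allele_frequencies(gm, s_ref)
  fr_test <- allele_frequencies(gm, s_test)
  om <- if (is.null(omega)) estimate_omega(fr_ref$p, fr_test$p) else
    structure(list(omega = omega, n_snps_used = NA_integer_),
              class = "omega_estimate")
  quadn <- params$n_quad_nodes
  g_test <- gm$geno[, s_test, drop = FALSE]
  k2_all <- rowSums(g_test, na.rm = TRUE)
  n2_all <- 2L * rowSums(!is.na(g_test))
  usable <- !is.na(fr_ref$p) & fr_ref$p > 0 & fr_ref$p < 1 & n2_all > 0
  quad <- gauss_legendre(quadn)
  pieces_all <- list(neu = rep(NA_real_, n_snps(gm)),
                     fix1 = rep(NA_real_, n_snps(gm)),
                     fix0 = rep(NA_real_, n_snps(gm)))
  pc <- sweep_lik_pieces(fr_ref$p[usable], k2_all[usable], n2_all[usable],
                         om$omega, quad, params$sweep_resid_frac)
  pieces_all$neu[usable] <- pc$neu
  pieces_all$fix1[usable] <- pc$fix1
  pieces_all$fix0[usable] <- pc$fix0

  res <- list()
  for (ch in names(gm$contigs)) {
    L <- gm$contigs[[ch]]
    starts <- seq(0, max(0, L - 1), by = params$step_bp)
    ends <- pmin(starts + params$window_bp, L)
    onch <- which(gm$chrom == ch & usable)
    pos <- gm$pos[onch]
    cm <- genetic_pos(ch, pos, gmap, params$recomb_rate_default)
    nwin <- length(starts)
    score <- rep(NA_real_, nwin); sig <- rep(NA_real_, nwin)
    nsnp <- integer(nwin)
    for (i in seq_len(nwin)) {
      # SNP pos is 1-based: pos-1 in [start, end)
      inw <- onch[pos > starts[i] & pos <= ends[i]]
      if (!length(inw)) next
      g_ref_w <- t(gm$geno[inw, s_ref, drop = FALSE])
      lw <- ld_weights(g_ref_w, params$corr_threshold,
                       params$max_snps_per_window)
      sel <- inw[lw$idx]
      focal <- (starts[i] + ends[i]) / 2
      dcm <- genetic_pos(ch, gm$pos[sel], gmap, params$recomb_rate_default)
      dfoc <- genetic_pos(ch, focal, gmap, params$recomb_rate_default)
      ws <- window_score(fr_ref$p[sel], k2_all[sel], n2_all[sel],
                         abs(dcm - dfoc), lw$w, om$omega, params,
                         pieces = list(neu = pieces_all$neu[sel],
                                       fix1 = pieces_all$fix1[sel],
                                       fix0 = pieces_all$fix0[sel]),
                         .force_c = .force_c)
      score[i] <- ws$score; sig[i] <- ws$sigma_hat; nsnp[i] <- ws$n_snps
    }
    res[[ch]] <- data.frame(
      chrom = ch, start = starts, end = ends,
      focal = (starts + ends) / 2, n_snps = nsnp,
      score = score, sigma_hat = sig,
      partial = (ends - starts) < params$window_bp)
  }
  track <- do.call(rbind, res)
  rownames(track) <- NULL
  structure(track, class = c("score_track", "data.frame"),
            omega = om, test = test, ref = ref, stat = "xpclr",
            contigs = gm$contigs, params = params)
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track:%s> %d windows, %d chromosome(s)%s\n",
              attr(x, "stat") %||% "?", nrow(x),
              length(unique(x$chrom)),
              if (!is.null(attr(x, "test")))
                sprintf(", %s vs %s", attr(x, "test"), attr(x, "ref"))
              else ""))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write a score track as TSV
#'
#' Stable column order chrom, start, end, focal_bp, n_snps, score,
#' sigma_hat; missing values written as "NA".
#' @param track a score_track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  out <- data.frame(chrom = track$chrom, start = track$start,
                    end = track$end, focal_bp = track$focal,
                    n_snps = track$n_snps, score = track$score,
                    sigma_hat = track$sigma_hat)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
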