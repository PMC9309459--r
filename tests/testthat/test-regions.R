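# Selected-region calling: cutoffs, masking, merging, consensus,
# summaries.

mk_track <- function(scores, chrom = "chr1", window = 1e5, step = 1e4) {
  n <- length(scores)
  starts <- seq(0, by = step, length.out = n)
  structure(data.frame(chrom = chrom, start = starts,
                       end = starts + window,
                       focal = starts + window / 2, n_snps = 10L,
                       score = scores, sigma_hat = NA_real_,
                       partial = FALSE),
            class = c("score_track", "data.frame"))
}

test_that("percentile_cutoff averages per-comparison 99th percentiles", {
  t1 <- mk_track(rep(100, 200)); t1$score[1] <- 250
  t2 <- mk_track(rep(100, 200)); t2$score[1] <- 350
  # degenerate single comparison: cutoff is its own q99
  c1 <- percentile_cutoff(list(a = t1))
  expect_equal(unname(c1$cutoff), unname(c1$per_comparison["a"]))
  # linear-interpolation percentile on 1..1000 and hand oracle
  tt <- mk_track(1:1000)
  ct <- percentile_cutoff(list(x = tt))
  expect_equal(unname(ct$per_comparison["x"]), 990.01)
  expect_equal(unname(ct$per_comparison["x"]),
               percentile_oracle(1:1000, 99))
  # mean across a subpopulation's comparisons
  q1 <- percentile_cutoff(list(a = t1))$per_comparison["a"]
  q2 <- percentile_cutoff(list(b = t2))$per_comparison["b"]
  both <- percentile_cutoff(list(a = t1, b = t2),
                            subpop_of = c(a = "S", b = "S"))
  expect_equal(unname(both$cutoff["S"]), mean(c(q1, q2)))
})

test_that("mask_centromeres blanks overlapping windows", {
  tr <- mk_track(rep(5, 50))
  mask <- data.frame(chrom = "chr1", start = 1.05e6, end = 1.25e6,
                     name = "cen")
  # window [1.0, 1.1) Mb overlaps mask [1.05, 1.25) Mb
  tr2 <- rbind(tr, tr[1, ])
  tr2$start[51] <- 1.0e6; tr2$end[51] <- 1.1e6
  out <- mask_centromeres(tr2, mask)
  expect_true(is.na(out$score[51]))
  expect_equal(sum(is.na(out$score)), 1L)
  expect_identical(mask_centromeres(tr, mask[0, ])$score, tr$score)
  # tiling arithmetic: a 200-kb mask on a 100-kb/10-kb grid removes
  # (200 + 100)/10 - 1 = 29 windows (all starts in (cen_start - 100k,
  # cen_end))
  big <- mk_track(rep(5, 300))
  cen <- data.frame(chrom = "chr1", start = 1e6, end = 1.2e6)
  mb <- mask_centromeres(big, cen)
  expect_equal(sum(is.na(mb$score)), 29L)
})

test_that("call_regions merges by gap and enforces minimum length", {
  params <- region_call_params()
  # single qualifying window -> one region of 100 kb (kept)
  tr <- mk_track(rep(0, 100)); tr$score[1] <- 10
  r1 <- call_regions(tr, cutoff = 5, params)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$end - r1$start, 1e5)
  # windows [0,100k) and [190k,290k): gap 90 kb <= 100 kb -> merged
  tr$score[] <- 0; tr$score[c(1, 20)] <- 10
  r2 <- call_regions(tr, 5, params)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(0, 290000))
  # windows [0,100k) and [210k,310k): gap 110 kb -> two regions
  tr$score[] <- 0; tr$score[c(1, 22)] <- 10
  r3 <- call_regions(tr, 5, params)
  expect_equal(nrow(r3), 2L)
  # strict inequality at the threshold
  tr$score[] <- 0; tr$score[1] <- 5
  expect_equal(nrow(call_regions(tr, 5, params)), 0L)
  # max score recorded
  tr$score[] <- 0; tr$score[1:3] <- c(6, 9, 7)
  expect_equal(call_regions(tr, 5, params)$max_score, 9)
})

test_that("call_regions is invariant to window order", {
  tr <- mk_track(c(rep(0, 40), rep(9, 5), rep(0, 55)))
  shuf <- tr[sample(nrow(tr)), ]
  expect_equal(call_regions(tr, 5)[, c("chrom", "start", "end")],
               call_regions(shuf, 5)[, c("chrom", "start", "end")])
})

test_that("raising the cutoff never grows the selected length", {
  set.seed(40)
  tr <- mk_track(rexp(500, 1 / 50))
  tot <- vapply(c(20, 50, 100, 200), function(ct)
    sum(with(call_regions(tr, ct), end - start)), numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("consensus keeps bases supported by min_support comparisons", {
  reg <- function(s, e) structure(
    data.frame(chrom = "chr1", start = s, end = e,
               name = sprintf("r%d", seq_along(s))),
    class = c("region_set", "data.frame"))
  sets <- list(c1 = reg(0, 3e5), c2 = reg(0, 3e5), c3 = reg(0, 3e5),
               c4 = reg(5e6, 5.4e6))
  p3 <- region_call_params(min_support = 3)
  out <- consensus_regions(sets, p3)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(0, 3e5))
  expect_equal(out$n_support, 3L)
  expect_setequal(strsplit(out$support, ",")[[1]], c("c1", "c2", "c3"))
  # present in only 2 of 4 -> absent
  sets2 <- list(c1 = reg(0, 3e5), c2 = reg(0, 3e5),
                c3 = reg(5e6, 5.4e6), c4 = reg(7e6, 7.4e6))
  expect_equal(nrow(consensus_regions(sets2, p3)), 0L)
  # staggered overlaps: depth >= 3 exactly on [200k, 300k), kept (100 kb)
  sets3 <- list(c1 = reg(0, 3e5), c2 = reg(1e5, 4e5), c3 = reg(2e5, 5e5))
  out3 <- consensus_regions(sets3, p3)
  expect_equal(nrow(out3), 1L)
  expect_equal(c(out3$start, out3$end), c(2e5, 3e5))
  expect_error(consensus_regions(sets3, region_call_params(min_support = 4)),
               "exceeds")
})

test_that("consensus bounds: union at support 1, intersection at n", {
  reg <- function(s, e) structure(
    data.frame(chrom = "chr1", start = s, end = e,
               name = sprintf("r%d", seq_along(s))),
    class = c("region_set", "data.frame"))
  sets <- list(a = reg(c(0, 4e5), c(1e5, 5e5)), b = reg(5e4, 2e5),
               c = reg(8e4, 1.5e5))
  p0 <- region_call_params(min_support = 1, merge_gap_bp = 0,
                           min_len_bp = 0)
  uni <- consensus_regions(sets, p0)   # union: [0, 2e5) and [4e5, 5e5)
  expect_equal(uni$start, c(0, 4e5))
  expect_equal(uni$end, c(2e5, 5e5))
  pN <- region_call_params(min_support = 3, merge_gap_bp = 0,
                           min_len_bp = 0)
  inter <- consensus_regions(sets, pN)
  expect_equal(c(inter$start, inter$end), c(8e4, 1e5))
})

test_that("region_summary reproduces per-subpopulation table arithmetic", {
  genome <- 373245519
  # 52 regions totalling 30,352,734 bp -> mean 583,706 and 8.1%
  s1 <- region_summary(genome_bp = genome, total_bp = 30352734,
                       n_regions = 52)
  expect_equal(s1$mean_length, 583706)
  expect_equal(s1$pct_genome, 8.1)
  # 28 regions totalling 16,147,785 bp -> mean 576,707 and 4.3%
  s2 <- region_summary(genome_bp = genome, total_bp = 16147785,
                       n_regions = 28)
  expect_equal(s2$mean_length, 576707)
  expect_equal(s2$pct_genome, 4.3)
  # trivial arithmetic and the empty set
  s3 <- region_summary(genome_bp = 1e6, total_bp = 1e5, n_regions = 1)
  expect_equal(s3$mean_length, 1e5)
  expect_equal(s3$pct_genome, 10.0)
  empty <- structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric()),
                     class = c("region_set", "data.frame"))
  s4 <- region_summary(empty, genome_bp = 1e6)
  expect_equal(s4$n_regions, 0)
  expect_equal(s4$total_length, 0)
})
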