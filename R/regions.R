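# Selected-region calling: percentile cutoffs, centromere masking,
# per-comparison calls, cross-comparison consensus, summaries.

#' Region-calling parameters
#'
#' @param merge_gap_bp qualifying windows/regions closer than or equal
#'   to this gap are merged (default 100000).
#' @param min_len_bp merged regions shorter than this are removed
#'   (default 80000); re-applied after consensus.
#' @param min_support number of pairwise comparisons that must support a
#'   base for it to enter the consensus (3 for Indica-style groups, 2
#'   for Japonica-style groups).
#' @return list of class \code{region_call_params}.
#' @export
region_call_params <- function(merge_gap_bp = 1e5, min_len_bp = 8e4,
                               min_support = 2) {
  stopifnot(merge_gap_bp >= 0, min_len_bp >= 0, min_support >= 1)
  structure(list(merge_gap_bp = merge_gap_bp, min_len_bp = min_len_bp,
                 min_support = min_support), class = "region_call_params")
}

#' Percentile score cutoffs per comparison and subpopulation
#'
#' The q-th percentile (linear interpolation between order statistics)
#' of each comparison's non-missing window scores; a subpopulation's
#' cutoff is the arithmetic mean of the q-th percentiles of its
#' comparisons.
#'
#' @param tracks named list of score tracks (names identify the
#'   comparisons, e.g. \code{"I5_vs_I1"}).
#' @param subpop_of optional named character vector mapping track name
#'   to the subpopulation it belongs to (its test population); when
#'   \code{NULL} all tracks form one group named \code{"all"}.
#' @param q percentile (default 99).
#' @return list of class \code{cutoff_spec}: \code{per_comparison}
#'   (named q-th percentiles), \code{cutoff} (named per-subpopulation
#'   means), \code{q}.
#' @export
percentile_cutoff <- function(tracks, subpop_of = NULL, q = 99) {
  stopifnot(length(tracks) >= 1)
  if (is.null(names(tracks)))
    names(tracks) <- sprintf("cmp%d", seq_along(tracks))
  q99 <- vapply(tracks, function(tr) pctl(tr$score, q), numeric(1))
  drop <- is.na(q99)
  if (any(drop)) {
    warnf("track(s) with all-missing scores excluded: %s",
          paste(names(tracks)[drop], collapse = ", "))
    q99 <- q99[!drop]
  }
  if (!length(q99)) stopf("no scoreable tracks")
  grp <- if (is.null(subpop_of)) rep("all", length(q99)) else
    unname(subpop_of[names(q99)])
  cutoff <- tapply(q99, grp, mean)
  structure(list(per_comparison = q99,
                 cutoff = stats::setNames(as.numeric(cutoff), names(cutoff)),
                 q = q), class = "cutoff_spec")
}

#' Mask centromeric windows in a score track
#'
#' Windows overlapping any mask interval get a missing score, excluding
#' them from percentile calibration and region calling.
#'
#' @param track a score track.
#' @param mask interval data.frame (e.g. 200-kb centromere intervals
#'   from a BED file).
#' @return the track with masked windows set to \code{NA}.
#' @export
mask_centromeres <- function(track, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(track)
  hit <- overlaps_any(track[, c("chrom", "start", "end")], mask)
  track$score[hit] <- NA_real_
  attr(track, "n_masked") <- sum(hit)
  track
}

#' Call selected regions from one comparison's track
#'
#' Windows scoring strictly above the cutoff become intervals; intervals
#' separated by at most `merge_gap_bp` are merged (overlapping windows
#' always are); merged regions shorter than `min_len_bp` are dropped.
#' The per-region maximum window score is recorded.
#'
#' @param track a score track (after any centromere masking).
#' @param cutoff scalar score cutoff (from [percentile_cutoff()]).
#' @param params a [region_call_params()].
#' @return a \code{region_set} data.frame: chrom, start, end, name,
#'   max_score, n_windows.
#' @export
call_regions <- function(track, cutoff, params = region_call_params()) {
  hit <- !is.na(track$score) & track$score > cutoff
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      max_score = numeric(), n_windows = integer())
  if (!any(hit))
    return(structure(empty, class = c("region_set", "data.frame")))
  iv <- track[hit, c("chrom", "start", "end"), drop = FALSE]
  merged <- merge_intervals(iv, gap = params$merge_gap_bp)
  merged <- merged[merged$end - merged$start >= params$min_len_bp, ,
                   drop = FALSE]
  if (nrow(merged) == 0L)
    return(structure(empty, class = c("region_set", "data.frame")))
  merged$name <- sprintf("r%03d", seq_len(nrow(merged)))
  merged$max_score <- NA_real_
  merged$n_windows <- 0L
  for (i in seq_len(nrow(merged))) {
    inw <- hit & track$chrom == merged$chrom[i] &
      track$start < merged$end[i] & track$end > merged$start[i]
    merged$max_score[i] <- max(track$score[inw])
    merged$n_windows[i] <- sum(inw)
  }
  rownames(merged) <- NULL
  structure(merged, class = c("region_set", "data.frame"))
}

#' Consensus regions across pairwise comparisons
#'
#' Computes per-base support depth across the per-comparison region
#' sets; bases supported by at least `min_support` comparisons are
#' retained, the resulting intervals are merged with the usual gap rule,
#' regions shorter than `min_len_bp` are removed, and each final region
#' records the comparisons overlapping it.
#'
#' @param region_sets named list of \code{region_set}s (one per
#'   comparison).
#' @param params a [region_call_params()] carrying \code{min_support}.
#' @return a \code{region_set} with columns \code{support} (comma-joined
#'   comparison names) and \code{n_support}.
#' @export
consensus_regions <- function(region_sets, params = region_call_params()) {
  if (params$min_support > length(region_sets))
    stopf("min_support (%d) exceeds number of comparisons (%d)",
          params$min_support, length(region_sets))
  if (is.null(names(region_sets)))
    names(region_sets) <- sprintf("cmp%d", seq_along(region_sets))
  deep <- depth_intervals(region_sets, params$min_support)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      support = character(), n_support = integer())
  if (nrow(deep) == 0L)
    return(structure(empty, class = c("region_set", "data.frame")))
  merged <- merge_intervals(deep, gap = params$merge_gap_bp)
  merged <- merged[merged$end - merged$start >= params$min_len_bp, ,
                   drop = FALSE]
  if (nrow(merged) == 0L)
    return(structure(empty, class = c("region_set", "data.frame")))
  merged$name <- sprintf("R%03d", seq_len(nrow(merged)))
  supp <- character(nrow(merged)); nsupp <- integer(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    who <- vapply(region_sets, function(rs)
      nrow(rs) > 0 && any(rs$chrom == merged$chrom[i] &
                            rs$start < merged$end[i] &
                            rs$end > merged$start[i]), logical(1))
    supp[i] <- paste(names(region_sets)[who], collapse = ",")
    nsupp[i] <- sum(who)
  }
  merged$support <- supp
  merged$n_support <- nsupp
  rownames(merged) <- NULL
  structure(merged, class = c("region_set", "data.frame"))
}

#' Summarize a selected-region set
#'
#' Region count, mean length (total / count rounded to the nearest
#' integer), total length, and percent of genome (one decimal place) --
#' the arithmetic of a per-subpopulation summary table row.
#'
#' @param regions a \code{region_set}, or \code{NULL} when giving
#'   `total_bp` and `n_regions` directly.
#' @param genome_bp genome size in bp.
#' @param total_bp,n_regions explicit totals (alternative input).
#' @return data.frame: n_regions, mean_length, total_length, pct_genome.
#' @export
region_summary <- function(regions = NULL, genome_bp, total_bp = NULL,
                           n_regions = NULL) {
  stopifnot(genome_bp > 0)
  if (!is.null(regions)) {
    n_regions <- nrow(regions)
    total_bp <- if (n_regions) sum(regions$end - regions$start) else 0
  }
  stopifnot(!is.null(total_bp), !is.null(n_regions))
  data.frame(
    n_regions = n_regions,
    mean_length = if (n_regions > 0) round(total_bp / n_regions) else 0,
    total_length = total_bp,
    pct_genome = round(100 * total_bp / genome_bp, 1))
}

#' Write a region set as BED6 plus a TSV provenance sidecar
#'
#' @param regions a \code{region_set}.
#' @param path BED output path; the sidecar gets \code{.provenance.tsv}
#'   appended to `path` without extension.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  score <- if ("max_score" %in% names(regions)) regions$max_score else 0
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.", regions$chrom,
                     as.integer(regions$start), as.integer(regions$end),
                     regions$name, format(score, trim = TRUE)), path)
  side <- sub("\\.bed$", "", path)
  utils::write.table(as.data.frame(regions),
                     paste0(side, ".provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d region(s), %s bp total\n", nrow(x),
              format(sum(x$end - x$start), big.mark = ",")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
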