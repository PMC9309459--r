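# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# --- interval algebra (0-based half-open, per chromosome) -------------------

# Merge intervals closer than or equal to `gap` bp (overlapping intervals are
# always merged). `x` is a data.frame with chrom/start/end; extra columns are
# dropped. Returns sorted disjoint intervals.
merge_intervals <- function(x, gap = 0L) {
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- vector("list", length(unique(x$chrom)))
  i <- 0L
  for (ch in unique(x$chrom)) {
    xi <- x[x$chrom == ch, , drop = FALSE]
    s <- xi$start; e <- xi$end
    ks <- s[1]; ke <- e[1]
    rs <- numeric(0); re <- numeric(0)
    if (nrow(xi) > 1L) {
      for (j in 2:nrow(xi)) {
        if (s[j] - ke <= gap) {
          ke <- max(ke, e[j])
        } else {
          rs <- c(rs, ks); re <- c(re, ke)
          ks <- s[j]; ke <- e[j]
        }
      }
    }
    rs <- c(rs, ks); re <- c(re, ke)
    i <- i + 1L
    out[[i]] <- data.frame(chrom = ch, start = rs, end = re)
  }
  do.call(rbind, out)
}

# Per-base support depth >= `min_depth` across a list of interval sets.
# Returns the maximal intervals where at least `min_depth` sets overlap.
depth_intervals <- function(sets, min_depth) {
  allx <- do.call(rbind, lapply(sets, function(s)
    s[, c("chrom", "start", "end"), drop = FALSE]))
  if (is.null(allx) || nrow(allx) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  out <- list()
  for (ch in unique(allx$chrom)) {
    xi <- allx[allx$chrom == ch, , drop = FALSE]
    ev <- data.frame(pos = c(xi$start, xi$end),
                     d = c(rep(1L, nrow(xi)), rep(-1L, nrow(xi))))
    ev <- ev[order(ev$pos, -ev$d), , drop = FALSE]
    pos <- unique(ev$pos)
    depth <- cumsum(ev$d)
    # depth on segment [pos_i, pos_{i+1}) is depth after all events at pos_i
    segd <- depth[!duplicated(ev$pos, fromLast = TRUE)]
    keep <- which(segd >= min_depth & pos < c(pos[-1], Inf))
    keep <- keep[keep < length(pos)]
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = pos[keep], end = pos[keep + 1L])
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  merge_intervals(do.call(rbind, out), gap = 0L)
}

# TRUE for each row of `x` overlapping any interval of `y` by >= 1 bp.
overlaps_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (is.null(y) || nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  res <- rep(FALSE, nrow(x))
  for (ch in unique(x$chrom)) {
    yi <- y[y$chrom == ch, , drop = FALSE]
    if (!nrow(yi)) next
    xi <- which(x$chrom == ch)
    for (i in xi)
      res[i] <- any(x$start[i] < yi$end & x$end[i] > yi$start)
  }
  res
}

# All overlapping pairs between interval frames x and y (>= 1 bp).
# Returns data.frame(xi, yi, overlap_bp).
overlap_pairs <- function(x, y) {
  out <- list()
  for (ch in unique(x$chrom)) {
    ix <- which(x$chrom == ch)
    iy <- which(y$chrom == ch)
    if (!length(ix) || !length(iy)) next
    for (i in ix) {
      o <- pmin(x$end[i], y$end[iy]) - pmax(x$start[i], y$start[iy])
      hit <- which(o > 0)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          xi = i, yi = iy[hit], overlap_bp = o[hit])
    }
  }
  if (!length(out))
    return(data.frame(xi = integer(), yi = integer(), overlap_bp = numeric()))
  do.call(rbind, out)
}

# --- Gauss-Legendre quadrature on (0, 1) ------------------------------------

# Golub-Welsch: nodes are eigenvalues of the symmetric tridiagonal Jacobi
# matrix; weights from the first eigenvector components.
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0.5, weights = 1))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  ord <- order(x)
  # map [-1, 1] -> [0, 1]
  list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
}

# Linear-interpolation percentile (type 7), ignoring NA.
pctl <- function(x, q) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  unname(stats::quantile(x, probs = q / 100, type = 7))
}
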