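# Independent brute-force oracles and small fixture builders. These are
# deliberately plain triple-loop implementations, written without reference to
# the package internals they check.

oracle_block_stats <- function(a, cv, half = 2) {
  d <- dim(a)
  vals <- c()
  for (x in max(1, cv[1] - half):min(d[1], cv[1] + half))
    for (y in max(1, cv[2] - half):min(d[2], cv[2] + half))
      for (z in max(1, cv[3] - half):min(d[3], cv[3] + half))
        vals <- c(vals, a[x, y, z])
  m <- sum(vals) / length(vals)
  c(m, sqrt(sum((vals - m)^2) / length(vals)))
}

oracle_abs_diff <- function(a, cv, step, offs) {
  d <- dim(a)
  tot <- 0
  for (i in seq_len(nrow(offs))) {
    nb <- cv + step * offs[i, ]
    nb <- pmin(pmax(nb, 1), d)
    tot <- tot + abs(a[cv[1], cv[2], cv[3]] - a[nb[1], nb[2], nb[3]])
  }
  tot / nrow(offs)
}

oracle_glcm <- function(blk, dir, n_levels) {
  d <- dim(blk)
  p <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    nb <- c(x, y, z) + dir
    if (nb[1] < 1 || nb[1] > d[1] || nb[2] < 1 || nb[2] > d[2] ||
        nb[3] < 1 || nb[3] > d[3]) next
    a <- blk[x, y, z] + 1; b <- blk[nb[1], nb[2], nb[3]] + 1
    p[a, b] <- p[a, b] + 1
    p[b, a] <- p[b, a] + 1
  }
  if (sum(p) > 0) p / sum(p) else p
}

oracle_glcm_props <- function(p) {
  n <- nrow(p)
  if (sum(p) == 0) return(c(0, 0, 0, 0))
  lv <- 0:(n - 1)
  contrast <- 0; energy <- 0; homog <- 0
  for (a in 1:n) for (b in 1:n) {
    contrast <- contrast + p[a, b] * (lv[a] - lv[b])^2
    energy <- energy + p[a, b]^2
    homog <- homog + p[a, b] / (1 + abs(lv[a] - lv[b]))
  }
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))
  corr <- 0
  if (sx * sy > 0) {
    for (a in 1:n) for (b in 1:n)
      corr <- corr + (lv[a] - mux) * (lv[b] - muy) * p[a, b]
    corr <- corr / (sx * sy)
  }
  c(contrast, corr, energy, homog)
}

# Full 57-feature oracle for one voxel of a volume, given the VOI used for
# normalization.
oracle_feature_row <- function(I, voi, cv, n_levels = 8, half = 2) {
  offs <- direction_offsets()
  vv <- I[voi]
  lo <- min(vv); hi <- max(vv)
  In <- if (hi - lo > 0) (I - lo) / (hi - lo) else array(0, dim(I))
  q <- pmin(floor(pmin(pmax(In, 0), 1) * n_levels), n_levels - 1)
  bs <- oracle_block_stats(In, cv, half)
  row <- c(In[cv[1], cv[2], cv[3]], bs[1], bs[2],
           oracle_abs_diff(In, cv, 1, offs), oracle_abs_diff(In, cv, 2, offs))
  d <- dim(I)
  xs <- max(1, cv[1] - half):min(d[1], cv[1] + half)
  ys <- max(1, cv[2] - half):min(d[2], cv[2] + half)
  zs <- max(1, cv[3] - half):min(d[3], cv[3] + half)
  blk <- array(q[xs, ys, zs], c(length(xs), length(ys), length(zs)))
  pr <- sapply(seq_len(nrow(offs)), function(i)
    oracle_glcm_props(oracle_glcm(blk, offs[i, ], n_levels)))
  c(row, pr[1, ], pr[2, ], pr[3, ], pr[4, ])
}

# Exhaustive best-path search for the scanline DP (tiny instances only).
oracle_best_path <- function(cost, lo, hi, delta) {
  nx <- nrow(cost); nz <- ncol(cost)
  best <- -Inf
  rec <- function(x, z, acc) {
    acc <- acc + cost[x, z]
    if (x == nx) { if (acc > best) best <<- acc; return(invisible()) }
    for (z2 in max(1, z - delta):min(nz, z + delta))
      if (z2 >= lo[x + 1] && z2 <= hi[x + 1]) rec(x + 1, z2, acc)
  }
  for (z in seq_len(nz)) if (z >= lo[1] && z <= hi[1]) rec(1, z, 0)
  best
}

# Direct double-loop bilateral filter over a whole slice.
oracle_bilateral <- function(img, ss, sr) {
  nx <- nrow(img); nz <- ncol(img)
  out <- img
  for (i in seq_len(nx)) for (j in seq_len(nz)) {
    w <- 0; v <- 0
    for (a in seq_len(nx)) for (b in seq_len(nz)) {
      wt <- exp(-((i - a)^2 + (j - b)^2) / (2 * ss^2)) *
            exp(-(img[i, j] - img[a, b])^2 / (2 * sr^2))
      w <- w + wt; v <- v + wt * img[a, b]
    }
    out[i, j] <- v / w
  }
  out
}

# Small, fast phantom configuration for pipeline-level tests.
small_phantom_config <- function(...) {
  phantom_config(nx = 64L, ny = 8L, nz = 112L,
                 disruption_radius_range = c(6, 10), ...)
}
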