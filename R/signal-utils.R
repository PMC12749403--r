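# Shared low-level signal helpers: extremum detection with prominence,
# sub-sample parabolic refinement, connected-component labelling.

# Indices of strict-ish local maxima (plateaus take the first sample).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  s <- sign(diff(y))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  # carry the previous nonzero slope sign through exact plateaus
  pos <- findInterval(seq_along(s), nz)
  s <- s[nz][pmax(pos, 1L)]
  which(diff(s) < 0) + 1L
}

# Topographic prominence of peaks at `idx` in `y`: height above the higher of
# the two key saddles (lowest point between the peak and the nearest
# higher-or-equal terrain, or the record edge).
peak_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    right <- if (i < length(y)) y[(i + 1L):length(y)] else numeric(0)
    lmin <- if (length(left)) {
      hi <- which(left > h) # strictly higher terrain bounds the saddle search
      min(left[seq.int(if (length(hi)) max(hi) else 1L, length(left))])
    } else h
    rmin <- if (length(right)) {
      hi <- which(right > h)
      min(right[seq_len(if (length(hi)) min(hi) else length(right))])
    } else h
    h - max(lmin, rmin)
  }, numeric(1))
}

# Detect local maxima with minimum prominence and minimum separation
# (samples). Peaks are accepted greedily from the most prominent down.
find_peaks <- function(y, min_prominence = 0, min_distance = 1L) {
  idx <- local_maxima(y)
  if (!length(idx)) return(integer(0))
  prom <- peak_prominence(y, idx)
  keep <- idx[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  ord <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(keep[i] - chosen) >= min_distance)) {
      chosen <- c(chosen, keep[i])
    }
  }
  sort(chosen)
}

# Quadratic (three-point parabola) vertex refinement of an extremum at sample
# index i; returns c(dt_offset_in_samples, refined_value).
parabolic_refine <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(c(0, y[i]))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  den <- a - 2 * b + c
  if (den == 0) return(c(0, b))
  off <- 0.5 * (a - c) / den
  val <- b - 0.25 * (a - c) * off
  c(off, val)
}

# 8-connected component labelling of a logical matrix (small grids; BFS).
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# Linear-interpolation resampling helper with strict bounds checking.
resample_linear <- function(t, y, t_out) {
  stats::approx(t, y, xout = t_out, rule = 2)$y
}
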