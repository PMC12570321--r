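# Independent brute-force oracles. These deliberately share no code with the
# package: connectivity is explored by breadth-first search and saddles by an
# exhaustive threshold sweep.

# 8-connected components of a logical mask by BFS; returns an integer matrix.
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue <- c(queue, list(c(rr, cc)))
          }
        }
      }
    }
  }
  lab
}

# Local maxima (plateau-aware): equal-value plateaus whose strict neighbors
# are all lower. Returns a list of representative linear indices + peak
# values.
oracle_maxima <- function(img, mask) {
  plat <- oracle_components_by_value(img, mask)
  out <- list()
  nr <- nrow(img); nc <- ncol(img)
  for (pl in plat) {
    v <- img[pl[1]]
    is_max <- TRUE
    for (p in pl) {
      r <- (p - 1) %% nr + 1; cc <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1) * nr + rr
          if (mask[q] && img[q] > v) is_max <- FALSE
        }
      }
    }
    if (is_max) out[[length(out) + 1]] <- list(idx = pl[1], peak = v)
  }
  out
}

# Equal-value 8-connected plateaus within the mask (list of index vectors).
oracle_components_by_value <- function(img, mask) {
  res <- list()
  for (v in unique(img[mask])) {
    m <- mask & img == v
    lab <- oracle_components(m)
    for (l in seq_len(max(lab)))
      res[[length(res) + 1]] <- which(lab == l)
  }
  res
}

# Saddle between two pixels: the highest threshold t (over observed values)
# at which both lie in the same component of {img >= t} & mask. Connectivity
# is monotone in t, so a bisection over the sorted values is exact.
oracle_saddle <- function(img, mask, i, j) {
  connected_at <- function(t) {
    lab <- oracle_components(mask & img >= t)
    lab[i] != 0 && lab[i] == lab[j]
  }
  vals <- sort(unique(img[mask]))
  if (!connected_at(vals[1])) return(NA_real_)
  lo <- 1L; hi <- length(vals)          # connected at lo, test upward
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (connected_at(vals[mid])) lo <- mid else hi <- mid - 1L
  }
  vals[lo]
}

# Expected object count under the saddle rule: maxima clusters merged
# greedily in descending-saddle order while saddle > frac * min(peaks).
oracle_object_count <- function(img, mask, frac = 0.5) {
  mx <- oracle_maxima(img, mask)
  k <- length(mx)
  if (k == 0) return(0L)
  comp_lab <- oracle_components(mask)
  counts <- 0L
  for (comp in seq_len(max(comp_lab))) {
    in_comp <- Filter(function(m) comp_lab[m$idx] == comp, mx)
    n <- length(in_comp)
    if (n == 0) next
    if (n == 1) { counts <- counts + 1L; next }
    peaks <- vapply(in_comp, `[[`, numeric(1), "peak")
    idxs <- vapply(in_comp, `[[`, numeric(1), "idx")
    cluster <- seq_len(n)
    pair_saddle <- matrix(NA_real_, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      pair_saddle[a, b] <- pair_saddle[b, a] <-
        oracle_saddle(img, mask, idxs[a], idxs[b])
    repeat {
      best <- -Inf; ba <- NA; bb <- NA
      for (a in 1:(n - 1)) for (b in (a + 1):n) {
        if (cluster[a] != cluster[b] && pair_saddle[a, b] > best) {
          best <- pair_saddle[a, b]; ba <- a; bb <- b
        }
      }
      if (!is.finite(best)) break
      pa <- max(peaks[cluster == cluster[ba]])
      pb <- max(peaks[cluster == cluster[bb]])
      if (best > frac * min(pa, pb)) {
        cluster[cluster == cluster[bb]] <- cluster[ba]
      } else {
        pair_saddle[ba, bb] <- pair_saddle[bb, ba] <- -Inf
      }
    }
    counts <- counts + length(unique(cluster))
  }
  counts
}

# Two off-axis Gaussian puncta on a small plane.
double_gaussian_plane <- function(n = 32, a1 = 1000, a2 = 600, sep = 8,
                                  sigma = 2) {
  y <- matrix(rep(seq_len(n), n), n)
  x <- t(y)
  c1 <- (n + 1) / 2 - sep / 2
  c2 <- (n + 1) / 2 + sep / 2
  mid <- (n + 1) / 2
  a1 * exp(-((y - mid)^2 + (x - c1)^2) / (2 * sigma^2)) +
    a2 * exp(-((y - mid)^2 + (x - c2)^2) / (2 * sigma^2))
}
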