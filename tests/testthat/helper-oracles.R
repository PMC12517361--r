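# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations, kept separate from the package
# internals they check.

# Budgeted breadth-first selection on a contour map: adjacency is
# Chebyshev distance <= 2 between contour pixels (8-connectivity with a
# one-pixel gap tolerance); `rings` BFS levels are taken from the seed set.
bfs_select_oracle <- function(contour, seeds, rings) {
  H <- nrow(contour); W <- ncol(contour)
  sel <- matrix(FALSE, H, W)
  sel[seeds] <- contour[seeds]
  frontier <- which(sel)
  for (k in seq_len(rings)) {
    if (!length(frontier)) break
    nxt <- integer(0)
    for (idx in frontier) {
      r0 <- (idx - 1) %% H + 1; c0 <- (idx - 1) %/% H + 1
      for (dr in -2:2) for (dc in -2:2) {
        r <- r0 + dr; c <- c0 + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            contour[r, c] && !sel[r, c]) {
          sel[r, c] <- TRUE
          nxt <- c(nxt, (c - 1) * H + r)
        }
      }
    }
    frontier <- nxt
  }
  sel
}

# Naive Chebyshev binary dilation by d pixels.
dilate_oracle <- function(m, d) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  idx <- which(m, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- max(1, idx[i, 1] - d):min(H, idx[i, 1] + d)
    c <- max(1, idx[i, 2] - d):min(W, idx[i, 2] + d)
    out[r, c] <- TRUE
  }
  out
}

# Build a segmentation state on a toy contour map with unit activity in
# the vertical channel and the given seed pixels already selected, ready
# for seed_and_spread stepping.
toy_state <- function(contour, seed_px,
                      params = model_params(tau_contour_ms = 1e9)) {
  H <- nrow(contour); W <- ncol(contour)
  rg <- raster_geometry(px_per_arcmin = 1,
                        xlim = c(0, W), ylim = c(0, H))
  st <- init_segmentation(rg, signals = NULL)
  st$field$a[1, 1, , ] <- contour * 1.0
  st$s[seed_px] <- as.numeric(contour[seed_px])
  st$seeded <- TRUE
  st
}

# Random connected-ish toy contour map: a few random line strokes.
random_contour_map <- function(H, W, n_strokes = 4) {
  m <- matrix(FALSE, H, W)
  for (i in seq_len(n_strokes)) {
    r <- sample.int(H, 1); c <- sample.int(W, 1)
    len <- sample(5:max(6, min(H, W) - 2), 1)
    dr <- sample(c(-1, 0, 1), 1); dc <- sample(c(-1, 0, 1), 1)
    if (dr == 0 && dc == 0) dc <- 1
    for (k in 0:len) {
      rr <- r + k * dr; cc <- c + k * dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) m[rr, cc] <- TRUE
    }
  }
  m
}

# Default geometry/raster pair shared by model tests.
test_rg <- function() raster_geometry()
zero_jitter_params <- function(...) model_params(seed_jitter_arcmin = 0, ...)
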