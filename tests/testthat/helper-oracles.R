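# Independent scalar oracles, deliberately written as naive per-pixel loops
# so they share no code with the package's vectorized implementations.

# Brute-force confusion counts by explicit pixel loop.
oracle_metrics <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t_ <- truth[i, j]
      if (p == 1 && t_ == 1) tp <- tp + 1L
      else if (p == 1 && t_ == 0) fp <- fp + 1L
      else if (p == 0 && t_ == 0) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       acc = (tp + tn) / length(pred))
}

# Queue-based breadth-first labeling of foreground components.
oracle_label <- function(m, connectivity = 8) {
  h <- nrow(m); w <- ncol(m)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (sj in seq_len(w)) for (si in seq_len(h)) {
    if (m[si, sj] != 1 || lab[si, sj] != 0) next
    cur <- cur + 1L
    queue <- list(c(si, sj))
    lab[si, sj] <- cur
    while (length(queue) > 0) {
      px <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r <- px[1] + o[1]; c_ <- px[2] + o[2]
        if (r >= 1 && r <= h && c_ >= 1 && c_ <= w &&
            m[r, c_] == 1 && lab[r, c_] == 0) {
          lab[r, c_] <- cur
          queue <- c(queue, list(c(r, c_)))
        }
      }
    }
  }
  lab
}

# Border-reachability flood fill: background pixels not reachable from the
# border (4-connected background) are holes.
oracle_fill <- function(m) {
  h <- nrow(m); w <- ncol(m)
  bg <- 1L - m
  reach <- matrix(0L, h, w)
  queue <- list()
  for (i in seq_len(h)) for (j in c(1L, w)) {
    if (bg[i, j] == 1 && reach[i, j] == 0) { reach[i, j] <- 1L; queue <- c(queue, list(c(i, j))) }
  }
  for (j in seq_len(w)) for (i in c(1L, h)) {
    if (bg[i, j] == 1 && reach[i, j] == 0) { reach[i, j] <- 1L; queue <- c(queue, list(c(i, j))) }
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  while (length(queue) > 0) {
    px <- queue[[1]]; queue <- queue[-1]
    for (o in offs) {
      r <- px[1] + o[1]; c_ <- px[2] + o[2]
      if (r >= 1 && r <= h && c_ >= 1 && c_ <= w &&
          bg[r, c_] == 1 && reach[r, c_] == 0) {
        reach[r, c_] <- 1L
        queue <- c(queue, list(c(r, c_)))
      }
    }
  }
  out <- m
  out[bg == 1L & reach == 0L] <- 1L
  out
}

# Central finite differences of a scalar function of a parameter array.
numeric_grad <- function(fn, p, eps = 1e-5) {
  g <- p
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p[i] + eps
    p2 <- p; p2[i] <- p[i] - eps
    g[i] <- (fn(p1) - fn(p2)) / (2 * eps)
  }
  g
}

cohen_d <- function(v, y) {
  abs(mean(v[y == 1]) - mean(v[y == 0])) /
    sqrt((stats::var(v[y == 1]) + stats::var(v[y == 0])) / 2)
}
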