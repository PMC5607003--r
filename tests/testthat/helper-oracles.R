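# Brute-force oracles, kept deliberately independent of the package's
# implementations: explicit loops, queue-based flood fill, exhaustive
# searches.

# per-pixel loop over z
oracle_sum_project <- function(a) {
  d <- dim(a)
  out <- array(0, d[c(1, 3, 4)])
  for (t in seq_len(d[1])) {
    for (y in seq_len(d[3])) {
      for (x in seq_len(d[4])) {
        s <- 0
        for (z in seq_len(d[2])) s <- s + a[t, z, y, x]
        out[t, y, x] <- s
      }
    }
  }
  out
}

# queue-based 8-connected flood fill
oracle_label <- function(fg) {
  ny <- nrow(fg)
  nx <- ncol(fg)
  lab <- matrix(0L, ny, nx)
  nxt <- 0L
  for (x0 in seq_len(nx)) {
    for (y0 in seq_len(ny)) {
      if (!fg[y0, x0] || lab[y0, x0] > 0L) next
      nxt <- nxt + 1L
      queue <- list(c(y0, x0))
      lab[y0, x0] <- nxt
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (dy in -1:1) {
          for (dx in -1:1) {
            y <- p[1] + dy
            x <- p[2] + dx
            if (y >= 1 && y <= ny && x >= 1 && x <= nx &&
                fg[y, x] && lab[y, x] == 0L) {
              lab[y, x] <- nxt
              queue[[length(queue) + 1]] <- c(y, x)
            }
          }
        }
      }
    }
  }
  lab
}

# exhaustive zero-padded mean-centred cross-correlation over all offsets in
# +/- radius; returns the estimated displacement (argmax), ties broken like
# the implementation (|dy|+|dx|, then dy, then dx)
oracle_shift <- function(frame, ref, radius) {
  f0 <- frame - mean(frame)
  g0 <- ref - mean(ref)
  ny <- nrow(ref)
  nx <- ncol(ref)
  res <- NULL
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      s <- 0
      for (y in seq_len(ny)) {
        for (x in seq_len(nx)) {
          yy <- y + dy
          xx <- x + dx
          if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) {
            s <- s + f0[yy, xx] * g0[y, x]
          }
        }
      }
      res <- rbind(res, c(dy, dx, s))
    }
  }
  cand <- res[res[, 3] >= max(res[, 3]) - 1e-9, , drop = FALSE]
  o <- order(abs(cand[, 1]) + abs(cand[, 2]), cand[, 1], cand[, 2])
  unname(cand[o[1], 1:2])
}

# explicit per-pixel averaging
oracle_trace <- function(a, label_image, label) {
  nt <- dim(a)[1]
  out <- numeric(nt)
  pix <- which(label_image == label, arr.ind = TRUE)
  for (t in seq_len(nt)) {
    s <- 0
    for (k in seq_len(nrow(pix))) s <- s + a[t, pix[k, 1], pix[k, 2]]
    out[t] <- s / nrow(pix)
  }
  out
}

# coarse-to-fine grid search over (tau, A, C), least squares
oracle_gridfit <- function(y, tt, t0) {
  best <- c(NA, NA, NA)
  best_rss <- Inf
  taus <- seq(5, 600, by = 1)
  as <- seq(0, 1.5, by = 0.01)
  cs <- seq(0, 1, by = 0.01)
  for (tau in taus) {
    e <- exp(-(tt - t0) / tau)
    for (A in as) {
      r0 <- y - A * e
      # optimal C given A, tau is the clamped mean of residuals
      C <- max(mean(r0), 0)
      rss <- sum((r0 - C)^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- c(tau, A, C)
      }
    }
  }
  list(tau = best[1], A = best[2], C = best[3], rss = best_rss)
}
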