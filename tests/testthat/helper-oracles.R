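# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own computation paths.

# Circle IoU by rasterization on a fine subpixel grid.
rasterCircleIoU <- function(cx1, cy1, r1, cx2, cy2, r2, res = 0.1) {
  lo <- c(min(cx1 - r1, cx2 - r2), min(cy1 - r1, cy2 - r2)) - res
  hi <- c(max(cx1 + r1, cx2 + r2), max(cy1 + r1, cy2 + r2)) + res
  xs <- seq(lo[1], hi[1], by = res)
  ys <- seq(lo[2], hi[2], by = res)
  g <- expand.grid(x = xs, y = ys)
  in1 <- (g$x - cx1)^2 + (g$y - cy1)^2 <= r1^2
  in2 <- (g$x - cx2)^2 + (g$y - cy2)^2 <= r2^2
  sum(in1 & in2) / sum(in1 | in2)
}

# Template-matching response by direct pixel counting: fraction of the
# rasterized disk of diameter r centered at (row, col) lying on foreground.
bruteResponse <- function(F, r, row, col) {
  h <- floor(r / 2)
  tot <- 0L
  hit <- 0L
  for (a in -h:h) for (b in -h:h) {
    if (a^2 + b^2 > (r / 2)^2) next
    tot <- tot + 1L
    i <- row + a
    j <- col + b
    if (i >= 1 && i <= nrow(F) && j >= 1 && j <= ncol(F) && F[i, j] > 0)
      hit <- hit + 1L
  }
  hit / tot
}

# Rasterize truth circles into a binary mask.
rasterCircles <- function(circles, H, W) {
  m <- matrix(0L, H, W)
  for (i in seq_len(nrow(circles))) {
    rows <- max(1, floor(circles$cy[i] - circles$r[i])):
      min(H, ceiling(circles$cy[i] + circles$r[i]))
    cols <- max(1, floor(circles$cx[i] - circles$r[i])):
      min(W, ceiling(circles$cx[i] + circles$r[i]))
    d2 <- outer((rows - circles$cy[i])^2, (cols - circles$cx[i])^2, `+`)
    sub <- m[rows, cols, drop = FALSE]
    sub[d2 <= circles$r[i]^2] <- 1L
    m[rows, cols] <- sub
  }
  m
}

# Maximum one-to-one matching count at threshold theta by exhaustive
# assignment enumeration (feasible for <= 5 circles a side).
optimalMatchCount <- function(truth, pred, theta) {
  nt <- nrow(truth)
  np <- nrow(pred)
  if (nt == 0 || np == 0) return(0L)
  iou <- outer(seq_len(nt), seq_len(np), function(i, j)
    circleIoU(truth$cx[i], truth$cy[i], truth$r[i],
              pred$cx[j], pred$cy[j], pred$r[j]))
  best <- 0L
  assignRec <- function(i, used, count) {
    if (count + (nt - i + 1) <= best) return()
    if (i > nt) {
      best <<- max(best, count)
      return()
    }
    assignRec(i + 1, used, count)  # truth i unmatched
    for (j in seq_len(np)) {
      if (!used[j] && iou[i, j] >= theta) {
        used[j] <- TRUE
        assignRec(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assignRec(1L, rep(FALSE, np), 0L)
  best
}
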