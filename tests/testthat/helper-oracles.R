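# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and EBImage): plain loops and closed
# forms only.

# 8-connectivity connected-component labeling by breadth-first search
oracle_label_blobs <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# centroids of all maximum-area blobs of a binary matrix (ties are real on
# random masks, and which of the tied blobs is tracked is unspecified)
oracle_largest_centroids <- function(mask) {
  lab <- oracle_label_blobs(mask)
  if (max(lab) == 0) return(NULL)
  areas <- tabulate(lab[lab > 0])
  t(vapply(which(areas == max(areas)), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    c(mean(idx[, "col"]), mean(idx[, "row"]))
  }, numeric(2)))
}

# textbook product-moment correlation
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# simple linear regression via the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# trajectory tibble from a position signal sampled at fs
make_traj <- function(y, fs, x = 0) {
  t <- (seq_along(y) - 1) / fs
  traj <- tibble::tibble(time_s = t, x_px = rep_len(x, length(y)), y_px = y)
  attr(traj, "fps") <- fs
  class(traj) <- c("trajectory", class(traj))
  traj
}
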