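# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain loops, closed forms, or exhaustive walks.

# Number of 6-connected (3D) / 4-connected (2D) components of TRUE voxels,
# by queue-based flood fill.
oracle_n_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  m <- array(mask, dim = d)
  seen <- array(FALSE, dim = d)
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  ncomp <- 0L
  for (start in which(m & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- list(arrayInd(start, d))
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (k in 1:6) {
        w <- v + off[k, ]
        if (any(w < 1L) || any(w > d)) next
        if (m[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  ncomp
}

# Cross-kernel dilation closed form: a pixel is in the k-fold dilation iff
# its Manhattan distance to the nearest TRUE pixel is <= k.
oracle_dilate <- function(mask, k) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      dist <- min(abs(src[, 1] - i) + abs(src[, 2] - j))
      if (dist <= k) out[i, j] <- TRUE
    }
  out
}

# Per-voxel ancestor walk: label belongs to cortex iff walking parent
# pointers from the label reaches root_id.
oracle_ancestor_mask <- function(labels, nodes, root_id) {
  parent <- stats::setNames(nodes$parent_id, nodes$id)
  reaches <- function(id) {
    while (!is.na(id)) {
      if (id == root_id) return(TRUE)
      id <- parent[[as.character(id)]]
    }
    FALSE
  }
  ok <- vapply(sort(unique(as.vector(labels))), function(l)
    l != 0L && l %in% nodes$id && reaches(l), logical(1))
  names(ok) <- sort(unique(as.vector(labels)))
  array(ok[as.character(labels)], dim = dim(labels))
}

# Plain-loop per-path maximum.
oracle_path_max <- function(values, path_matrix) {
  vapply(seq_len(nrow(path_matrix)), function(i) {
    p <- path_matrix[i, ]
    max(values[p[!is.na(p)]])
  }, numeric(1))
}

# Exhaustive single CART tree, Gini criterion, grown to purity; returns the
# per-feature sum of weighted impurity decreases. Mirrors the stated split
# conventions (ascending feature order, strict improvement, midpoint
# thresholds, x <= threshold goes left) but is written independently.
oracle_gini_importance <- function(X, y) {
  G <- ncol(X)
  N <- nrow(X)
  imp <- numeric(G)
  rec <- function(idx) {
    n <- length(idx)
    yy <- y[idx]
    c1 <- sum(yy)
    c0 <- n - c1
    if (c0 == 0L || c1 == 0L || n < 2L) return(invisible(NULL))
    g <- 1 - (c0 / n)^2 - (c1 / n)^2
    best_dec <- 0; best_f <- -1L; best_thr <- NA_real_
    for (f in seq_len(G)) {
      o <- order(X[idx, f])
      xs <- X[idx, f][o]
      ys <- yy[o]
      l0 <- 0; l1 <- 0
      for (i in 2:n) {
        if (ys[i - 1L] == 1L) l1 <- l1 + 1 else l0 <- l0 + 1
        if (xs[i] <= xs[i - 1L]) next
        r0 <- c0 - l0; r1 <- c1 - l1
        nl <- l0 + l1; nr <- r0 + r1
        gl <- 1 - (l0 / nl)^2 - (l1 / nl)^2
        gr <- 1 - (r0 / nr)^2 - (r1 / nr)^2
        dec <- g - (nl / n) * gl - (nr / n) * gr
        if (dec > best_dec) {
          best_dec <- dec; best_f <- f
          best_thr <- 0.5 * (xs[i - 1L] + xs[i])
        }
      }
    }
    if (best_f < 0L || best_dec <= 0) return(invisible(NULL))
    imp[best_f] <<- imp[best_f] + (n / N) * best_dec
    left <- idx[X[idx, best_f] <= best_thr]
    right <- idx[X[idx, best_f] > best_thr]
    rec(left)
    rec(right)
  }
  rec(seq_len(N))
  imp
}
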