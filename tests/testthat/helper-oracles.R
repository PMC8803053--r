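# Independent brute-force oracles used to validate the implementation.

# queue-based flood-fill labeling (no union-find, deliberately naive)
flood_label_oracle <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb[k, 1]; cc <- c + nb[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
        }
      }
    }
  }
  attr(lab, "n_labels") <- nxt
  lab
}

# hole filling by flood fill: background 8-connected, border-touching
# background is never a hole, fill strictly-smaller-than-threshold holes
fill_holes_oracle <- function(mask, min_hole_px) {
  bg <- flood_label_oracle(!mask, 8)
  n <- attr(bg, "n_labels")
  if (n == 0) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  out <- mask
  for (l in seq_len(n)) {
    if (l %in% border) next
    if (sum(bg == l) < min_hole_px) out[bg == l] <- TRUE
  }
  out
}

remove_small_oracle <- function(mask, min_obj_px) {
  lab <- flood_label_oracle(mask, 4)
  n <- attr(lab, "n_labels")
  out <- mask
  for (l in seq_len(n)) if (sum(lab == l) < min_obj_px) out[lab == l] <- FALSE
  out
}

# two-way ANOVA ICC(C,1) via stats::aov, an independent code path from the
# package's closed-form sums of squares
icc_aov_oracle <- function(m, alpha = 0.05) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- f / qf(1 - alpha / 2, df1, df2)
  fu <- f * qf(1 - alpha / 2, df2, df1)
  list(icc = icc, f = f,
       p = pf(f, df1, df2, lower.tail = FALSE),
       ci_low = (fl - 1) / (fl + k - 1),
       ci_high = (fu - 1) / (fu + k - 1))
}

# dense direct 2-D convolution (O(n * k^2)), replicate borders
conv2_oracle <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0
      for (a in -kr:kr) {
        for (b in -kc:kc) {
          rr <- min(nr, max(1, r + a)); cc <- min(nc, max(1, c + b))
          acc <- acc + kern[a + kr + 1, b + kc + 1] * m[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}
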