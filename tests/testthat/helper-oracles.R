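# Brute-force oracles, written independently of the package engine:
# plain nested-loop window enumeration with explicit subarray extraction.

# window origin list under the shared convention: grid mode tiles from the low
# corner keeping clipped edge windows; gliding strides by 1; axes shorter than
# s give a single clipped window.
oracle_window_list <- function(d, s, stride_mode) {
  nw <- vapply(d, function(e) {
    if (stride_mode == "grid") ceiling(e / s) else max(e - s + 1, 1)
  }, numeric(1))
  stride <- if (stride_mode == "grid") s else 1
  origins <- expand.grid(lapply(nw, function(n) seq_len(n) - 1))
  lapply(seq_len(nrow(origins)), function(i) {
    lo <- as.numeric(origins[i, ]) * stride
    hi <- pmin(lo + s, d)
    list(lo = lo, hi = hi)
  })
}

oracle_window_values <- function(a, w) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(ax) seq.int(w$lo[ax] + 1, w$hi[ax]))
  do.call(`[`, c(list(a), idx))
}

oracle_box_count <- function(a, s, stride_mode) {
  ws <- oracle_window_list(dim(a), s, stride_mode)
  sum(vapply(ws, function(w) any(oracle_window_values(a, w) > 0), logical(1)))
}

pop_var <- function(v) mean((v - mean(v))^2)

oracle_lacunarity <- function(a, s, stride_mode, statistic = "literal",
                              normalize = TRUE) {
  ws <- oracle_window_list(dim(a), s, stride_mode)
  if (statistic == "literal") {
    cv2 <- vapply(ws, function(w) {
      v <- oracle_window_values(a, w)
      mu <- mean(v)
      if (mu <= 0) return(NA_real_)
      pop_var(v) / mu^2
    }, numeric(1))
    cv2 <- cv2[!is.na(cv2)]
    stopifnot(length(cv2) > 0)
    out <- mean(cv2)
  } else {
    masses <- vapply(ws, function(w) sum(oracle_window_values(a, w)), numeric(1))
    mu <- mean(masses)
    out <- pop_var(masses) / mu^2
  }
  if (normalize) 1 + out else out
}

oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# ICC(2,1) via stats::aov mean squares -- an independent route to the
# two-way decomposition.
oracle_icc21 <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

random_mask_array <- function(n, fill, seed) {
  set.seed(seed)
  a <- array(rbinom(n^3, 1, fill), c(n, n, n))
  if (sum(a) == 0) a[1] <- 1L
  a
}
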