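# Independent oracles, deliberately naive.

# plain stack-based BFS flood fill, one pixel at a time, 8-connectivity
bfs_oracle <- function(eligible, seed_row, seed_col) {
  out <- matrix(FALSE, nrow(eligible), ncol(eligible))
  if (!eligible[seed_row, seed_col]) return(out)
  stack <- list(c(seed_row, seed_col))
  out[seed_row, seed_col] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= nrow(eligible) && c >= 1 && c <= ncol(eligible) &&
          eligible[r, c] && !out[r, c]) {
        out[r, c] <- TRUE
        stack[[length(stack) + 1]] <- c(r, c)
      }
    }
  }
  out
}

# all-pairs concordance AUC, ties counted one half
auc_oracle <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# set-arithmetic morphology oracles: direct definition over all offsets
erode_oracle <- function(mask, k = 3) {
  half <- (k - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    rs <- (r - half):(r + half); cs <- (c - half):(c + half)
    if (any(rs < 1 | rs > nrow(mask)) || any(cs < 1 | cs > ncol(mask))) next
    out[r, c] <- all(mask[rs, cs])
  }
  out
}

dilate_oracle <- function(mask, k = 3) {
  half <- (k - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    rs <- max(1, r - half):min(nrow(mask), r + half)
    cs <- max(1, c - half):min(ncol(mask), c + half)
    out[r, c] <- any(mask[rs, cs])
  }
  out
}

# closed-form OLS via normal equations
ols_oracle <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))
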