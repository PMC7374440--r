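# independent brute-force oracles used across the suite

# trailing-window mean of |x|, plain double loop
bruteMovingMean <- function(x, win) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - win + 1L)
    out[i] <- mean(abs(x[lo:i]))
  }
  out
}

bruteLongestRun <- function(b) {
  best <- 0L; cur <- 0L
  for (v in b) {
    cur <- if (isTRUE(v)) cur + 1L else 0L
    if (cur > best) best <- cur
  }
  best
}

# textbook paired t on differences d = post - pre
brutePairedT <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, p = p, df = n - 1)
}

# midrank Spearman rho via explicit rank computation
bruteSpearmanRho <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..n (small n only)
allPerms <- function(n) {
  if (n == 1) return(matrix(1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- allPerms(n - 1L)
    cbind(i, matrix((seq_len(n))[-i][p], nrow(p)))
  }))
}

# quick single-channel record from a numeric vector
toyRecord <- function(x, fs = 1000, role = "ECR", ann = NULL) {
  if (is.null(ann)) ann <- myocoh::emptyAnnotations()
  myocoh::SignalRecord(matrix(x, ncol = 1), fs, role, ann)
}
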