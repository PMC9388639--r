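# Shared fixtures, built in code.

# Small scenes keep the unit tests fast; the pixel pitch stays at the
# optical default so cell sizes in px are realistic.
smallScene <- function(...) {
  sceneConfig(frameWidthPx = 250L, frameHeightPx = 250L, ...)
}

# Hand-built five-frame batch from a function frame(i) -> matrix.
buildBatch <- function(frameFun, spacingMs = 100) {
  f1 <- frameFun(1)
  a <- array(0, dim = c(nrow(f1), ncol(f1), 5))
  a[, , 1] <- f1
  for (i in 2:5) a[, , i] <- frameFun(i)
  new("FrameBatch", frames = a, spacingMs = spacingMs)
}

# Constant-background batch with one dark soft disk moving dx px/frame.
movingCellBatch <- function(size = 200L, start = c(40, 100), dx = 30,
                            sigma = 2, delta = -60, bg = 180) {
  buildBatch(function(i) {
    m <- matrix(bg, size, size)
    x <- start[1] + (i - 1) * dx
    y <- start[2]
    cols <- pmax(1, round(x - 10)):pmin(size, round(x + 10))
    rows <- pmax(1, round(y - 10)):pmin(size, round(y + 10))
    for (r in rows) for (cc in cols) {
      m[r, cc] <- m[r, cc] +
        delta * exp(-((cc - x)^2 + (r - y)^2) / (2 * sigma^2))
    }
    m
  })
}

# Parameters suited to hand-built noiseless scenes at full resolution.
plainParams <- function(...) {
  defaultParameters(
    downscaleFactor = 1L, cellBlurSigma = 0, cellMinArea = 1,
    cellMaxArea = 400, artifactMinArea = 500, ...
  )
}

# Independent normal-equations oracle for simple linear regression.
olsOracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Brute-force pairwise concordance oracle for the AUROC (ties count 1/2).
aurocOracle <- function(pred, labels) {
  pos <- pred[labels == "positive"]
  neg <- pred[labels == "negative"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided sign-permutation p-value for the Wilcoxon signed-rank
# statistic W = min(W+, W-), enumerating all 2^n sign assignments.
wilcoxExactOracle <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- n * (n + 1) / 2
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    wPos <- sum(r[signs])
    w <- min(wPos, total - wPos)
    if (w <= wObs) count <- count + 1L
  }
  count / 2^n
}
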