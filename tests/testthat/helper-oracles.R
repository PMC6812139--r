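# Independent oracles and small builders shared across test files.

# Brute-force EDT: all-pairs minimum distance from each foreground pixel to
# the nearest background pixel. Quadratic and only for small masks.
bruteForceEDT <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(mask == 0, arr.ind = TRUE)
  fg <- which(mask > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    out[fg[k, 1], fg[k, 2]] <-
      sqrt(min((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2))
  }
  out
}

# Brute-force two-sample KS statistic: maximum ECDF gap over all sample points.
bruteForceKSD <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- ecdf(a)(pts)
  fb <- ecdf(b)(pts)
  max(abs(fa - fb))
}

# Digital disc mask of radius r with a 2-px background margin.
discMask <- function(r) {
  n <- 2L * (r + 2L) + 1L
  ctr <- r + 3L
  xx <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  yy <- matrix(rep(seq_len(n) - ctr, times = n), n, n)
  matrix(as.integer(sqrt(xx^2 + yy^2) <= r), n, n)
}

# Match mapper records to ground-truth alleles of the same nucleus by
# proximity; returns |rrp - realized_rrp| for records whose nearest truth
# spot lies within matchRadius pixels.
truthErrors <- function(records, truth, matchRadius = 2) {
  errs <- numeric(0)
  for (i in seq_len(nrow(records))) {
    s <- truth[truth$nucleus_id == records$nucleus_id[i] &
                 truth$gene == records$gene[i], ]
    if (!nrow(s)) next
    d2 <- (s$x - records$x[i])^2 + (s$y - records$y[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= matchRadius)
      errs <- c(errs, abs(records$rrp[i] - s$realized_rrp[j]))
  }
  errs
}

# Random connected blob mask (single 8-connected component) for EDT tests.
randomBlobMask <- function(maxSide = 30L) {
  nr <- sample(8:maxSide, 1)
  nc <- sample(8:maxSide, 1)
  m <- matrix(0L, nr, nc)
  r <- sample(2:(nr - 1), 1)
  cc <- sample(2:(nc - 1), 1)
  m[r, cc] <- 1L
  for (step in seq_len(sample(20:80, 1))) {
    r <- min(max(r + sample(-1:1, 1), 2L), nr - 1L)
    cc <- min(max(cc + sample(-1:1, 1), 2L), nc - 1L)
    m[r, cc] <- 1L
  }
  m
}

prostateBenignIds <- c(sprintf("N%d", 1:16), sprintf("B%d", 1:9))

# Compare a computed percentage with a value printed to one decimal place
# (allows for rounding/truncation of the printed figure).
expectPrinted <- function(actual, printed) {
  testthat::expect_lt(abs(actual - printed), 0.15)
}
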