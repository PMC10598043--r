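# Independent brute-force oracles and fixture builders. These deliberately
# re-derive each quantity from first principles, by loops and textbook
# formulas, never by calling the package's own code paths.

# random count table, samples x OTUs, with a heavy-tailed abundance spectrum
randomCounts <- function(nSamples, nOtus, depth = 5000) {
  base <- exp(rnorm(nOtus, 0, 2))
  base <- base / sum(base)
  m <- t(vapply(seq_len(nSamples),
                function(i) as.numeric(rmultinom(1, depth, base)),
                numeric(nOtus)))
  dimnames(m) <- list(paste0("S", seq_len(nSamples)),
                      paste0("OTU", seq_len(nOtus)))
  m
}

# six abundance rules applied literally, one OTU at a time
oracleAbundance <- function(ra, hi = 0.01, lo = 1e-4) {
  out <- character(0)
  for (j in seq_len(ncol(ra))) {
    v <- ra[, j]
    if (all(v == 0)) next
    cat6 <-
      if (all(v > hi)) "AAT"
      else if (all(v < lo)) "ART"
      else if (all(v >= lo) && all(v <= hi)) "MT"
      else if (all(v >= lo) && any(v > hi)) "CAT"
      else if (any(v < lo) && all(v <= hi)) "CRT"
      else "CRAT"
    out[colnames(ra)[j]] <- cat6
  }
  out
}

# Levins breadth by explicit loop
oracleLevins <- function(x) {
  p <- x / sum(x)
  s <- 0
  for (v in p) s <- s + v * v
  1 / s
}

# ANOSIM R by explicit rank bookkeeping
oracleAnosimR <- function(m, groups) {
  n <- nrow(m)
  d <- r <- NULL
  within <- logical(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, m[j, i])
    within <- c(within, groups[i] == groups[j])
  }
  rk <- rank(d)
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# exact ANOSIM p for 2 groups of 2 by enumerating the 3 distinct partitions
oracleAnosimExactP <- function(m) {
  parts <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  rs <- vapply(parts, function(g) oracleAnosimR(m, g), numeric(1))
  rObs <- rs[1]
  mean(rs >= rObs - 1e-12)
}

# one-way ANOVA F by the textbook sums of squares
oracleAnovaF <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- nlevels(groups)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# RDA constrained fraction as 1 - RSS/TSS of the per-column regressions
oracleRdaFraction <- function(y, x, hellinger = TRUE) {
  y <- as.matrix(y)
  if (hellinger) y <- sqrt(y / rowSums(y))
  yc <- sweep(y, 2, colMeans(y))
  X <- cbind(1, as.matrix(x))
  rss <- 0
  for (j in seq_len(ncol(yc))) {
    fit <- lm.fit(X, yc[, j])
    rss <- rss + sum(fit$residuals^2)
  }
  1 - rss / sum(yc^2)
}

tinyMeta <- function(n = 4) {
  data.frame(longitude_deg = 117.4 + seq_len(n) / 100,
             latitude_deg = 36.43 + seq_len(n) / 100,
             elevation_m = 500 + 10 * seq_len(n),
             row.names = paste0("S", seq_len(n)))
}
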