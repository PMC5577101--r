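# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by direct enumeration / simulation, not by calling the
# package's optimised code paths.

# run expr with a local RNG state, restoring whatever was there before
localSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# integer-valued test image from a seed
randomCountImage <- function(nr, nc, maxval = 1000, seed = 1) {
  localSeed(seed,
            matrix(as.numeric(sample(0:maxval, nr * nc, replace = TRUE)),
                   nr, nc))
}

wellFromMatrix <- function(m, bitDepth = 16L, wellId = "A01") {
  WellImage(m, bitDepth = bitDepth, wellId = wellId)
}

# direct 2-D evaluation of the Gaussian-weighted local mean with half-sample
# reflection at the borders (the kernel is the outer product of the 1-D
# Gaussian of sigma = window/6 truncated to the window)
bfLocalMean <- function(img, window) {
  half <- window %/% 2
  sigma <- window / 6
  w1 <- exp(-0.5 * (((-half):half) / sigma)^2)
  w1 <- w1 / sum(w1)
  K <- outer(w1, w1)
  reflect <- function(t, n) {
    while (any(t < 1 | t > n)) {
      t[t < 1] <- 1 - t[t < 1]       # 0 -> 1, -1 -> 2 on 1-based indices
      t[t > n] <- 2 * n + 1 - t[t > n]
    }
    t
  }
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in (-half):half) for (dj in (-half):half)
      acc <- acc + K[di + half + 1, dj + half + 1] *
        img[reflect(i + di, nr), reflect(j + dj, nc)]
    out[i, j] <- acc
  }
  out
}

# 8-connected components of a logical matrix by breadth-first search
bfComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      idx <- queue[1L]; queue <- queue[-1L]
      i <- (idx - 1L) %% nr + 1L
      j <- (idx - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- i + di; nj <- j + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        nidx <- ni + (nj - 1L) * nr
        if (mask[nidx] && lab[nidx] == 0L) {
          lab[nidx] <- cur
          queue <- c(queue, nidx)
        }
      }
    }
  }
  lab
}

hasTwoByTwoBlock <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr < 2 || nc < 2) return(FALSE)
  any(mask[-nr, -nc] & mask[-1, -nc] & mask[-nr, -1] & mask[-1, -1])
}

# literal simulation of the marker-seeded intensity-priority flood fill:
# pop order (intensity desc, label asc, insertion order asc), assign on
# first pop, expand neighbours in the fixed offset order
bfPriorityFlood <- function(img, mask, markers) {
  nr <- nrow(img)
  labels <- markers
  expanded <- matrix(FALSE, nr, ncol(img))
  qi <- numeric(0); ql <- integer(0); qo <- integer(0); qx <- integer(0)
  counter <- 0L
  push <- function(idx, lab) {
    qi <<- c(qi, img[idx]); ql <<- c(ql, lab)
    qo <<- c(qo, counter); qx <<- c(qx, idx)
    counter <<- counter + 1L
  }
  for (idx in which(markers > 0L)) push(idx, markers[idx])
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  while (length(qx)) {
    best <- order(-qi, ql, qo)[1L]
    idx <- qx[best]; poplab <- ql[best]
    qi <- qi[-best]; ql <- ql[-best]; qo <- qo[-best]; qx <- qx[-best]
    if (expanded[idx]) next
    if (labels[idx] == 0L) labels[idx] <- poplab
    expanded[idx] <- TRUE
    i <- (idx - 1L) %% nr + 1L
    j <- (idx - 1L) %/% nr + 1L
    for (k in 1:8) {
      ni <- i + offs[k, 1L]; nj <- j + offs[k, 2L]
      if (ni < 1 || ni > nr || nj < 1 || nj > ncol(img)) next
      nidx <- ni + (nj - 1L) * nr
      if (mask[nidx] && !expanded[nidx] && labels[nidx] == 0L)
        push(nidx, labels[idx])
    }
  }
  labels
}

# pooled-variance t statistic (direct formula, no stats:: call)
bfPooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# two-sided permutation p-value of the pooled t statistic
bfPermutationP <- function(a, b, nPerm = 1e5, seed = 1) localSeed(seed, {
  x <- c(a, b)
  na <- length(a); N <- length(x)
  tobs <- abs(bfPooledT(a, b))
  hits <- 0L
  for (r in seq_len(nPerm)) {
    sel <- sample.int(N, na)
    tr <- bfPooledT(x[sel], x[-sel])
    if (abs(tr) >= tobs - 1e-12) hits <- hits + 1L
  }
  hits / nPerm
})

# coarse grid search over (ec50, hill) with bottom/top solved linearly
bfGrid4PLRss <- function(x, y, nGrid = 25) {
  ecs <- exp(seq(log(min(x)), log(max(x)), length.out = nGrid))
  hills <- seq(-4, 4, length.out = nGrid)
  best <- Inf
  for (e in ecs) for (h in hills) {
    if (abs(h) < 1e-6) next
    f <- 1 / (1 + (e / x)^h)
    X <- cbind(1 - f, f)
    fit <- tryCatch(lm.fit(X, y), error = function(err) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$residuals^2)
    if (rss < best) best <- rss
  }
  best
}
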