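# Shared fixtures and independent oracles.

# small phantom for fast geometric tests (channel-2 grid 64x64x10 at 1 mm
# in-plane, channel 1 at 2 mm)
tinyPhantomConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    gridShape = c(64L, 64L, 10L),
    spacingCh1 = c(2, 2, 4), spacingCh2 = c(1, 1, 4),
    nLesions = 1L, lesionRadiusRange = c(7, 11),
    t1HypoFraction = 0.5, confuserCount = 3L,
    confuserRadiusRange = c(4, 7), misregOffset = c(1, 0.5, 0),
    noiseSd = 0.03, seed = 1L)
  defaults[names(args)] <- args
  do.call(phantomConfig, defaults)
}

# 2-stage net for 32x32 slices; small enough to train in seconds
tinyNetConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    inputSize = 32L, channelsPerStage = c(8L, 16L), growthRate = 8L,
    denseMicroBlocks = 2L, bottleneckFactor = 2L, gnGroups = 4L)
  defaults[names(args)] <- args
  do.call(segNetConfig, defaults)
}

# independent flood-fill component labeling (recursive frontier growth in
# plain R; no shared code with the package's BFS)
floodFillLabels <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  nb <- nb[!(nb$di == 0 & nb$dj == 0 & nb$dk == 0), ]
  manh <- abs(nb$di) + abs(nb$dj) + abs(nb$dk)
  nb <- nb[switch(as.character(connectivity),
                  "6" = manh == 1, "18" = manh <= 2, manh <= 3), ]
  nextLab <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k] == 0 || lab[i, j, k] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- matrix(c(i, j, k), ncol = 3)
    lab[i, j, k] <- nextLab
    while (nrow(frontier) > 0) {
      newFrontier <- NULL
      for (r in seq_len(nrow(frontier))) {
        for (q in seq_len(nrow(nb))) {
          ni <- frontier[r, 1] + nb$di[q]
          nj <- frontier[r, 2] + nb$dj[q]
          nk <- frontier[r, 3] + nb$dk[q]
          if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] ||
              nk < 1 || nk > d[3]) next
          if (mask[ni, nj, nk] == 1 && lab[ni, nj, nk] == 0L) {
            lab[ni, nj, nk] <- nextLab
            newFrontier <- rbind(newFrontier, c(ni, nj, nk))
          }
        }
      }
      frontier <- if (is.null(newFrontier)) matrix(numeric(0), ncol = 3) else
        newFrontier
    }
  }
  lab
}

# two labelings describe the same partition iff the label-pair mapping is
# one-to-one in both directions
samePartition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  pairs <- unique(cbind(a[fg], b[fg]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# central-difference numerical gradient of f at x (elementwise)
numGrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(as.array(x)))
  xv <- as.array(x)
  for (i in seq_along(xv)) {
    xp <- xv; xp[i] <- xp[i] + eps
    xm <- xv; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
exactMannWhitneyP <- function(a, b) {
  n1 <- length(a)
  pool <- c(a, b)
  n <- length(pool)
  r <- rank(pool)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, uOf)
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# deterministic random binary mask
randomMask <- function(d, p = 0.35, seed = 1) {
  set.seed(seed)
  array(as.numeric(stats::runif(prod(d)) < p), d)
}
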