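## Independent brute-force oracles used across the suite.

## Per-voxel central-difference gradient magnitude with edge replication,
## written as explicit loops (independent of the vectorized implementation).
oracle_gradmag <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    gx <- (a[min(i + 1, d[1]), j, k] - a[max(i - 1, 1), j, k]) / 2
    gy <- (a[i, min(j + 1, d[2]), k] - a[i, max(j - 1, 1), k]) / 2
    gz <- (a[i, j, min(k + 1, d[3])] - a[i, j, max(k - 1, 1)]) / 2
    out[i, j, k] <- sqrt(gx^2 + gy^2 + gz^2)
  }
  out
}

## Naive Meyer flooding: repeatedly label the pending (frontier) voxel with
## the smallest (landscape value, linear index); a voxel keeps the label it
## was first reached with. 6-connectivity.
oracle_watershed <- function(grad, markers, mask = NULL) {
  d <- dim(grad)
  n <- length(grad)
  if (is.null(mask)) mask <- rep(TRUE, n) else mask <- as.logical(mask)
  lab <- as.integer(markers)
  pend <- integer(n)
  active <- logical(n)
  sxy <- d[1] * d[2]
  nbrs <- function(v) {
    x <- (v - 1) %% d[1] + 1
    y <- ((v - 1) %/% d[1]) %% d[2] + 1
    z <- (v - 1) %/% sxy + 1
    out <- integer(0)
    if (x > 1) out <- c(out, v - 1L)
    if (x < d[1]) out <- c(out, v + 1L)
    if (y > 1) out <- c(out, v - d[1])
    if (y < d[2]) out <- c(out, v + d[1])
    if (z > 1) out <- c(out, v - sxy)
    if (z < d[3]) out <- c(out, v + sxy)
    out
  }
  push_from <- function(v) {
    for (u in nbrs(v)) {
      if (mask[u] && lab[u] == 0L && !active[u]) {
        pend[u] <<- lab[v]
        active[u] <<- TRUE
      }
    }
  }
  for (v in which(lab != 0L & mask)) push_from(v)
  while (any(active)) {
    cand <- which(active)
    v <- cand[order(grad[cand], cand)[1]]
    active[v] <- FALSE
    lab[v] <- pend[v]
    push_from(v)
  }
  array(lab, d)
}

## OLS slope/intercept by explicit normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

## Two-sided Fisher exact p for the 2-group median table, by enumeration of
## the hypergeometric support.
oracle_median_exact_p <- function(g1, g2) {
  all_v <- c(g1, g2)
  med <- stats::median(all_v)
  a <- sum(g1 > med)
  A <- sum(all_v > med)
  n1 <- length(g1); n2 <- length(g2)
  xs <- max(0, A - n2):min(A, n1)
  probs <- choose(n1, xs) * choose(n2, A - xs) / choose(n1 + n2, A)
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Shared fixture: the generator's default calibration line.
ref_calib <- function() default_calibration()
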