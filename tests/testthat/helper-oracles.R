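# Independent brute-force oracles: plain loops, no reuse of package internals.

oracle_quantile <- function(x, probs) {
  s <- sort(x)
  m <- length(s)
  vapply(probs, function(p) {
    h <- (m - 1) * p + 1
    lo <- floor(h)
    if (lo >= m) return(s[m])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }, 0)
}

oracle_wdist <- function(points, w) {
  w <- w / sum(w)
  m <- nrow(points)
  dm <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      dm[i, j] <- sqrt(sum(w * (points[i, ] - points[j, ])^2))
    }
  }
  dm
}

oracle_or <- function(points, w) {
  dm <- oracle_wdist(points, w)
  m <- nrow(dm)
  pair <- dm[upper.tri(dm)]
  vapply(seq_len(m), function(i) mean(dm[i, -i]) / mean(pair), 0)
}

oracle_fp_dfp <- function(pot, nulls, K, w, eps = 1e-10) {
  np <- nrow(pot)
  fp <- dfp <- numeric(np)
  for (g in seq_len(np)) {
    cand <- rbind(pot[-g, , drop = FALSE], nulls)
    flag <- c(rep(FALSE, np - 1), rep(TRUE, nrow(nulls)))
    d <- vapply(seq_len(nrow(cand)), function(j) {
      sqrt(sum((w / sum(w)) * (pot[g, ] - cand[j, ])^2))
    }, 0)
    nn <- order(d, seq_along(d))[seq_len(K)]
    null_nn <- nn[flag[nn]]
    fp[g] <- length(null_nn)
    dfp[g] <- sum(1 / pmax(d[null_nn], eps))
  }
  list(fp = fp, dfp = dfp)
}

oracle_silhouette <- function(points, assignment) {
  dm <- as.matrix(stats::dist(points))
  m <- nrow(dm)
  s <- numeric(m)
  for (i in seq_len(m)) {
    own <- assignment == assignment[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(m) != i])
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(cl) mean(dm[i, assignment == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive optimum over all medoid subsets of size k
oracle_pam_best_cost <- function(points, k) {
  dm <- as.matrix(stats::dist(points))
  sets <- utils::combn(nrow(points), k)
  min(apply(sets, 2, function(med) sum(apply(dm[, med, drop = FALSE], 1, min))))
}

rand_points <- function(m, p, sd = 1) matrix(rnorm(m * p, sd = sd), m, p)
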