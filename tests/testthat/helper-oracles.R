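# Independent reference implementations used to cross-check the package.
# These deliberately take brute-force routes (linear solves, flood fill,
# explicit rank arithmetic) distinct from the implementation paths.

# Moment-preserving threshold via a linear solve and polynomial root
# finding, then a scan over all cut points for the first cumulative
# fraction reaching the preserved background fraction.
oracle_moments <- function(counts) {
  p <- counts / sum(counts)
  z <- 0:255
  m <- vapply(1:3, function(k) sum(z^k * p), numeric(1))
  A <- matrix(c(1, m[1], m[1], m[2]), 2, 2)
  cc <- solve(A, -c(m[2], m[3]))          # c0, c1 of z^2 + c1 z + c0
  r <- sort(Re(polyroot(c(cc[1], cc[2], 1))))
  p0 <- (r[2] - m[1]) / (r[2] - r[1])
  cum <- cumsum(p)
  candidates <- which(cum >= p0 - 1e-9)
  z[candidates[1]]
}

# Connected components by breadth-first flood fill (8-neighbourhood).
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          i <- (cc - 1L) * nr + rr
          if (mask[i] && lab[i] == 0L) {
            lab[i] <- nxt
            queue <- c(queue, i)
          }
        }
      }
    }
  }
  lab
}

# Kruskal-Wallis H from explicit rank sums with tie correction.
oracle_kw_h <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

# Dunn z statistics from explicit mean ranks.
oracle_dunn_z <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  N <- length(values)
  nn <- tabulate(g)
  mr <- tapply(r, g, mean)
  ties <- table(values)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_len(nlevels(g)), 2)
  apply(pairs, 2, function(pr) {
    (mr[[pr[1]]] - mr[[pr[2]]]) /
      sqrt(v0 * (1 / nn[pr[1]] + 1 / nn[pr[2]]))
  })
}

# Exact bin-overlap fractions of a set of foreground columns with the
# 11-bin partition of 800 columns (for analytic downsampling checks).
oracle_col_bin_fractions <- function(fg_lo, fg_hi, n_src = 800, n_bin = 11) {
  e <- n_src * (0:n_bin) / n_bin
  vapply(seq_len(n_bin), function(j) {
    ov <- max(0, min(e[j + 1], fg_hi) - max(e[j], fg_lo))
    ov / (e[j + 1] - e[j])
  }, numeric(1))
}

random_histogram <- function() {
  h <- integer(256)
  k <- sample(3:30, 1)
  lv <- sample(0:255, k)
  h[lv + 1] <- sample(1:500, k, replace = TRUE)
  h
}
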