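# Independent brute-force CBS oracle: exhaustive O(n^2) arc scan plus the
# same sequential permutation rule, implemented with plain vectorized R.
# Used to check the package's segmentation (including its pruned
# permutation scan) on small arrays where exhaustive search is feasible.

oracle_stat_matrix <- function(x, min_width) {
  n <- length(x)
  C <- c(0, cumsum(x - mean(x)))
  D <- abs(outer(C, C, "-"))            # |C[j+1] - C[i+1]| at (i+1, j+1)
  k <- outer(0:n, 0:n, function(i, j) j - i)
  w <- matrix(0, n + 1, n + 1)
  valid <- k >= min_width & k <= n - min_width
  w[valid] <- sqrt(n / (k[valid] * (n - k[valid])))
  D * w
}

oracle_best_arc <- function(x, min_width) {
  S <- oracle_stat_matrix(x, min_width)
  best <- -Inf
  bi <- bj <- -1L
  n <- length(x)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      s <- S[i + 1, j + 1]
      if (s > best) {
        best <- s
        bi <- i
        bj <- j
      }
    }
  }
  list(i = bi, j = bj, stat = best)
}

oracle_max_stat <- function(x, min_width) max(oracle_stat_matrix(x, min_width))

# Full recursive CBS with the sequential permutation decision, consuming
# R's RNG stream in the same documented order as cbs_segment (left-to-right
# depth-first; one sample.int(n) per permutation; stop once the exceedance
# count proves p > alpha).
oracle_cbs <- function(x, params) {
  rec <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n >= 2 * params$min_width) {
      xs <- x[lo:hi]
      if (diff(range(xs)) >= 1e-12) {
        sc <- oracle_best_arc(xs, params$min_width)
        if (is.finite(sc$stat) && sc$stat > 0) {
          limit <- floor(params$alpha * params$nperm)
          count <- 0L
          b <- 0L
          reject <- FALSE
          while (b < params$nperm) {
            b <- b + 1L
            xp <- xs[sample.int(n)]
            if (oracle_max_stat(xp, params$min_width) >= sc$stat) {
              count <- count + 1L
              if (count > limit) {
                reject <- TRUE
                break
              }
            }
          }
          if (!reject) {
            out <- list()
            if (sc$i > 0) out <- c(out, rec(lo, lo + sc$i - 1L))
            out <- c(out, rec(lo + sc$i, lo + sc$j - 1L))
            if (lo + sc$j <= hi) out <- c(out, rec(lo + sc$j, hi))
            return(out)
          }
        }
      }
    }
    list(c(lo, hi))
  }
  do.call(rbind, rec(1L, length(x)))
}
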