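#' Parameters for circular binary segmentation
#'
#' Defaults mirror the classical defaults of the reference CBS
#' implementation: split significance `alpha = 0.01`, minimum arc width 2
#' probes, 2.5% trimmed variance. `nperm` defaults to 1,000 permutations
#' (the reference tool documents 10,000; 1,000 keeps routine runs fast at
#' the cost of coarser p-value resolution near `alpha`).
#'
#' @param alpha Significance level for accepting a split.
#' @param nperm Number of permutations per tested segment.
#' @param min_width Minimum number of probes on each side of a split.
#' @param trim Tail fraction trimmed when estimating the segment SD.
#' @param seed Integer seed for the permutation stream.
#' @param max_exhaustive Maximum segment length scanned exhaustively;
#'   longer segments use an overlapping windowed scan.
#' @param window Window length (probes) for the windowed scan; windows
#'   overlap by 50%.
#' @return An object of class `CbsParams`.
#' @export
cbs_params <- function(alpha = 0.01, nperm = 1000L, min_width = 2L,
                       trim = 0.025, seed = 1L, max_exhaustive = 5000L,
                       window = 2500L) {
  stopifnot(alpha > 0, alpha < 1, nperm >= 100, min_width >= 1,
            trim >= 0, trim < 0.5, window >= 2 * min_width)
  structure(
    list(alpha = alpha, nperm = as.integer(nperm),
         min_width = as.integer(min_width), trim = trim,
         seed = as.integer(seed),
         max_exhaustive = as.integer(max_exhaustive),
         window = as.integer(window)),
    class = "CbsParams"
  )
}

# Symmetric value-trimmed SD with a normal-consistency inflation factor:
# for trim fraction t per tail and q = qnorm(1 - t), the variance of the
# central (1 - 2t) mass of a normal is [(1 - 2t) - 2 q dnorm(q)] / (1 - 2t)
# times the full variance; the factor undoes that shrinkage.
trimmed_sd <- function(x, trim = 0.025) {
  n <- length(x)
  if (n < 4) return(stats::sd(x))
  ntrim <- floor(n * trim)
  if (ntrim == 0) return(stats::sd(x))
  t_eff <- ntrim / n
  xs <- sort(x)
  core <- xs[(ntrim + 1):(n - ntrim)]
  q <- stats::qnorm(1 - t_eff)
  corr <- sqrt((1 - 2 * t_eff) /
                 ((1 - 2 * t_eff) - 2 * q * stats::dnorm(q)))
  stats::sd(core) * corr
}

# Test one segment for a split. Returns NULL (no accepted split) or
# list(i, j, p): 0-based boundaries of the best arc within the segment.
# The arc statistic is scale-invariant between the observed and permuted
# series (the common trimmed-SD denominator cancels), so the scan runs on
# raw values. Permutations are drawn from R's RNG stream in a fixed order;
# the sequential loop stops as soon as the exceedance count proves
# p > alpha.
.cbs_find_split <- function(xs, params) {
  n <- length(xs)
  if (n < 2 * params$min_width) return(NULL)
  if (diff(range(xs)) < 1e-12) return(NULL) # constant segment
  scan <- .cpp_cbs_scan(xs, params$min_width, params$window,
                        params$max_exhaustive)
  if (!is.finite(scan$stat) || scan$stat <= 0) return(NULL)
  limit <- floor(params$alpha * params$nperm)
  count <- 0L
  b <- 0L
  while (b < params$nperm) {
    b <- b + 1L
    xp <- xs[sample.int(n)]
    if (.cpp_cbs_exceeds(xp, scan$stat, params$min_width, params$window,
                         params$max_exhaustive)) {
      count <- count + 1L
      if (count > limit) return(NULL)
    }
  }
  list(i = as.integer(scan$i), j = as.integer(scan$j), p = count / params$nperm)
}

# Recursive CBS over one chromosome's values. Returns a matrix of 1-based
# inclusive (start, end) index ranges, left to right. Pieces of an accepted
# split are processed left to right, depth first (this fixed order also
# fixes the permutation stream).
.cbs_chrom <- function(x, params) {
  rec <- function(lo, hi) {
    n <- hi - lo + 1
    if (n >= 2 * params$min_width) {
      split <- .cbs_find_split(x[lo:hi], params)
      if (!is.null(split)) {
        i <- split$i # boundaries 0-based within [lo, hi]
        j <- split$j
        out <- list()
        if (i > 0) out <- c(out, rec(lo, lo + i - 1))
        out <- c(out, rec(lo + i, lo + j - 1))
        if (lo + j <= hi) out <- c(out, rec(lo + j, hi))
        return(out)
      }
    }
    list(c(lo, hi))
  }
  do.call(rbind, rec(1L, length(x)))
}

#' Circular binary segmentation of a log2 profile
#'
#' Per chromosome, recursively finds the arc maximizing the two-sample
#' t-like statistic between in-arc and out-of-arc probes, accepts the split
#' iff its permutation p-value is at most `alpha` (probe values permuted
#' within the tested segment), and recurses on the resulting pieces.
#' Segments longer than `params$max_exhaustive` probes are scanned with
#' overlapping windows (see [cbs_params()]); the permutation test uses the
#' identical windowed statistic, so its calibration is unaffected.
#'
#' Deterministic for fixed `params` (the seed governs the permutation
#' stream), and shift-equivariant: segmenting `profile + c` gives identical
#' breakpoints with means shifted by `c`.
#'
#' @param profile A [log2_profile()].
#' @param params A [cbs_params()].
#' @return An object of class `SegmentedProfile`: a `segments` data.frame
#'   (`chrom`, `start`, `end` in 0-based half-open bp, `n_probes`, `mean`,
#'   `idx_start`, `idx_end` half-open probe indices into the profile) plus
#'   the parameters used.
#' @export
cbs_segment <- function(profile, params = cbs_params()) {
  stopifnot(inherits(profile, "Log2Profile"), inherits(params, "CbsParams"))
  if (any(!is.finite(profile$values))) stop("non-finite profile values")
  chroms <- unique(profile$probes$chrom)
  bad <- setdiff(chroms, profile$chrom_order)
  if (length(bad) > 0) {
    stop("chromosome(s) absent from chrom_order: ", paste(bad, collapse = ", "))
  }
  set.seed(params$seed)
  seg_list <- list()
  offset <- 0L
  for (chrom in chroms) {
    sel <- which(profile$probes$chrom == chrom)
    x <- profile$values[sel]
    ranges <- .cbs_chrom(x, params)
    p <- profile$probes[sel, , drop = FALSE]
    seg_list[[chrom]] <- data.frame(
      chrom = chrom,
      start = p$start[ranges[, 1]],
      end = p$end[ranges[, 2]],
      n_probes = ranges[, 2] - ranges[, 1] + 1L,
      mean = vapply(seq_len(nrow(ranges)),
                    function(k) mean(x[ranges[k, 1]:ranges[k, 2]]),
                    numeric(1)),
      idx_start = offset + ranges[, 1] - 1L, # half-open global probe indices
      idx_end = offset + ranges[, 2],
      stringsAsFactors = FALSE
    )
    offset <- offset + length(sel)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  structure(
    list(sample_id = profile$sample_id, segments = segments, params = params,
         n_values = length(profile$values)),
    class = "SegmentedProfile"
  )
}

#' @export
print.SegmentedProfile <- function(x, ...) {
  cat(sprintf("SegmentedProfile '%s': %d segments over %d probes\n",
              x$sample_id, nrow(x$segments), x$n_values))
  invisible(x)
}
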