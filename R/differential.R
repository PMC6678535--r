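#' Profile dynamics (interquartile range)
#'
#' The dynamics of a profile is the IQR of its probe values
#' (linear-interpolation quantiles), used to decide which member of a pair
#' is regression-rescaled before differencing.
#'
#' @param profile A [log2_profile()] with at least 4 probes.
#' @return The IQR as a single number.
#' @export
profile_dynamics <- function(profile) {
  stopifnot(inherits(profile, "Log2Profile"))
  if (length(profile$values) < 4) stop("profile_dynamics needs >= 4 probes")
  unname(diff(stats::quantile(profile$values, c(0.25, 0.75), type = 7)))
}

.intersect_pair <- function(a, b, max_loss = 0.05) {
  shared <- intersect(a$probes$probe_id, b$probes$probe_id)
  n_max <- max(length(a$values), length(b$values))
  loss <- 1 - length(shared) / n_max
  if (loss > max_loss) {
    stop(sprintf("probe universes differ by %.1f%% (> %.0f%%): mismatched designs",
                 100 * loss, 100 * max_loss))
  }
  sub <- function(p) {
    keep <- p$probes$probe_id %in% shared
    p$values <- p$values[keep]
    p$probes <- p$probes[keep, , drop = FALSE]
    rownames(p$probes) <- NULL
    p
  }
  a2 <- sub(a)
  b2 <- sub(b)
  # align b to a's genome order by probe_id
  m <- match(a2$probes$probe_id, b2$probes$probe_id)
  b2$values <- b2$values[m]
  b2$probes <- b2$probes[m, , drop = FALSE]
  rownames(b2$probes) <- NULL
  list(a = a2, b = b2, n_dropped = n_max - length(shared))
}

#' Dynamics-scale a pair of profiles onto a common scale
#'
#' Identifies the profile with the lowest dynamics (smallest probe-value
#' IQR) and maps it onto the other by ordinary least squares
#' `high ~ slope * low + intercept`, after which the low-dynamics
#' profile's probe values are replaced by the fitted transform. The
#' high-dynamics profile is untouched. IQRs differing by less than
#' `tie_epsilon` (relative) are below the measurement resolution of the
#' IQR on dense arrays and are treated as ties, resolved by `sample_id`
#' order (in conventional paired naming the parental line sorts first,
#' matching the usual direction of the published procedure).
#'
#' With `method = "segments"` (the default) the regression is fitted on
#' segment-mean-expanded values (each probe represented by the mean of its
#' CBS segment, each profile segmented separately): averaging within
#' segments suppresses the probe-noise attenuation that biases a
#' probe-value regression towards zero whenever aberrations cover a small
#' fraction of the genome. Because the fit's purpose is to align the
#' dynamic range of the aberrations the two samples share, probes whose
#' segmental state (gain/neutral/loss relative to each profile's own
#' calling threshold) disagrees between the profiles -- candidate private
#' lesions -- are excluded from the regression; if no concordant aberrant
#' structure exists at all (e.g. two flat profiles), the transform falls
#' back to a pure level shift (slope 1). `method = "probes"` fits on raw
#' probe values with no trimming.
#'
#' @param a,b [log2_profile()]s on the same probe universe (intersected by
#'   `probe_id`; designs losing more than 5% of probes are rejected).
#' @param method Fit the regression on segment-mean expansions
#'   (`"segments"`, default) or raw probe values (`"probes"`).
#' @param cbs [cbs_params()] used to segment the profiles when
#'   `method = "segments"`.
#' @param tie_epsilon Relative IQR difference below which the dynamics
#'   comparison is treated as a tie.
#' @return List `a`, `b` (same identities as the inputs, one rescaled) and
#'   `fit`, a `ScalingFit` with `low_sample`, `high_sample`, `slope`,
#'   `intercept`, `iqr_low`, `iqr_high`, `n_dropped`.
#' @export
scale_pair <- function(a, b, method = c("segments", "probes"),
                       cbs = cbs_params(), tie_epsilon = 0.02) {
  stopifnot(inherits(a, "Log2Profile"), inherits(b, "Log2Profile"))
  method <- match.arg(method)
  pr <- .intersect_pair(a, b)
  a <- pr$a
  b <- pr$b
  iqr_a <- profile_dynamics(a)
  iqr_b <- profile_dynamics(b)
  rel_gap <- abs(iqr_a - iqr_b) / max(iqr_a, iqr_b, .Machine$double.eps)
  a_is_low <- if (rel_gap <= tie_epsilon) {
    order(c(a$sample_id, b$sample_id))[1] == 1
  } else iqr_a < iqr_b
  low <- if (a_is_low) a else b
  high <- if (a_is_low) b else a
  if (method == "probes" && stats::sd(low$values) < 1e-12) {
    stop("degenerate regression: low-dynamics profile '", low$sample_id,
         "' has zero variance")
  }
  if (method == "segments") {
    expand <- function(p) {
      s <- cbs_segment(p, cbs)$segments
      rep(s$mean, s$n_probes)
    }
    x <- expand(low)
    y <- expand(high)
    # aberration state relative to each profile's own level (median), so
    # a global level offset between the profiles does not mask concordance
    state <- function(v, thr) {
      v <- v - stats::median(v)
      (v > thr) - (v < -thr)
    }
    sx <- state(x, suppressWarnings(calling_threshold(low)$value))
    sy <- state(y, suppressWarnings(calling_threshold(high)$value))
    keep <- sx == sy
    if (!any(keep)) keep <- rep(TRUE, length(x))
    structured <- keep & sx != 0L
    if (!any(structured) || stats::sd(x[keep]) < 1e-10) {
      slope <- 1
      intercept <- mean(y[keep]) - mean(x[keep])
    } else {
      fit <- stats::lm(y[keep] ~ x[keep])
      slope <- unname(stats::coef(fit)[2])
      intercept <- unname(stats::coef(fit)[1])
    }
  } else {
    x <- low$values
    y <- high$values
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  low$values <- slope * low$values + intercept
  low$normalization_log <- c(low$normalization_log, "dynamics_scale")
  scaling <- structure(
    list(low_sample = low$sample_id, high_sample = high$sample_id,
         slope = slope, intercept = intercept,
         iqr_low = min(iqr_a, iqr_b), iqr_high = max(iqr_a, iqr_b),
         n_dropped = pr$n_dropped),
    class = "ScalingFit"
  )
  if (a_is_low) list(a = low, b = high, fit = scaling)
  else list(a = high, b = low, fit = scaling)
}

#' Annotate regions with overlapping genes and cytobands
#'
#' Overlap is half-open with at least 1 bp; a gene or band spanning a
#' region boundary is reported for every region it touches.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and any other columns, e.g. non-neutral segments.
#' @param ann A [genome_annotation()].
#' @return `regions` with list-columns `genes` and `cytobands` appended.
#' @export
annotate_regions <- function(regions, ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  hits_for <- function(df) {
    if (nrow(regions) == 0 || nrow(df) == 0) {
      return(replicate(nrow(regions), character(0), simplify = FALSE))
    }
    q <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(start = regions$start + 1, end = regions$end))
    s <- .annotation_granges(df)
    ov <- GenomicRanges::findOverlaps(q, s)
    lapply(seq_len(nrow(regions)), function(i) {
      df$name[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    })
  }
  regions$genes <- I(hits_for(ann$genes))
  regions$cytobands <- I(hits_for(ann$cytobands))
  regions
}

#' Differential copy-number regions between two profiles
#'
#' The paired comparison: [scale_pair()] the two profiles, compute the
#' probe-wise difference `test - ref` (oriented so positive values are
#' gains acquired in `test` regardless of which side was rescaled), derive
#' the calling threshold from the difference profile itself, segment the
#' difference with CBS, call gains/losses, and annotate every non-neutral
#' segment. Segment means of the difference are the `diff_l2r` statistic.
#'
#' @param test,ref Normalized (and nominally centered) [log2_profile()]s;
#'   `test` is the resistant/test sample, `ref` the parental/reference.
#' @param cbs A [cbs_params()].
#' @param ann Optional [genome_annotation()] for region annotation.
#' @param threshold_source Profile from which the calling threshold is
#'   computed: the difference itself (default), or the test/ref input.
#' @return A `DifferentialResult`: `diff_profile`, `called`
#'   (CalledSegmentedProfile of the difference), `scaling`, `threshold`
#'   and `regions` (annotated non-neutral segments with `diff_l2r`, sorted
#'   by `|diff_l2r|` descending).
#' @export
differential_regions <- function(test, ref, cbs = cbs_params(), ann = NULL,
                                 threshold_source = c("diff", "test", "ref")) {
  stopifnot(inherits(test, "Log2Profile"), inherits(ref, "Log2Profile"))
  threshold_source <- match.arg(threshold_source)
  sp <- scale_pair(test, ref, cbs = cbs)
  test_s <- sp$a
  ref_s <- sp$b
  diff_profile <- log2_profile(
    probes = test_s$probes,
    values = test_s$values - ref_s$values,
    sample_id = paste0(test$sample_id, "-vs-", ref$sample_id),
    chrom_order = test$chrom_order,
    normalization_log = c(test_s$normalization_log, "difference")
  )
  thr_profile <- switch(threshold_source,
                        diff = diff_profile, test = test_s, ref = ref_s)
  threshold <- calling_threshold(thr_profile)
  segmented <- cbs_segment(diff_profile, cbs)
  called <- call_segments(segmented, threshold)
  seg <- called$segments
  regions <- seg[seg$call != "neutral",
                 c("chrom", "start", "end", "n_probes", "mean", "call"),
                 drop = FALSE]
  names(regions)[names(regions) == "mean"] <- "diff_l2r"
  regions <- regions[order(abs(regions$diff_l2r), decreasing = TRUE), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  if (!is.null(ann)) regions <- annotate_regions(regions, ann)
  structure(
    list(diff_profile = diff_profile, called = called, scaling = sp$fit,
         threshold = threshold, regions = regions),
    class = "DifferentialResult"
  )
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf(
    "DifferentialResult %s: %d differential region(s), threshold %.4f\n",
    x$diff_profile$sample_id, nrow(x$regions), x$threshold$value))
  cat(sprintf("  scaling: %s -> %s, slope %.4f, intercept %.4f\n",
              x$scaling$low_sample, x$scaling$high_sample,
              x$scaling$slope, x$scaling$intercept))
  if (nrow(x$regions) > 0) {
    top <- utils::head(x$regions, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s:%d-%d  Diff.l2r %+0.4f  %s\n", top$chrom[i],
                  top$start[i] + 1, top$end[i], top$diff_l2r[i], top$call[i]))
    }
  }
  invisible(x)
}

#' Export differential regions as TSV
#'
#' Columns: `chrom`, `start`, `end` (1-based inclusive), `n_probes`,
#' `diff_l2r`, `call`, `cytobands`, `genes` (semicolon-joined).
#'
#' @param result A [differential_regions()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(result, path) {
  stopifnot(inherits(result, "DifferentialResult"))
  r <- result$regions
  join <- function(col) {
    if (is.null(col)) rep("", nrow(r))
    else vapply(col, function(x) paste(x, collapse = ";"), "")
  }
  out <- data.frame(
    chrom = r$chrom,
    start = if (nrow(r)) format(r$start + 1, scientific = FALSE, trim = TRUE) else character(0),
    end = if (nrow(r)) format(r$end, scientific = FALSE, trim = TRUE) else character(0),
    n_probes = r$n_probes,
    diff_l2r = if (nrow(r)) sprintf("%.6f", r$diff_l2r) else character(0),
    call = r$call,
    cytobands = join(r$cytobands),
    genes = join(r$genes),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
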