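# Loess curve helper shared by the dye and GC corrections. Fits on a
# uniform (by predictor order) subsample of at most `max_fit` points for
# tractability on 180K-probe arrays, then interpolates the fitted curve at
# all predictor values. Robustness iterations downweight outlier probes.
#
# With trim_tails > 0 the curve is estimated only on the central
# (1 - 2 * trim_tails) range of the predictor and extended linearly
# beyond it using the boundary slope of the fit. Probes outside the bulk
# predictor range (e.g. probes of a high-level amplification, which can
# locally dominate the extreme intensity tail) are then corrected by the
# extrapolated bulk trend instead of by a tail fit they themselves drive.
.loess_curve <- function(x, y, span = 0.3, degree = 1, iterations = 3,
                         max_fit = 20000, trim_tails = 0) {
  n <- length(x)
  lims <- if (trim_tails > 0) {
    stats::quantile(x, c(trim_tails, 1 - trim_tails), names = FALSE)
  } else range(x)
  inside <- x >= lims[1] & x <= lims[2]
  xi <- x[inside]
  yi <- y[inside]
  ni <- length(xi)
  ord <- order(xi)
  idx <- if (ni > max_fit) ord[unique(round(seq(1, ni, length.out = max_fit)))] else ord
  fit <- stats::loess(
    y ~ x, data = data.frame(x = xi[idx], y = yi[idx]),
    span = span, degree = degree, family = "symmetric",
    control = stats::loess.control(surface = "interpolate",
                                   statistics = "approximate",
                                   iterations = iterations)
  )
  m <- min(2000L, length(idx))
  grid <- seq(min(xi), max(xi), length.out = m)
  pred <- stats::predict(fit, newdata = data.frame(x = grid))
  ok <- is.finite(pred)
  grid <- grid[ok]
  pred <- pred[ok]
  out <- stats::approx(grid, pred, xout = x, rule = 2)$y
  m <- length(grid)
  k <- max(2L, round(0.1 * m))
  lo <- x < grid[1]
  if (any(lo)) {
    s <- (pred[k] - pred[1]) / (grid[k] - grid[1])
    out[lo] <- pred[1] + s * (x[lo] - grid[1])
  }
  hi <- x > grid[m]
  if (any(hi)) {
    s <- (pred[m] - pred[m - k + 1]) / (grid[m] - grid[m - k + 1])
    out[hi] <- pred[m] + s * (x[hi] - grid[m])
  }
  out
}

#' Dye-composition normalization (Cy3 fitted over Cy5)
#'
#' Corrects intensity-dependent dye bias by locally weighted regression of
#' log2(reference) on log2(test) across probes: the fitted curve
#' `f(a) = E[log2 ref | log2 test = a]` is the systematic dye trend, and the
#' reference channel is rescaled by `2^(a - f(a))` so that, locally in
#' intensity, the two channels agree in expectation. The test channel is
#' left untouched. The trend is estimated on the central 99.5% of test
#' intensities and extended linearly beyond them, so probes outside the
#' bulk intensity range (e.g. probes of a high-level amplification) are
#' corrected by the extrapolated bulk trend rather than by a tail fit
#' they themselves dominate.
#'
#' @param raw A [probe_set()] with strictly positive intensities.
#' @param span,degree,iterations Loess settings (span 0.3, degree 1, 3
#'   robustness iterations by default).
#' @param max_fit Maximum number of probes used for the fit; the curve is
#'   interpolated for the rest.
#' @return The ProbeSet with a corrected reference channel and
#'   `"dye_normalize"` appended to its normalization log.
#' @export
dye_normalize <- function(raw, span = 0.3, degree = 1, iterations = 3,
                          max_fit = 20000) {
  stopifnot(inherits(raw, "ProbeSet"))
  n <- nrow(raw$probes)
  if (n < 50) stop("dye_normalize needs >= 50 probes; got ", n)
  if (any(raw$probes$intensity_test <= 0) ||
      any(raw$probes$intensity_ref <= 0)) {
    stop("non-positive intensities; filter before normalizing")
  }
  a <- log2(raw$probes$intensity_test)
  b <- log2(raw$probes$intensity_ref)
  f <- .loess_curve(a, b, span = span, degree = degree,
                    iterations = iterations, max_fit = max_fit,
                    trim_tails = 0.0025)
  raw$probes$intensity_ref <- 2^(b - (f - a))
  raw$normalization_log <- c(raw$normalization_log, "dye_normalize")
  raw
}

#' Transform a ProbeSet into a log2(Test/Ref) profile
#'
#' @param normed A ProbeSet, normally after [dye_normalize()]. Set
#'   `require_dye_norm = FALSE` to transform raw intensities explicitly.
#' @param require_dye_norm Refuse to transform a set whose normalization log
#'   does not record dye normalization.
#' @return An object of class `Log2Profile`: genome-ordered probe
#'   coordinates (with GC carried along) and per-probe
#'   `log2(intensity_test / intensity_ref)` values.
#' @export
compute_log2_profile <- function(normed, require_dye_norm = TRUE) {
  stopifnot(inherits(normed, "ProbeSet"))
  if (require_dye_norm && !("dye_normalize" %in% normed$normalization_log)) {
    stop("ProbeSet is not dye-normalized; run dye_normalize() or pass ",
         "require_dye_norm = FALSE")
  }
  values <- log2(normed$probes$intensity_test / normed$probes$intensity_ref)
  if (any(!is.finite(values))) stop("non-finite log2 ratios")
  log2_profile(
    probes = normed$probes[c("probe_id", "chrom", "start", "end", "gc")],
    values = values, sample_id = normed$sample_id,
    chrom_order = normed$chrom_order,
    normalization_log = c(normed$normalization_log, "log2_ratio")
  )
}

#' Construct a Log2Profile
#'
#' @param probes data.frame `probe_id`, `chrom`, `start`, `end` and
#'   optionally `gc`, genome-ordered (re-sorted if not).
#' @param values Per-probe log2(Test/Ref) values aligned with `probes`.
#' @param sample_id Sample identifier.
#' @param chrom_order Chromosome ordering.
#' @param normalization_log Steps already applied.
#' @return An object of class `Log2Profile`.
#' @export
log2_profile <- function(probes, values, sample_id,
                         chrom_order = default_chrom_order(),
                         normalization_log = character(0)) {
  stopifnot(nrow(probes) == length(values))
  if (any(!is.finite(values))) stop("non-finite profile values")
  if (is.null(probes$gc)) probes$gc <- NA_real_
  probes <- probes[c("probe_id", "chrom", "start", "end", "gc")]
  ord <- .genome_order(probes, chrom_order)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  structure(
    list(sample_id = sample_id, probes = probes, values = values[ord],
         chrom_order = chrom_order, normalization_log = normalization_log),
    class = "Log2Profile"
  )
}

#' @export
print.Log2Profile <- function(x, ...) {
  cat(sprintf("Log2Profile '%s': %d probes, value range [%.3f, %.3f]\n",
              x$sample_id, length(x$values), min(x$values), max(x$values)))
  if (length(x$normalization_log) > 0) {
    cat("  steps:", paste(x$normalization_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' GC-content loess correction of a log2 profile
#'
#' Removes the mean effect of local GC content by subtracting the centered
#' loess fit of value versus GC fraction: the profile's overall level is
#' preserved, only GC-dependent waviness is removed. Idempotent to within
#' fit tolerance.
#'
#' @param profile A [log2_profile()].
#' @param gc Per-probe GC fractions in `[0, 1]`; defaults to the `gc`
#'   column carried in the profile.
#' @inheritParams dye_normalize
#' @return The corrected profile, with `"gc_correct"` appended to its
#'   normalization log. A constant GC vector leaves the profile untouched
#'   with a warning.
#' @export
gc_correct <- function(profile, gc = NULL, span = 0.3, degree = 1,
                       iterations = 3, max_fit = 20000) {
  stopifnot(inherits(profile, "Log2Profile"))
  if (is.null(gc)) gc <- profile$probes$gc
  if (length(gc) != length(profile$values)) {
    stop("gc vector not aligned with profile")
  }
  if (any(is.na(gc)) || any(gc < 0 | gc > 1)) {
    stop("gc fractions must be in [0, 1] with no missing values")
  }
  if (diff(range(gc)) < 1e-12) {
    warning("constant GC vector; gc_correct is a no-op")
    return(profile)
  }
  f <- .loess_curve(gc, profile$values, span = span, degree = degree,
                    iterations = iterations, max_fit = max_fit)
  profile$values <- profile$values - (f - mean(f))
  profile$normalization_log <- c(profile$normalization_log, "gc_correct")
  profile
}
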