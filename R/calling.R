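#' Center a profile on the most centered of its three most populated
#' density peaks
#'
#' Estimates the probe-value density by Gaussian KDE (Silverman bandwidth,
#' 2,048-point grid spanning the value range), finds local maxima (grid
#' points higher than both neighbors), ranks them by density height, and
#' among the top three (fewer if fewer exist) picks the one closest to zero
#' (`rule = "nearest_zero"`, the default) or closest to the distribution's
#' mean (`rule = "center_of_mass"`). The chosen peak location is subtracted
#' from all probe values and, when supplied, from all segment means.
#'
#' @param profile A [log2_profile()] with at least 100 probes.
#' @param segmented Optional matching [cbs_segment()] result whose segment
#'   means are shifted by the same offset.
#' @param rule Which of the top peaks is "most centered".
#' @return List with elements `profile`, `segmented` (NULL if not given)
#'   and `centering`, a `CenteringResult`: `offset`, `peak_locations`
#'   (up to three, by population rank), `chosen_peak_index` (1-based into
#'   `peak_locations`), `bandwidth`.
#' @export
center_profile <- function(profile, segmented = NULL,
                           rule = c("nearest_zero", "center_of_mass")) {
  stopifnot(inherits(profile, "Log2Profile"))
  rule <- match.arg(rule)
  v <- profile$values
  if (length(v) < 100) stop("center_profile needs >= 100 probes")
  d <- stats::density(v, bw = "nrd0", n = 2048, from = min(v), to = max(v))
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] > y[3:n], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) == 0) stop("degenerate density: no peaks found")
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  top <- peaks[seq_len(min(3L, length(peaks)))]
  locs <- d$x[top]
  anchor <- if (rule == "nearest_zero") 0 else mean(v)
  chosen <- which.min(abs(locs - anchor))
  offset <- locs[chosen]
  profile$values <- profile$values - offset
  profile$normalization_log <- c(profile$normalization_log, "center")
  if (!is.null(segmented)) {
    stopifnot(inherits(segmented, "SegmentedProfile"))
    segmented$segments$mean <- segmented$segments$mean - offset
  }
  centering <- structure(
    list(offset = offset, peak_locations = locs,
         chosen_peak_index = chosen, bandwidth = d$bw),
    class = "CenteringResult"
  )
  list(profile = profile, segmented = segmented, centering = centering)
}

#' Derivative-median calling threshold
#'
#' One-fourth of the median absolute difference between consecutive
#' log2(Test/Ref) values along the genome. By default pairs straddling a
#' chromosome junction are excluded (they contribute artifactual jumps);
#' set `include_junctions = TRUE` for the literal all-consecutive-pairs
#' reading (the median shifts by well under 0.1% on dense arrays).
#'
#' @param profile A [log2_profile()] with at least 2 probes.
#' @param include_junctions Include inter-chromosome consecutive pairs.
#' @return A `CallThreshold`: `value` (median/4) and `n_pairs` used. A
#'   constant profile yields value 0 with a warning.
#' @export
calling_threshold <- function(profile, include_junctions = FALSE) {
  stopifnot(inherits(profile, "Log2Profile"))
  v <- profile$values
  if (length(v) < 2) stop("calling_threshold needs >= 2 probes")
  dv <- abs(diff(v))
  if (!include_junctions) {
    same <- profile$probes$chrom[-1] == profile$probes$chrom[-length(v)]
    dv <- dv[same]
  }
  if (length(dv) == 0) stop("no within-chromosome consecutive pairs")
  value <- stats::median(dv) / 4
  if (value == 0 && diff(range(v)) < 1e-12) {
    warning("degenerate (constant) profile: threshold is 0")
  }
  structure(list(value = value, n_pairs = length(dv)),
            class = "CallThreshold")
}

#' Call gains and losses on a segmented profile
#'
#' Ternary call per segment: `gain` iff mean > +threshold, `loss` iff
#' mean < -threshold, else `neutral` (strict inequalities: a mean exactly
#' at the threshold is neutral). The profile is assumed centered.
#'
#' @param segmented A [cbs_segment()] result (means already centered).
#' @param threshold A [calling_threshold()] result.
#' @param centering Optional `CenteringResult` to attach for provenance.
#' @return A `CalledSegmentedProfile`: the segmented profile with a `call`
#'   column plus `threshold`, `centering`, `n_gain`, `n_loss`.
#' @export
call_segments <- function(segmented, threshold, centering = NULL) {
  stopifnot(inherits(segmented, "SegmentedProfile"),
            inherits(threshold, "CallThreshold"))
  m <- segmented$segments$mean
  call <- rep("neutral", length(m))
  eps <- 1e-9 # guard against float dust when the threshold is exactly 0
  call[m > threshold$value + eps] <- "gain"
  call[m < -threshold$value - eps] <- "loss"
  segmented$segments$call <- call
  segmented$threshold <- threshold
  segmented$centering <- centering
  segmented$n_gain <- sum(call == "gain")
  segmented$n_loss <- sum(call == "loss")
  class(segmented) <- c("CalledSegmentedProfile", class(segmented))
  segmented
}

#' @export
print.CalledSegmentedProfile <- function(x, ...) {
  cat(sprintf(
    "CalledSegmentedProfile '%s': %d segments (%d gain, %d loss), threshold %.4f\n",
    x$sample_id, nrow(x$segments), x$n_gain, x$n_loss, x$threshold$value))
  invisible(x)
}
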