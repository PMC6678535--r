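# Shared fixture builders. Everything is generated in code; no stored data.

# A Log2Profile over one or more chromosomes with evenly spaced probes.
make_profile <- function(values, chrom = NULL, sample_id = "s1",
                         spacing = 10000, gc = NULL) {
  n <- length(values)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(gc)) gc <- rep(0.5, n)
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  probes <- data.frame(
    probe_id = sprintf("P%06d", seq_len(n)),
    chrom = chrom,
    start = (idx - 1) * spacing,
    end = (idx - 1) * spacing + 60,
    gc = gc,
    stringsAsFactors = FALSE
  )
  log2_profile(probes, values, sample_id = sample_id)
}

# A small ProbeSet with given log2 ratios and flat intensities.
make_probe_set <- function(log2_ratio, sample_id = "s1", base = 1000) {
  n <- length(log2_ratio)
  df <- data.frame(
    probe_id = sprintf("P%06d", seq_len(n)),
    chrom = rep("chr1", n),
    start = (seq_len(n) - 1) * 10000,
    end = (seq_len(n) - 1) * 10000 + 60,
    intensity_test = base * 2^log2_ratio,
    intensity_ref = rep(base, n),
    gc = rep(0.5, n),
    stringsAsFactors = FALSE
  )
  probe_set(df, sample_id = sample_id)
}

# Match called differential regions against the generator's acquired truth:
# each acquired region must be hit by exactly one called region of the
# right sign; anything unmatched counts as extra.
match_acquired <- function(regions, truth) {
  acq <- truth[truth$scope == "resistant_only", , drop = FALSE]
  used <- rep(FALSE, nrow(regions))
  hits <- integer(nrow(acq))
  errs <- rep(NA_real_, nrow(acq))
  for (i in seq_len(nrow(acq))) {
    ov <- which(regions$chrom == acq$chrom[i] & regions$start < acq$end[i] &
                  regions$end > acq$start[i] & !used)
    hits[i] <- length(ov)
    if (length(ov) >= 1) {
      used[ov[1]] <- TRUE
      errs[i] <- abs(regions$diff_l2r[ov[1]] - acq$delta_log2[i])
    }
  }
  list(hits = hits, n_extra = nrow(regions) - sum(used), errs = errs)
}
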