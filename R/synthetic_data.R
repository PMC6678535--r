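#' hg19-like chromosome lengths
#'
#' Hard-coded hg19 chromosome lengths (bp) used to spread synthetic probes
#' proportionally; no reference genome is required.
#'
#' @return Named numeric vector, chr1..chr22, chrX, chrY.
#' @export
hg19_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516,
    chr12 = 133851895, chr13 = 115169878, chr14 = 107349540,
    chr15 = 102531392, chr16 = 90354753, chr17 = 81195210,
    chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Generate a synthetic array design
#'
#' Emulates a 180K-probe CGH array: probes are allocated to chromosomes
#' proportionally to chromosome length (largest-remainder rounding),
#' placed at jittered regular spacings, 60 bp long, with a smooth spatial
#' GC field in `[0.3, 0.7]` (a per-chromosome sum of three sinusoids with
#' random phases, wavelengths 50 Mb / 7 Mb / 1.3 Mb).
#'
#' @param n_probes Total probe count (>= 1,000).
#' @param chrom_lengths Named chromosome lengths; defaults to
#'   [hg19_chrom_lengths()].
#' @param seed Integer seed; the design is deterministic given it.
#' @return An `ArrayDesign`: `probes` data.frame (`probe_id`, `chrom`,
#'   `start`, `end`, `gc`, genome-ordered, 0-based half-open),
#'   `chrom_lengths`, `chrom_order`.
#' @export
generate_design <- function(n_probes = 180000,
                            chrom_lengths = hg19_chrom_lengths(),
                            seed = 1) {
  if (n_probes < 1000) stop("generate_design needs n_probes >= 1000")
  set.seed(seed)
  chrom_order <- names(chrom_lengths)
  share <- n_probes * chrom_lengths / sum(chrom_lengths)
  counts <- floor(share)
  rem <- n_probes - sum(counts)
  if (rem > 0) {
    extra <- order(share - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  probe_len <- 60
  dfs <- lapply(chrom_order, function(chrom) {
    m <- counts[[chrom]]
    if (m == 0) return(NULL)
    L <- chrom_lengths[[chrom]]
    spacing <- L / m
    start <- round((seq_len(m) - 0.5) * spacing +
                     stats::runif(m, -0.3, 0.3) * spacing)
    start <- pmin(pmax(start, 0), L - probe_len)
    start <- sort(start)
    # enforce strictly increasing starts
    start <- start + cummax(c(0, pmax(0, 1 - diff(start))))
    pos <- start + probe_len / 2
    ph <- stats::runif(3, 0, 2 * pi)
    gc <- 0.5 + 0.08 * sin(2 * pi * pos / 5e7 + ph[1]) +
      0.06 * sin(2 * pi * pos / 7e6 + ph[2]) +
      0.04 * sin(2 * pi * pos / 1.3e6 + ph[3])
    data.frame(chrom = chrom, start = start, end = start + probe_len,
               gc = pmin(0.7, pmax(0.3, gc)), stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, dfs)
  probes <- cbind(probe_id = sprintf("P%07d", seq_len(nrow(probes))), probes,
                  stringsAsFactors = FALSE)
  rownames(probes) <- NULL
  structure(
    list(probes = probes, chrom_lengths = chrom_lengths,
         chrom_order = chrom_order),
    class = "ArrayDesign"
  )
}

#' Specify ground-truth copy-number regions
#'
#' @param chrom,start,end Region coordinates (0-based half-open bp).
#' @param delta_log2 Non-zero log2-ratio shift of each region.
#' @param scope `"shared"` (present in both members of a pair) or
#'   `"resistant_only"` (acquired by the resistant member).
#' @return A `CnaSpec` data.frame.
#' @export
cna_spec <- function(chrom, start, end, delta_log2, scope) {
  stopifnot(all(scope %in% c("shared", "resistant_only")),
            all(delta_log2 != 0), all(start < end))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   delta_log2 = delta_log2, scope = scope,
                   stringsAsFactors = FALSE)
  class(df) <- c("CnaSpec", "data.frame")
  df
}

#' Draw a random non-overlapping CNA specification over a design
#'
#' Places `n_shared` baseline regions (both samples) and `n_acquired`
#' regions (resistant only) at random probe positions, mutually
#' non-overlapping, each spanning a uniform draw of `min_probes` to
#' `max_probes` probes. Default amplitudes span the magnitude range of
#' reported acquired differential regions (|Diff.l2r| up to ~4.7).
#'
#' @param design An [generate_design()] result.
#' @param n_shared,n_acquired Region counts.
#' @param min_probes,max_probes Region widths in probes.
#' @param shared_amplitudes,acquired_amplitudes Candidate `delta_log2`
#'   values sampled uniformly.
#' @param seed Integer seed.
#' @return A [cna_spec()].
#' @export
random_cna_spec <- function(design, n_shared = 5, n_acquired = 3,
                            min_probes = 80, max_probes = 200,
                            shared_amplitudes = c(-1, -0.58, 0.58, 1),
                            acquired_amplitudes = c(-4.7, -3.2, -1, -0.58,
                                                    0.58, 1, 3.2, 4.7),
                            seed = 1) {
  set.seed(seed)
  probes <- design$probes
  n_total <- n_shared + n_acquired
  taken <- logical(nrow(probes)) # probes already inside a region
  rows <- vector("list", n_total)
  widths <- min_probes:max_probes
  for (r in seq_len(n_total)) {
    w <- widths[sample.int(length(widths), 1)]
    for (try in 1:1000) {
      i0 <- sample(nrow(probes) - w, 1)
      idx <- i0:(i0 + w - 1)
      if (length(unique(probes$chrom[idx])) > 1) next
      if (any(taken[idx])) next
      taken[idx] <- TRUE
      amp_pool <- if (r <= n_shared) shared_amplitudes else acquired_amplitudes
      rows[[r]] <- data.frame(
        chrom = probes$chrom[i0], start = probes$start[i0],
        end = probes$end[i0 + w - 1],
        # index draw: sample() on a length-1 pool would expand it to 1:x
        delta_log2 = amp_pool[sample.int(length(amp_pool), 1)],
        scope = if (r <= n_shared) "shared" else "resistant_only",
        stringsAsFactors = FALSE)
      break
    }
    if (is.null(rows[[r]])) stop("could not place non-overlapping regions")
  }
  df <- do.call(rbind, rows)
  cna_spec(df$chrom, df$start, df$end, df$delta_log2, df$scope)
}

#' Noise and bias model for the probe simulator
#'
#' @param probe_noise_sd SD of Gaussian log2-ratio noise per probe
#'   (split evenly between the two channels in log space).
#' @param gc_bias Length-2 numeric `(linear, quadratic)` coefficients of
#'   the GC-dependent log2-ratio bias in `(gc - 0.5)`.
#' @param dye_bias Amplitude of the intensity-dependent dye bias added to
#'   the reference channel in log2 space (proportional to the centered
#'   test-channel log intensity, the covariate the dye correction
#'   conditions on).
#' @param outlier_rate Fraction of probes receiving an extra heavy-tailed
#'   (t, 3 df) log2-ratio perturbation; at most 0.01.
#' @return A `NoiseModel`.
#' @export
noise_model <- function(probe_noise_sd = 0.25, gc_bias = c(0.15, 0.3),
                        dye_bias = 0.1, outlier_rate = 0.001) {
  stopifnot(probe_noise_sd >= 0, length(gc_bias) == 2,
            outlier_rate >= 0, outlier_rate <= 0.01)
  structure(list(probe_noise_sd = probe_noise_sd, gc_bias = gc_bias,
                 dye_bias = dye_bias, outlier_rate = outlier_rate),
            class = "NoiseModel")
}

.true_log2 <- function(probes, cna, scopes) {
  v <- numeric(nrow(probes))
  keep <- cna$scope %in% scopes
  for (r in which(keep)) {
    hit <- probes$chrom == cna$chrom[r] &
      probes$start < cna$end[r] & probes$end > cna$start[r]
    v[hit] <- v[hit] + cna$delta_log2[r]
  }
  v
}

#' Simulate a paired parental/resistant hybridization
#'
#' Ground truth: per-probe true log2 ratio is the sum of the deltas of the
#' covering regions (shared regions in both samples, `resistant_only`
#' added to the resistant sample). Channel intensities are back-computed
#' as `ref = lognormal base`, `test = ref * 2^(true log2)`; GC bias (on
#' the test channel) and intensity-dependent dye bias (on the reference
#' channel) are applied in log2 space; Gaussian noise is split between
#' channels; a small fraction of probes receives heavy-tailed outliers.
#'
#' @param design An [generate_design()] result.
#' @param cna A [cna_spec()]; overlapping regions of the same scope are an
#'   error (ambiguous truth).
#' @param noise A [noise_model()].
#' @param seed Integer seed; output is fully deterministic given it.
#' @param sample_ids Length-2 ids for (parental, resistant).
#' @return List `parental` and `resistant` ([probe_set()]s) plus `truth`,
#'   the CnaSpec with per-region probe counts appended.
#' @export
simulate_pair <- function(design, cna, noise = noise_model(), seed = 1,
                          sample_ids = c("parental", "resistant")) {
  stopifnot(inherits(design, "ArrayDesign"), inherits(cna, "CnaSpec"))
  for (sc in unique(cna$scope)) {
    sub <- cna[cna$scope == sc, , drop = FALSE]
    if (nrow(sub) > 1) {
      for (i in seq_len(nrow(sub) - 1)) {
        later <- (i + 1):nrow(sub)
        clash <- sub$chrom[later] == sub$chrom[i] &
          sub$start[later] < sub$end[i] & sub$end[later] > sub$start[i]
        if (any(clash)) stop("overlapping regions of scope '", sc,
                             "': ambiguous truth")
      }
    }
  }
  set.seed(seed)
  probes <- design$probes
  n <- nrow(probes)
  true_par <- .true_log2(probes, cna, "shared")
  true_res <- .true_log2(probes, cna, c("shared", "resistant_only"))
  # lognormal base channel; the wide spread emulates probe-affinity
  # variation (real two-channel arrays span several orders of magnitude)
  ref_log2 <- stats::rnorm(n, mean = 10, sd = 1.6)
  gcc <- probes$gc - 0.5
  gc_shift <- noise$gc_bias[1] * gcc + noise$gc_bias[2] * gcc^2
  ch_sd <- noise$probe_noise_sd / sqrt(2)
  one_sample <- function(true_log2, id) {
    test_log2 <- ref_log2 + true_log2 + gc_shift + stats::rnorm(n, 0, ch_sd)
    ref_obs <- ref_log2 + stats::rnorm(n, 0, ch_sd)
    # dye bias modeled as a smooth function of the test-channel intensity,
    # the covariate the dye correction conditions on
    ref_obs <- ref_obs + noise$dye_bias * (test_log2 - mean(test_log2))
    if (noise$outlier_rate > 0) {
      n_out <- round(noise$outlier_rate * n)
      if (n_out > 0) {
        out_idx <- sample.int(n, n_out)
        test_log2[out_idx] <- test_log2[out_idx] +
          stats::rt(n_out, df = 3) * 2 * noise$probe_noise_sd
      }
    }
    df <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                     start = probes$start, end = probes$end,
                     intensity_test = 2^test_log2, intensity_ref = 2^ref_obs,
                     gc = probes$gc, stringsAsFactors = FALSE)
    probe_set(df, sample_id = id, chrom_order = design$chrom_order)
  }
  parental <- one_sample(true_par, sample_ids[1])
  resistant <- one_sample(true_res, sample_ids[2])
  truth <- cna
  truth$n_probes <- vapply(seq_len(nrow(cna)), function(r) {
    sum(probes$chrom == cna$chrom[r] & probes$start < cna$end[r] &
          probes$end > cna$start[r])
  }, integer(1))
  list(parental = parental, resistant = resistant, truth = truth)
}

#' Simulate a dose-response experiment
#'
#' Responses follow the 4PL curve of `truth` plus Gaussian noise, clipped
#' at zero.
#'
#' @param truth List with `top`, `bottom`, `hill`, `ic50` (uM); `ic50`
#'   must lie within the dose range.
#' @param doses Non-zero concentrations (uM).
#' @param replicates Replicates per dose.
#' @param noise_sd Response noise SD.
#' @param seed Integer seed.
#' @param compound,sample_id Labels.
#' @return A [dose_response_data()].
#' @export
simulate_dose_response <- function(truth, doses, replicates = 3,
                                   noise_sd = 0.05, seed = 1,
                                   compound = "drug", sample_id = "sample") {
  stopifnot(truth$ic50 >= min(doses), truth$ic50 <= max(doses))
  set.seed(seed)
  d <- rep(doses, each = replicates)
  mu <- .fourpl(d, truth$top, truth$bottom, truth$hill, truth$ic50)
  y <- pmax(0, mu + stats::rnorm(length(d), 0, noise_sd))
  dose_response_data(compound, sample_id, d, y,
                     replicate = rep(seq_len(replicates), length(doses)))
}

#' Write a synthetic annotation fixture over a design
#'
#' Builds a simple cytoband table (each chromosome cut into `bands_per_chrom`
#' equal bands, named like `p1..` / `q1..`) and, optionally, takes a gene
#' table as given. Purely synthetic coordinates for testing and demos.
#'
#' @param design An [generate_design()] result.
#' @param bands_per_chrom Bands per chromosome.
#' @return A data.frame `chrom`, `start`, `end`, `name` usable as the
#'   cytoband slot of [genome_annotation()].
#' @export
synthetic_cytobands <- function(design, bands_per_chrom = 8) {
  dfs <- lapply(design$chrom_order, function(chrom) {
    L <- design$chrom_lengths[[chrom]]
    cuts <- round(seq(0, L, length.out = bands_per_chrom + 1))
    half <- ceiling(bands_per_chrom / 2)
    arm <- c(rep("p", half), rep("q", bands_per_chrom - half))
    num <- c(rev(seq_len(half)), seq_len(bands_per_chrom - half))
    data.frame(chrom = chrom, start = cuts[-length(cuts)], end = cuts[-1],
               name = paste0(sub("chr", "", chrom), arm, num),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}
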