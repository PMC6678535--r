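test_that("dye normalization removes global and intensity-dependent bias", {
  set.seed(1)
  n <- 5000
  r <- rnorm(n, 10, 1.5)
  df <- data.frame(
    probe_id = sprintf("P%05d", 1:n), chrom = "chr1",
    start = (1:n - 1) * 1000, end = (1:n - 1) * 1000 + 60,
    intensity_test = 2^r, intensity_ref = 2^r, gc = runif(n, 0.3, 0.7))

  # identical channels: correction is (numerically) the identity
  ps <- probe_set(df, "ident")
  out <- dye_normalize(ps)
  expect_lt(max(abs(log2(out$probes$intensity_ref /
                           out$probes$intensity_test))), 1e-6)

  # global 2x reference excess: post-normalization median log-ratio ~ 0
  df2 <- df
  df2$intensity_ref <- 2 * df2$intensity_test
  prof <- compute_log2_profile(dye_normalize(probe_set(df2, "bias2x")))
  expect_lt(abs(median(prof$values)), 1e-6)

  # multiplicative intensity-dependent bias on the reference channel:
  # residual trend of log-ratio vs mean intensity must be flattened
  set.seed(2)
  noise <- rnorm(n, 0, 0.1)
  df3 <- df
  df3$intensity_test <- 2^(r + noise / 2)
  a <- (log2(df3$intensity_test) + r) / 2
  df3$intensity_ref <- 2^(r - noise / 2 + 0.1 * (a - mean(a)))
  raw_prof <- compute_log2_profile(probe_set(df3, "dye"),
                                   require_dye_norm = FALSE)
  raw_slope <- coef(lm(raw_prof$values ~ a))[2]
  norm_prof <- compute_log2_profile(dye_normalize(probe_set(df3, "dye")))
  norm_slope <- coef(lm(norm_prof$values ~ a))[2]
  expect_gt(abs(raw_slope), 0.05)
  expect_lt(abs(norm_slope), 0.01)

  expect_error(dye_normalize(make_probe_set(rep(0, 10))), ">= 50")
})

test_that("log2 transform is the exact closed form and enforces provenance", {
  ps <- make_probe_set(rep(0, 60))
  expect_error(compute_log2_profile(ps), "not dye-normalized")
  prof <- compute_log2_profile(ps, require_dye_norm = FALSE)
  expect_equal(prof$values, rep(0, 60))
  expect_equal(compute_log2_profile(make_probe_set(rep(1, 60)),
                                    require_dye_norm = FALSE)$values,
               rep(1, 60))
  expect_equal(compute_log2_profile(make_probe_set(rep(log2(3), 60)),
                                    require_dye_norm = FALSE)$values[1],
               log2(3), tolerance = 1e-12)
})

test_that("GC correction removes GC trends, is centered and idempotent", {
  set.seed(3)
  n <- 8000
  gc <- runif(n, 0.3, 0.7)

  # flat profile: correction changes nothing beyond fit tolerance
  p_flat <- make_profile(rnorm(n, 0.2, 0.001), gc = gc)
  out_flat <- gc_correct(p_flat)
  expect_lt(max(abs(out_flat$values - p_flat$values)), 1e-3)

  # exactly linear GC signal is removed almost entirely
  p_lin <- make_profile(0.5 * (gc - mean(gc)), gc = gc)
  out_lin <- gc_correct(p_lin)
  expect_lt(max(abs(out_lin$values)), 1e-2)

  # quadratic GC bias of amplitude 0.3: residual correlation with GC ~ 0
  # quadratic bias spanning 0.3 log2 units over the GC range
  v <- rnorm(n, 0, 0.2) + 0.3 * ((gc - 0.5) / 0.2)^2
  p_quad <- make_profile(v, gc = gc)
  out_quad <- gc_correct(p_quad)
  expect_gt(abs(cor(p_quad$values, (gc - 0.5)^2)), 0.2)
  expect_lt(abs(cor(out_quad$values, (gc - 0.5)^2)), 0.05)
  expect_lt(abs(cor(out_quad$values, gc)), 0.05)

  # idempotence: second application changes values by < 1e-3 RMS
  # (low-noise profile so the bound probes the operator, not fit noise)
  p_idem <- make_profile(rnorm(n, 0, 0.01) + 0.05 * ((gc - 0.5) / 0.2)^2,
                         gc = gc)
  once <- gc_correct(p_idem)
  twice <- gc_correct(once)
  expect_lt(sqrt(mean((twice$values - once$values)^2)), 1e-3)

  # constant GC: warned no-op
  p_const <- make_profile(rnorm(200), gc = rep(0.5, 200))
  expect_warning(out_const <- gc_correct(p_const), "constant")
  expect_equal(out_const$values, p_const$values)
})

test_that("bias-free simulated data is recovered within the noise floor", {
  design <- generate_design(20000, seed = 4)
  cna <- cna_spec("chr1", 1e6, 2e7, 1, "shared")
  sim <- simulate_pair(design, cna, noise_model(0.2, c(0, 0), 0, 0), seed = 5)
  prof <- gc_correct(compute_log2_profile(dye_normalize(sim$parental)))
  truth <- numeric(nrow(prof$probes))
  hit <- prof$probes$chrom == "chr1" & prof$probes$start < 2e7 &
    prof$probes$end > 1e6
  truth[hit] <- 1
  rmse <- sqrt(mean((prof$values - truth)^2))
  expect_lte(rmse, 1.05 * 0.2)
})
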