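test_that("profile dynamics is the linear-interpolation IQR", {
  expect_equal(profile_dynamics(make_profile(1:100)), 49.5)
  expect_equal(profile_dynamics(make_profile(rep(2, 10))), 0)
  set.seed(1)
  p <- make_profile(rnorm(500))
  p2 <- p
  p2$values <- 2 * p$values
  expect_equal(profile_dynamics(p2), 2 * profile_dynamics(p))
})

test_that("dynamics scaling recovers exact affine maps and handles ties", {
  # piecewise-constant structured profile, noiseless: b = 2a + 0.1 exactly
  lv <- rep(c(0, 0.6, 0, -0.5, 0.9, 0), c(100, 60, 120, 50, 40, 130))
  a <- make_profile(lv, sample_id = "a")
  b <- make_profile(2 * lv + 0.1, sample_id = "b")
  sp <- scale_pair(a, b, cbs = cbs_params(seed = 1))
  expect_equal(sp$fit$low_sample, "a")
  expect_lt(abs(sp$fit$slope - 2), 1e-9)
  expect_lt(abs(sp$fit$intercept - 0.1), 1e-9)
  expect_equal(sp$a$values, b$values, tolerance = 1e-9)

  # identical profiles: tie broken by sample id, identity transform
  set.seed(2)
  v <- rnorm(300, 0, 0.2)
  x <- make_profile(v, sample_id = "s1")
  y <- make_profile(v, sample_id = "s2")
  spt <- scale_pair(x, y, cbs = cbs_params(seed = 1))
  expect_equal(spt$fit$low_sample, "s1")
  expect_equal(spt$fit$slope, 1)
  expect_equal(spt$fit$intercept, 0)

  # noisy compression recovery: truth slope 1.4, intercept 0.1
  set.seed(3)
  base <- rep(rnorm(20, 0, 0.9), each = 500)
  lowp <- make_profile(base + rnorm(10000, 0, 0.2), sample_id = "low")
  highp <- make_profile(1.4 * base + 0.1 + rnorm(10000, 0, 0.2),
                        sample_id = "high")
  spn <- scale_pair(lowp, highp, cbs = cbs_params(seed = 2))
  expect_equal(spn$fit$low_sample, "low")
  expect_lt(abs(spn$fit$slope - 1.4), 0.02)
  expect_lt(abs(spn$fit$intercept - 0.1), 0.01)

  # mismatched probe universes beyond 5% are rejected
  z <- make_profile(rnorm(200), sample_id = "z")
  short <- make_profile(rnorm(150), sample_id = "w")
  expect_error(scale_pair(z, short), "mismatched")
})

test_that("region annotation reports all overlapping genes and bands", {
  genes <- data.frame(chrom = "chr7", start = 87133177, end = 87342639,
                      name = "ABCB1")
  bands <- data.frame(chrom = c("chr7", "chr7"),
                      start = c(8e7, 8.71e7), end = c(8.71e7, 9.5e7),
                      name = c("7q21.11", "7q21.12"))
  ann <- genome_annotation(cytobands = bands, genes = genes)
  regions <- data.frame(chrom = "chr7", start = 86259618, end = 88276590)
  out <- annotate_regions(regions, ann)
  expect_true("ABCB1" %in% out$genes[[1]])
  expect_setequal(out$cytobands[[1]], c("7q21.11", "7q21.12"))

  # region inside one band reports exactly that band
  r2 <- annotate_regions(data.frame(chrom = "chr7", start = 8.2e7,
                                    end = 8.3e7), ann)
  expect_equal(r2$cytobands[[1]], "7q21.11")
  expect_equal(length(r2$genes[[1]]), 0)

  # empty annotation: empty lists, no error
  r3 <- annotate_regions(regions, genome_annotation())
  expect_equal(length(r3$genes[[1]]), 0)
})

test_that("null and noiseless differentials behave as contracts demand", {
  # test == ref: no called regions
  set.seed(4)
  v <- rnorm(800, 0, 0.2)
  t1 <- make_profile(v, sample_id = "t")
  r1 <- make_profile(v, sample_id = "r")
  expect_warning(dr <- differential_regions(t1, r1, cbs_params(seed = 1)),
                 "degenerate")
  expect_equal(nrow(dr$regions), 0)

  # noiseless acquired CNA: diff_l2r equals the injected amplitude exactly
  base <- rep(c(0, 0.8, 0), c(200, 80, 220))
  extra <- rep(c(0, 0, 1.0, 0), c(350, 0, 60, 90))
  tst <- make_profile(base + extra, sample_id = "res")
  ref <- make_profile(base, sample_id = "par")
  dr2 <- differential_regions(tst, ref, cbs_params(seed = 2))
  expect_equal(nrow(dr2$regions), 1)
  expect_equal(dr2$regions$diff_l2r, 1.0, tolerance = 1e-9)
  expect_equal(dr2$regions$call, "gain")
  expect_equal(dr2$regions$n_probes, 60L)
})

test_that("swapping test and ref flips signs with identical breakpoints", {
  set.seed(5)
  v <- rnorm(1000, 0, 0.2)
  v2 <- v + rep(c(0, 1.2, 0, -0.9, 0), c(200, 90, 300, 80, 330)) +
    rnorm(1000, 0, 0.2) - v   # independent second profile with structure
  pa <- make_profile(v, sample_id = "pa")
  pb <- make_profile(v2, sample_id = "pb")
  d_ab <- differential_regions(pa, pb, cbs_params(seed = 3))
  d_ba <- differential_regions(pb, pa, cbs_params(seed = 3))
  expect_equal(d_ab$diff_profile$values, -d_ba$diff_profile$values,
               tolerance = 1e-9)
  expect_equal(d_ab$called$segments[c("start", "end", "n_probes")],
               d_ba$called$segments[c("start", "end", "n_probes")])
  ra <- d_ab$regions[order(d_ab$regions$chrom, d_ab$regions$start), ]
  rb <- d_ba$regions[order(d_ba$regions$chrom, d_ba$regions$start), ]
  expect_equal(ra$diff_l2r, -rb$diff_l2r, tolerance = 1e-9)
})
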