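doses8 <- 10^seq(-3, 1, length.out = 8) # uM

test_that("noiseless 4PL curves are recovered to high precision", {
  truth <- list(top = 1, bottom = 0, hill = 1, ic50 = 0.05)
  dat <- simulate_dose_response(truth, doses8, replicates = 1, noise_sd = 0,
                                seed = 1)
  fit <- fit_4pl(dat)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 0.05, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-5)

  # steeper curve, shifted asymptotes
  truth2 <- list(top = 0.95, bottom = 0.1, hill = 2.2, ic50 = 0.7)
  fit2 <- fit_4pl(simulate_dose_response(truth2, doses8, 1, 0, seed = 2))
  expect_equal(fit2$ic50, 0.7, tolerance = 1e-5)
  expect_equal(fit2$hill, 2.2, tolerance = 1e-4)
})

test_that("dose scale equivariance holds for the fitted IC50", {
  truth <- list(top = 1, bottom = 0, hill = 1.3, ic50 = 0.08)
  d1 <- simulate_dose_response(truth, doses8, 3, 0.03, seed = 3)
  f1 <- fit_4pl(d1)
  d2 <- d1
  d2$data$dose <- d1$data$dose * 50
  f2 <- fit_4pl(d2)
  expect_equal(f2$ic50 / f1$ic50, 50, tolerance = 1e-3)
})

test_that("degenerate and non-inhibitory data are censored", {
  flat <- dose_response_data("drug", "s", rep(doses8, each = 3),
                             rep(1, 24))
  ffit <- fit_4pl(flat)
  expect_false(ffit$converged)
  expect_equal(ffit$censored, "greater")
  expect_equal(ffit$ic50, max(doses8))

  set.seed(4)
  rising <- dose_response_data("drug", "s", rep(doses8, each = 3),
                               rep(seq(0.5, 1.2, length.out = 8), each = 3) +
                                 rnorm(24, 0, 0.01))
  rfit <- fit_4pl(rising)
  expect_false(rfit$converged)
  expect_equal(rfit$censored, "greater")
})

test_that("resistance index reproduces the printed worked example", {
  tab <- read.delim(system.file("extdata", "printed_ic50_table.tsv",
                                package = "cnadiff"))
  row <- tab[tab$cell_line == "HOS" & tab$compound == "MTX" &
               tab$condition == "drug_on", ]
  ri <- resistance_index(as.numeric(row$ic50_resistant_uM),
                         as.numeric(row$ic50_parental_uM), compound = "MTX")
  expect_equal(ri$ri, as.numeric(row$ri_printed))
  expect_equal(ri$censored, "none")

  # RI of a line against itself is exactly 1
  self <- resistance_index(0.04, 0.04, compound = "MTX")
  expect_equal(self$ri, 1)
})

test_that("censored IC50 bounds propagate through the RI arithmetic", {
  cens <- structure(list(ic50 = 100, censored = "greater", compound = "MTX",
                         sample_id = "r", converged = FALSE),
                    class = "FourPLFit")
  point <- structure(list(ic50 = 0.04, censored = "none", compound = "MTX",
                          sample_id = "p", converged = TRUE),
                     class = "FourPLFit")
  ri <- resistance_index(cens, point)
  expect_equal(ri$censored, "greater")
  expect_equal(ri$ri, 2500)
  expect_gte(ri$ri, 2000) # consistent with the printed ">2000" bound

  ri2 <- resistance_index(point, cens)
  expect_equal(ri2$censored, "less")

  low <- structure(list(ic50 = 0.001, censored = "less", compound = "MTX",
                        sample_id = "r2", converged = FALSE),
                   class = "FourPLFit")
  ri3 <- resistance_index(cens, low)
  expect_equal(ri3$censored, "greater")
  ri4 <- resistance_index(cens, cens)
  expect_equal(ri4$censored, "indeterminate")
  expect_true(is.na(ri4$ri))
})

test_that("verapamil-style reversion lowers the fitted RI", {
  # resistant line: high IC50; with PgP inhibition the truth reverts
  par_truth <- list(top = 1, bottom = 0.05, hill = 1.2, ic50 = 0.06)
  res_truth <- list(top = 1, bottom = 0.05, hill = 1.2, ic50 = 5)
  rev_truth <- list(top = 1, bottom = 0.05, hill = 1.2, ic50 = 0.4)
  doses <- 10^seq(-3, 1.5, length.out = 9)
  f_par <- fit_4pl(simulate_dose_response(par_truth, doses, 3, 0.04, seed = 5))
  f_res <- fit_4pl(simulate_dose_response(res_truth, doses, 3, 0.04, seed = 6))
  f_rev <- fit_4pl(simulate_dose_response(rev_truth, doses, 3, 0.04, seed = 7))
  ri_no <- resistance_index(f_res, f_par)
  ri_ver <- resistance_index(f_rev, f_par)
  expect_gt(ri_no$ri, ri_ver$ri)
  expect_gt(ri_no$ri, 10)
})

test_that("dose-response tables round-trip through the TSV reader", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  dat <- simulate_dose_response(list(top = 1, bottom = 0, hill = 1,
                                     ic50 = 0.1), doses8, 2, 0.02, seed = 8,
                                compound = "MTX", sample_id = "HOS")
  df <- data.frame(compound = dat$compound, sample_id = dat$sample_id,
                   dose_uM = dat$data$dose, viability = dat$data$response,
                   replicate = dat$data$replicate)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_dose_response(tmp)
  expect_length(back, 1)
  expect_equal(back[[1]]$data$response, dat$data$response)
  expect_error(dose_response_data("d", "s", c(0, 1, 2), c(1, 1, 1)),
               "4 distinct")
})
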