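# Build profiles with an exact target correlation matrix from mean-zero
# orthonormal basis vectors (Cholesky mixing), so Pearson distances are
# known by construction.
profiles_with_cor <- function(R, n = 400, ids = NULL) {
  k <- nrow(R)
  set.seed(99)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- qr.Q(qr(Z))[, 1:k]
  Z <- scale(Z, center = TRUE, scale = FALSE) # still ~orthogonal
  X <- Z %*% chol(R)
  if (is.null(ids)) ids <- paste0("s", seq_len(k))
  lapply(seq_len(k), function(i) make_profile(X[, i], sample_id = ids[i]))
}

test_that("Ward/Pearson clustering reproduces hand-computed merges", {
  # identical pair + anti-correlated third: pair merges first at height ~ 0
  set.seed(5)
  v <- rnorm(300)
  ps <- list(make_profile(v, sample_id = "a"),
             make_profile(v + rnorm(300, 0, 1e-6), sample_id = "b"),
             make_profile(-v, sample_id = "c"))
  cl <- cluster_profiles(ps)
  expect_equal(sort(cl$merge[1, ]), c(-2, -1)) # leaves a and b merge first
  expect_lt(cl$heights[1], 1e-3)

  # engineered distances d(1,2)^2 etc: heights follow the Lance-Williams
  # update for Ward (on squared dissimilarities, reported on the d scale)
  R <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, 3)
  ps2 <- profiles_with_cor(R)
  cl2 <- cluster_profiles(ps2)
  d12 <- 0.1
  d13 <- 0.9
  h1 <- cl2$heights[1]
  expect_equal(h1, d12, tolerance = 1e-6)
  # Ward.D2 merge of {1,2} with 3: d^2 = (2*d13^2 + 2*d23^2 - d12^2)/3
  h2_expected <- sqrt((2 * d13^2 + 2 * d13^2 - d12^2) / 3)
  expect_equal(cl2$heights[2], h2_expected, tolerance = 1e-6)

  # affine invariance: rescaling all profiles leaves the tree unchanged
  ps3 <- lapply(ps2, function(p) { p$values <- 3 * p$values - 1; p })
  cl3 <- cluster_profiles(ps3)
  expect_equal(cl3$heights, cl2$heights, tolerance = 1e-8)
  expect_identical(cl3$merge, cl2$merge)

  # constant profile is rejected by name
  ps4 <- c(ps2[1:2], list(make_profile(rep(1, 400), sample_id = "flat")))
  expect_error(cluster_profiles(ps4), "flat")
})

test_that("newick export writes a tree with all sample labels", {
  R <- diag(4) * 0.5 + 0.5
  ps <- profiles_with_cor(matrix(c(1, .8, .2, .2,
                                   .8, 1, .2, .2,
                                   .2, .2, 1, .7,
                                   .2, .2, .7, 1), 4, 4))
  cl <- cluster_profiles(ps)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, cl$sample_ids)
  expect_equal(unname(cut_clusters(cl, 2)[1]), unname(cut_clusters(cl, 2)[2]))
})

test_that("cytoband enrichment matches the closed-form hypergeometric", {
  # 10 bands x 5 genes; query = all genes of band b1
  bands <- data.frame(chrom = "chr1",
                      start = (0:9) * 1e6, end = (1:10) * 1e6,
                      name = paste0("b", 1:10))
  genes <- data.frame(chrom = "chr1",
                      start = rep((0:9) * 1e6, each = 5) +
                        rep((0:4) * 1e5, 10) + 1000,
                      end = rep((0:9) * 1e6, each = 5) +
                        rep((0:4) * 1e5, 10) + 2000,
                      name = paste0("g", 1:50))
  ann <- genome_annotation(cytobands = bands, genes = genes)
  background <- genes$name
  query <- paste0("g", 1:5)
  out <- cytoband_enrichment(query, background, ann)
  expect_equal(out$cytoband[1], "b1")
  expect_equal(out$p[1], choose(45, 0) * choose(5, 5) / choose(50, 5),
               tolerance = 1e-12)
  expect_equal(out$k[1], 5L)
  expect_equal(out$N[1], 50L)
  # BH monotone in p-rank, p_adj >= p
  expect_true(all(diff(out$p_adj[order(out$p)]) >= -1e-12))
  expect_true(all(out$p_adj >= out$p - 1e-12))

  expect_equal(nrow(cytoband_enrichment(character(0), background, ann)), 0)
  expect_error(cytoband_enrichment("not_a_gene", background, ann), "subset")
})

test_that("uniform random queries are calibrated under the null", {
  # large per-band counts keep the discrete p-values close to nominal
  bands <- data.frame(chrom = "chr1",
                      start = (0:9) * 1e6, end = (1:10) * 1e6,
                      name = paste0("b", 1:10))
  ngene <- 5000
  gstart <- rep((0:9) * 1e6, each = 500) + rep((0:499) * 1900, 10) + 100
  genes <- data.frame(chrom = "chr1", start = gstart, end = gstart + 1500,
                      name = paste0("g", seq_len(ngene)))
  ann <- genome_annotation(cytobands = bands, genes = genes)
  background <- genes$name
  hits <- 0
  total <- 0
  set.seed(12)
  for (i in 1:200) {
    query <- sample(background, 500)
    out <- cytoband_enrichment(query, background, ann)
    hits <- hits + sum(out$p < 0.05)
    total <- total + nrow(out)
  }
  expect_lt(abs(hits / total - 0.05), 0.02)
})
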