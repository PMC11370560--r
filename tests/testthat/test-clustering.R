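behavior_fixture <- function(n = 60, seed = 2) {
  cfg <- sip_config(n_males = n / 2, n_females = n / 2, cage_size = 1,
                    seed = seed)
  cohort <- generate_cohort(cfg)
  generate_behavior_table(cfg, cohort$animals)
}

test_that("standardization gives population z-scores and is invertible", {
  beh <- behavior_fixture()$behavior
  std <- standardize(beh)
  expect_lt(max(abs(colMeans(std$z))), 1e-9)
  n <- nrow(std$z)
  pop_sd <- sqrt(colMeans(sweep(std$z, 2, colMeans(std$z))^2))
  expect_equal(unname(pop_sd), rep(1, 12), tolerance = 1e-9)

  # inverse transform recovers the input
  back <- sweep(sweep(std$z, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(back, as_behavior_matrix(beh), tolerance = 1e-9)

  const <- beh
  const$OFB_distance <- 5
  expect_error(standardize(const), "OFB_distance")
  expect_error(standardize(beh[1, ]), "at least 2")
})

test_that("PCA matches an independent eigendecomposition", {
  z <- standardize(behavior_fixture(n = 40, seed = 8)$behavior)$z
  pca <- pca_reduce(z)
  expect_equal(sum(pca$ratios), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$ratios) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(pca$loadings), diag(12), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigen oracle on the covariance (same n-1 divisor as prcomp)
  ev <- eigen(stats::cov(z), symmetric = TRUE)$values
  expect_equal(pca$ratios, ev / sum(ev), tolerance = 1e-8)
  # scores reproduce z through the loadings
  expect_equal(pca$scores %*% t(pca$loadings), z, tolerance = 1e-8)

  # rank-1 data: first component explains everything
  line <- cbind(1:10, 2 * (1:10))
  pca1 <- pca_reduce(scale(line, scale = FALSE))
  expect_equal(pca1$ratios[1], 1, tolerance = 1e-12)

  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(pca$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("component selection takes the smallest m above the threshold", {
  expect_equal(select_components(c(0.5, 0.2, 0.1, 0.1, 0.1), 0.75), 3L)
  expect_equal(select_components(c(0.8, 0.2), 0.75), 1L)
  expect_equal(select_components(c(0.4, 0.6), 0), 1L)
  expect_error(select_components(numeric(0)), "empty")
})

test_that("k-means recovers trivial partitions", {
  x <- matrix(c(0, 0, 10, 10), ncol = 1)
  fit <- kmeans_fit(x, 2, seed = 1)
  expect_equal(fit$inertia, 0)
  expect_equal(sort(as.vector(fit$centroids)), c(0, 10))
  expect_equal(fit$labels[1], fit$labels[2], ignore_attr = TRUE)
  expect_false(fit$labels[1] == fit$labels[3])

  # k = 1: centroid is the column mean, inertia the total SS
  y <- matrix(rnorm(20), ncol = 2)
  f1 <- kmeans_fit(y, 1, seed = 1)
  expect_equal(as.vector(f1$centroids), colMeans(y))
  expect_equal(f1$inertia, sum(sweep(y, 2, colMeans(y))^2))

  expect_error(kmeans_fit(y, 11), "exceeds")
})

test_that("agreement metrics match hand formulas on small labelings", {
  # identical labelings: everything 1
  m <- agreement_metrics(c(1, 1, 2, 2, 3), c(5, 5, 6, 6, 7))
  expect_equal(unname(m), rep(1, 5))

  # crossed 2x2 design: ARI = -0.5 from the pair-counting formula
  m2 <- agreement_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(m2[["ari"]], -0.5)
  expect_equal(m2[["homogeneity"]], 0)
  expect_equal(m2[["v_measure"]], 0)

  # one candidate cluster vs 2 reference classes: homogeneity 0,
  # completeness 1 (every class inside the single cluster)
  m3 <- agreement_metrics(c(0, 0, 0, 0), c(0, 0, 1, 1))
  expect_equal(m3[["homogeneity"]], 0)
  expect_equal(m3[["completeness"]], 1)

  expect_error(agreement_metrics(1:3, 1:4), "length")
})

test_that("ARI agrees with an independent implementation and is centered", {
  skip_if_not_installed("mclust")
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- sample(0:3, 40, replace = TRUE)
      b <- sample(0:2, 40, replace = TRUE)
      expect_equal(agreement_metrics(a, b)[["ari"]],
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
  # independent uniform labelings: ARI near 0
  withr::with_seed(11, {
    a <- sample(0:2, 1000, replace = TRUE)
    b <- sample(0:2, 1000, replace = TRUE)
  })
  expect_lt(abs(agreement_metrics(a, b)[["ari"]]), 0.05)
  # labels invariant up to renumbering: ARI = 1
  expect_equal(agreement_metrics(a, 10 - a)[["ari"]], 1)
})

test_that("stability table is deterministic and finds clean structure", {
  withr::with_seed(1, {
    blobs <- rbind(
      matrix(rnorm(60, 0), ncol = 2),
      matrix(rnorm(60, 8), ncol = 2),
      matrix(rnorm(60, c(16, 0)), ncol = 2)
    )
  })
  s1 <- stability_table(blobs, k_range = 3:6, B = 20, seed = 4)
  s2 <- stability_table(blobs, k_range = 3:6, B = 20, seed = 4)
  expect_identical(s1, s2)
  expect_equal(attr(s1, "recommended_k"), 3L)
  expect_true(all(s1[s1$k == 3, c("homogeneity", "completeness", "v_measure",
                                  "ari", "ami")] >= 0.99))
  # column order mirrors the stability-report convention
  expect_equal(names(s1), c("k", "homogeneity", "completeness", "v_measure",
                            "ari", "ami"))
})

test_that("cluster-by-sex table reproduces the reference chi-squared", {
  roster <- tibble::tibble(
    tag = sprintf("t%02d", 1:56),
    sex = rep(c("M", "F"), c(32, 24)),
    body_weight_g = 25, cage = "C01"
  )
  labels <- tibble::tibble(
    tag = roster$tag,
    cluster = c(rep(0L, 7), rep(1L, 1), rep(2L, 24),   # males 7/1/24
                rep(0L, 4), rep(1L, 5), rep(2L, 15))   # females 4/5/15
  )
  out <- cluster_by_group_table(labels, roster)
  expect_equal(unname(out$table[, c("M", "F")]),
               rbind(c(7, 4), c(1, 5), c(24, 15)), ignore_attr = TRUE)
  expect_equal(round(out$test$statistic, 1), 4.5)
  expect_equal(out$test$df1, 2)
  expect_equal(round(out$test$p_value, 1), 0.1)

  # proportional rows: chi-squared exactly 0
  expect_equal(chi_square_test(rbind(c(10, 5), c(20, 10)))$statistic, 0)
  # single-sex cohort: degenerate
  one_sex <- roster
  one_sex$sex <- "M"
  expect_error(cluster_by_group_table(labels, one_sex), "degenerate")
})

test_that("full phenotyping pipeline recovers planted phenotypes", {
  beh <- behavior_fixture(n = 100, seed = 21)
  cl <- cluster_phenotypes(beh$behavior, k = "auto", B = 20, seed = 3)
  expect_equal(cl$k, 3L)
  truth <- beh$truth$phenotype[match(cl$clusters$tag, beh$truth$tag)]
  expect_gte(agreement_metrics(cl$clusters$cluster, truth)[["ari"]], 0.8)
  # tidy/glance accessors
  expect_equal(nrow(tidy(cl)), 100)
  g <- glance(cl)
  expect_gt(g$variance_explained, 0.75)
  expect_equal(g$k, 3L)
})
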