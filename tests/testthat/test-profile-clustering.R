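test_that("PCA separates planted projects and keeps SVD properties", {
  one_cluster <- function(name, centroid)
    project_spec(name, 16, clusters = list(
      list(name = name, weight = 1, concentration = 80, centroid = centroid)))
  specA <- one_cluster("hiMan5", project_spec_a()$clusters[[1]]$centroid)
  specB <- one_cluster("hiG1F", project_spec_b()$clusters[[3]]$centroid)
  dsA <- make_profiles(specA, seed = 1)
  dsB <- make_profiles(specB, seed = 2)
  x <- rbind(dsA$profiles, dsB$profiles)
  proj <- rep(c("A", "B"), times = c(nrow(dsA$profiles), nrow(dsB$profiles)))
  p <- pca_profiles(x, n_components = 4)
  # loadings orthonormal
  g <- crossprod(p$loadings)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  expect_lte(sum(p$variance_explained), 1 + 1e-12)
  # PC1 separates projects cleanly: silhouette on 1-d scores
  s1 <- p$scores[, 1]
  sil <- vapply(seq_along(s1), function(i) {
    own <- mean(abs(s1[i] - s1[setdiff(which(proj == proj[i]), i)]))
    oth <- mean(abs(s1[i] - s1[proj != proj[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gte(mean(sil), 0.5)
})

test_that("PCA reconstructs exactly with all components", {
  x <- make_profiles(project_spec_a(12), seed = 3)$profiles
  p <- pca_profiles(x, n_components = min(dim(x)))
  ctr <- colMeans(x)
  recon <- sweep(p$scores %*% t(p$loadings), 2, ctr, "+")
  expect_lt(max(abs(recon - x)), 1e-8)
})

test_that("a variance-free matrix is handled gracefully", {
  x <- matrix(rep(c(0.4, 0.6), each = 5), 5, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_warning(p <- pca_profiles(x), "variance")
  expect_true(all(p$variance_explained == 0))
})

test_that("k-means recovers planted clusters and the k=1 identity", {
  dsA <- make_profiles(project_spec_a(), seed = 4)
  smA <- rowsum(dsA$profiles, dsA$sample_id) / 2
  smA <- smA / rowSums(smA)
  km1 <- kmeans_profiles(smA, 1, seed = 1)
  tss <- sum(sweep(smA, 2, colMeans(smA))^2)
  expect_equal(km1$wcss, tss, tolerance = 1e-9)

  km2 <- kmeans_profiles(smA, 2, seed = 1)
  expect_gte(mclust::adjustedRandIndex(
    km2$labels, dsA$sample_labels[rownames(smA)]), 0.9)

  dsB <- make_profiles(project_spec_b(), seed = 5)
  smB <- rowsum(dsB$profiles, dsB$sample_id) / 2
  smB <- smB / rowSums(smB)
  km3 <- kmeans_profiles(smB, 3, seed = 1)
  expect_gte(mclust::adjustedRandIndex(
    km3$labels, dsB$sample_labels[rownames(smB)]), 0.9)
  expect_error(kmeans_profiles(smA, nrow(smA) + 1, seed = 1), "k must be")
})

test_that("returned WCSS is the within-cluster sum of squares and beats
           random assignments", {
  x <- make_profiles(project_spec_b(20), seed = 6)$profiles
  km <- kmeans_profiles(x, 3, seed = 2)
  direct <- sum((x - km$centroids[km$labels, , drop = FALSE])^2)
  expect_equal(km$wcss, direct, tolerance = 1e-8)
  withr::with_seed(8, {
    for (i in 1:5) {
      lab <- sample(1:3, nrow(x), replace = TRUE)
      cent <- apply(x, 2, function(col) tapply(col, lab, mean))
      rand_wcss <- sum((x - cent[lab, , drop = FALSE])^2)
      expect_lte(km$wcss, rand_wcss + 1e-9)
    }
  })
})

test_that("elbow curves are monotone and kink at the planted k", {
  dsB <- make_profiles(project_spec_b(), seed = 7)
  smB <- rowsum(dsB$profiles, dsB$sample_id) / 2
  smB <- smB / rowSums(smB)
  for (s in 1:3) {
    eb <- elbow_curve(smB, 6, seed = s)
    expect_true(all(diff(eb$wcss) <= 1e-9))
    expect_identical(best_elbow_k(eb), 3L)
  }
  # k = n gives zero WCSS
  tiny <- smB[1:5, ]
  eb5 <- elbow_curve(tiny, 5, seed = 1)
  expect_lt(eb5$wcss[5], 1e-12)
})

test_that("cluster characterization names dominant glycans", {
  ds <- make_profiles(project_spec_a(), seed = 9)
  sm <- rowsum(ds$profiles, ds$sample_id) / 2
  sm <- sm / rowSums(sm)
  km <- kmeans_profiles(sm, 2, seed = 3)
  ch <- characterize_clusters(km, sm, pca_profiles(sm))
  expect_setequal(ch$clusters$name, c("Man5", "G0F"))
  expect_true(any(c("Man5", "G0F") %in% names(ch$discriminating)))
  expect_length(ch$empty, 0)

  # identical clusters: nothing discriminates
  flat <- matrix(rep(c(0.5, 0.3, 0.2), each = 8), 8, 3,
                 dimnames = list(NULL, c("G0F", "G1F", "Man5")))
  flat_km <- list(labels = rep(1:2, 4), k = 2L,
                  centroids = flat[1:2, ], wcss = 0)
  ch2 <- characterize_clusters(flat_km, flat)
  expect_length(ch2$discriminating, 0)
})
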