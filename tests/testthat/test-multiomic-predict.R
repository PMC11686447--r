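test_that("gene panel filtering preserves order and reports absences", {
  x <- matrix(0, 4, 5, dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  out <- filter_gene_panel(x, c("d", "a", "b"))
  expect_identical(colnames(out), c("d", "a", "b"))
  expect_warning(out2 <- filter_gene_panel(x, c("a", "zz")), "zz")
  expect_identical(colnames(out2), "a")
  expect_error(filter_gene_panel(x, character(0)), "empty")
  expect_error(filter_gene_panel(x, c("q", "r")), "no panel gene")
})

test_that("sPLS honours its self-covariance and sparsity contracts", {
  withr::with_seed(1, X <- matrix(rnorm(40 * 8), 40, 8,
                                  dimnames = list(NULL, letters[1:8])))
  fit <- spls_pair(X, X, n_components = 1)
  expect_gt(abs(cor(fit$scores_X[, 1], fit$scores_Y[, 1])), 1 - 1e-6)

  withr::with_seed(2, Y <- matrix(rnorm(40 * 6), 40, 6))
  sparse <- spls_pair(X, Y, n_components = 2, keepX = 1, keepY = 3)
  expect_identical(colSums(sparse$loadings_X != 0), c(1, 1))
  expect_identical(colSums(sparse$loadings_Y != 0), c(3, 3))
  expect_error(spls_pair(X, Y, keepX = 99), "exceed")
})

test_that("sPLS recovers a planted shared latent factor", {
  withr::with_seed(3, {
    n <- 50; f <- rnorm(n)
    X <- outer(f, c(2, -1.5, 1, 0, 0)) + matrix(rnorm(n * 5, sd = 0.5), n, 5)
    Y <- outer(f, c(1, 2, 0, 0)) + matrix(rnorm(n * 4, sd = 0.5), n, 4)
  })
  fit <- spls_pair(X, Y, n_components = 1)
  expect_gte(abs(cor(fit$scores_X[, 1], fit$scores_Y[, 1])), 0.9)
})

test_that("sPLS scores agree with the mixOmics reference on a strong signal", {
  withr::with_seed(4, {
    n <- 40; f <- rnorm(n)
    X <- outer(f, runif(6, 0.5, 2)) + matrix(rnorm(n * 6, sd = 0.3), n, 6)
    Y <- outer(f, runif(5, 0.5, 2)) + matrix(rnorm(n * 5, sd = 0.3), n, 5)
  })
  colnames(X) <- paste0("x", 1:6); colnames(Y) <- paste0("y", 1:5)
  ours <- spls_pair(X, Y, n_components = 1)
  ref <- suppressMessages(mixOmics::spls(X, Y, ncomp = 1, mode = "canonical"))
  expect_gte(abs(cor(ours$scores_X[, 1], ref$variates$X[, 1])), 0.95)
})

test_that("design weights reflect pairwise component correlation", {
  withr::with_seed(5, {
    base <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("g", 1:6)))
    noise <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("h", 1:6)))
  })
  D <- build_design(list(a = base, b = base + rnorm(360, sd = 0.01),
                         c = noise))
  expect_identical(D["a", "b"], 1)
  expect_identical(D["a", "c"], 0.1)
  expect_identical(D, t(D))
  expect_identical(unname(diag(D)), rep(0, 3))
  expect_error(build_design(list(a = base)), "2 blocks")
})

test_that("the multiblock model separates a separable fixture exactly", {
  fx <- separable_blockset(seed = 6)
  fit <- fit_block_splsda(fx$blocks, fx$y, n_components = 2,
                          keepX = lapply(fx$blocks, function(b) 5))
  pr <- predict_classes(fit, fx$blocks)
  expect_identical(pr$predicted, fx$y)
  # loading sparsity honours keepX exactly per component
  for (b in names(fx$blocks))
    expect_equal(unname(colSums(fit$loadings[[b]] != 0)), c(5, 5))
  expect_error(fit_block_splsda(fx$blocks, fx$y,
                                keepX = lapply(fx$blocks, function(b) 99)),
               "keepX")
  expect_error(fit_block_splsda(fx$blocks, factor(rep("a", 24))), "2 classes")
})

test_that("prediction on blocks missing model features errors informatively", {
  fx <- separable_blockset(seed = 7)
  fit <- fit_block_splsda(fx$blocks, fx$y, n_components = 1)
  crippled <- fx$blocks
  crippled$block1 <- crippled$block1[, -1]
  expect_error(predict_classes(fit, crippled), "g01")
})

test_that("rank AUC equals trapezoidal ROC integration", {
  expect_identical(roc_auc(c(1, 2, 3, 10, 11), rep(c("n", "p"), c(3, 2)), "p"), 1)
  expect_identical(roc_auc(rep(1, 10), rep(c("n", "p"), 5), "p"), 0.5)
  withr::with_seed(8, {
    for (i in 1:100) {
      n <- sample(10:40, 1)
      scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
      labels <- sample(c("n", "p"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_lt(abs(roc_auc(scores, labels, "p") -
                    trapezoid_auc(scores, labels, "p")), 1e-9)
    }
  })
  # cross-check against the pROC reference implementation
  withr::with_seed(9, {
    sc <- rnorm(40); lb <- sample(c("n", "p"), 40, replace = TRUE)
  })
  ref <- as.numeric(suppressMessages(pROC::auc(lb, sc, levels = c("n", "p"),
                                               direction = "<")))
  expect_equal(roc_auc(sc, lb, "p"), ref, tolerance = 1e-12)
  expect_error(roc_auc(1:4, rep("p", 4), "p"), "one class")
})

test_that("cross-validation is deterministic and leakage-safe by group", {
  fx <- separable_blockset(n_per_class = 10, seed = 10)
  group <- rep(1:10, each = 2)  # duplicates share a biological sample
  cv1 <- cv_block_splsda(fx$blocks, fx$y, n_components = 1,
                         keepX = lapply(fx$blocks, function(b) 4),
                         n_folds = 5, seed = 42, group = group)
  cv2 <- cv_block_splsda(fx$blocks, fx$y, n_components = 1,
                         keepX = lapply(fx$blocks, function(b) 4),
                         n_folds = 5, seed = 42, group = group)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$selection_count, cv2$selection_count)
  expect_identical(cv1$class_auc, cv2$class_auc)
  # duplicates never straddle folds
  expect_true(all(tapply(cv1$folds, group, function(f) length(unique(f))) == 1))
  expect_gte(cv1$mean_auc, 0.95)
})

test_that("stability selection applies the 7-of-10 rule", {
  fx <- separable_blockset(n_per_class = 15, seed = 11)
  cv <- cv_block_splsda(fx$blocks, fx$y, n_components = 1,
                        keepX = lapply(fx$blocks, function(b) 4),
                        n_folds = 10, seed = 13)
  st <- stability_select(cv)
  expect_true(all(st$frequency >= 0.7))
  # signal genes g01..g04 dominate the stable set
  expect_true(all(c("g01", "g02", "g03", "g04") %in%
                  st$gene[st$block == "block1"]))
  # threshold boundary: a synthetic report with counts 6 and 7
  fake <- cv
  fake$selection_count <- list(block1 = c(lo = 6, hi = 7))
  fake$mean_abs_loading <- list(block1 = c(lo = 1, hi = 1))
  fake$class_means <- list(block1 = matrix(c(0, 1, 1, 0), 2, 2,
    dimnames = list(c("a", "b"), c("lo", "hi"))))
  st2 <- stability_select(fake)
  expect_identical(st2$gene, "hi")
})

test_that("label permutation collapses performance to chance", {
  fx <- separable_blockset(n_per_class = 12, seed = 12)
  aucs <- vapply(1:3, function(s) {
    withr::with_seed(500 + s, yperm <- sample(fx$y))
    cv <- cv_block_splsda(fx$blocks, yperm, n_components = 1,
                          keepX = lapply(fx$blocks, function(b) 4),
                          n_folds = 5, seed = s)
    cv$mean_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("tuning returns the single grid point and prefers sparse fits", {
  fx <- separable_blockset(n_per_class = 10, seed = 13)
  tn <- tune_model(fx$blocks, fx$y, grid_ncomp = 1, grid_keepX = 4,
                   n_folds = 5, seed = 3)
  expect_identical(tn$n_components, 1)
  expect_identical(tn$keepX, 4)
  tn2 <- tune_model(fx$blocks, fx$y, grid_ncomp = 1,
                    grid_keepX = c(4, 12, 20), n_folds = 5, seed = 3)
  expect_lte(tn2$keepX, 12)
})
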