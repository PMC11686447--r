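test_that("synthetic profiles are valid, replicated and deterministic", {
  spec <- project_spec_a(10)
  a <- make_profiles(spec, seed = 5)
  b <- make_profiles(spec, seed = 5)
  expect_identical(a$profiles, b$profiles)
  expect_true(all(abs(rowSums(a$profiles) - 1) < 1e-9))
  expect_identical(nrow(a$profiles), 20L)  # 10 samples x 2 replicates
  expect_identical(length(unique(a$sample_id)), 10L)
  # replicate rows of one sample are close but not identical
  reps <- a$profiles[a$sample_id == a$sample_id[1], ]
  expect_gt(max(abs(reps[1, ] - reps[2, ])), 0)
  expect_lt(max(abs(reps[1, ] - reps[2, ])), 0.1)
})

test_that("infinite concentration collapses profiles onto centroids", {
  spec <- project_spec_a(6)
  for (i in seq_along(spec$clusters)) {
    spec$clusters[[i]]$concentration <- 1e9
  }
  spec$replicate_concentration <- 1e9
  pr <- make_profiles(spec, seed = 6)
  cents <- do.call(rbind, lapply(spec$clusters, `[[`, "centroid"))
  rownames(cents) <- vapply(spec$clusters, `[[`, character(1), "name")
  for (r in seq_len(nrow(pr$profiles)))
    expect_lt(max(abs(pr$profiles[r, ] -
                      cents[as.character(pr$labels[r]), ])), 1e-3)
})

test_that("degenerate cluster centroids are rejected", {
  cl <- list(list(name = "z", weight = 1, concentration = 10,
                  centroid = setNames(rep(0, 10), glycan_species())))
  expect_error(project_spec("bad", 5, clusters = cl), "zero")
})

test_that("expression blocks are integer counts aligned to profiles", {
  ds <- make_dataset(project_spec_a(8), seed = 9)
  ex <- ds$expression
  expect_named(ex$blocks, c("day0", "day6", "day10"))
  for (b in ex$blocks) {
    expect_true(all(b >= 0))
    expect_true(all(b == round(b)))
    expect_identical(rownames(b), rownames(ds$profiles$profiles))
  }
  expect_true(all(ds$true_markers$gene %in% colnames(ex$blocks$day0)))
  # marker genes must belong to the gene universe
  spec_bad <- project_spec_a(8)
  spec_bad$markers$gene[1] <- "NotAGene"
  pr <- make_profiles(spec_bad, seed = 1)
  expect_error(make_expression(spec_bad, pr, seed = 2), "universe")
})

test_that("planted markers shift expression in the right cluster and day", {
  ds <- make_dataset(project_spec_b(24), seed = 10)
  ex <- ds$expression
  lab <- ds$true_labels
  for (i in seq_len(nrow(ds$true_markers))) {
    mk <- ds$true_markers[i, ]
    blk <- log2(ex$blocks[[mk$day]] + 1)
    delta <- mean(blk[lab == mk$cluster, mk$gene]) -
      mean(blk[lab != mk$cluster, mk$gene])
    expect_gt(delta, 0.5 * mk$log2_effect)
  }
  # no marker was planted at day 6 in this preset: no gene separates there
  blk6 <- log2(ex$blocks$day6 + 1)
  deltas <- apply(blk6, 2, function(g)
    abs(mean(g[lab == "G1F"]) - mean(g[lab != "G1F"])))
  expect_lt(max(deltas), 0.8)
})

test_that("ABC targets respond directionally to planted perturbations", {
  eng <- ssa_engine()
  base <- simulate_profile(default_enzyme_params(), 5000, seed = 77,
                           engine = eng)$profile
  man5_up <- 0; gal_up <- 0
  for (s in 1:5) {
    low_mgat1 <- make_abc_target(perturbation = c(Mgat1 = 0.25),
                                 n_glycans = 5000, seed = 100 + s,
                                 engine = eng)
    hi_galt <- make_abc_target(perturbation = c(GalT = 4),
                               n_glycans = 5000, seed = 200 + s,
                               engine = eng)
    man5_up <- man5_up + (low_mgat1$observed["Man5"] > base["Man5"])
    g_obs <- sum(hi_galt$observed[c("G1F", "G2F")], na.rm = TRUE)
    g_base <- sum(base[c("G1F", "G2F")], na.rm = TRUE)
    gal_up <- gal_up + (g_obs > g_base)
  }
  expect_gte(man5_up, 4)
  expect_gte(gal_up, 4)
  # identity perturbation reproduces the base law within Monte-Carlo noise
  ident <- make_abc_target(perturbation = c(Mgat1 = 1), n_glycans = 10000,
                           seed = 300, engine = eng)
  fresh <- simulate_profile(default_enzyme_params(), 10000, seed = 301,
                            engine = eng)$profile
  expect_lt(total_variation(ident$observed, fresh), 0.03)
  expect_error(make_abc_target(perturbation = c(NoSuch = 2)), "unknown enzyme")
})

test_that("a null generator yields chance-level prediction", {
  spec <- project_spec_a(20)
  spec$markers <- NULL
  ds <- make_dataset(spec, seed = 13)
  blocks <- lapply(ds$expression$blocks, function(b)
    filter_gene_panel(log2(b + 1), ds$expression$gene_panel))
  cv <- suppressWarnings(
    cv_block_splsda(blocks, ds$true_labels, n_components = 2,
                    keepX = lapply(blocks, function(b) 5),
                    seed = 14, group = ds$profiles$sample_id))
  # with no planted effects the labels carry no expression signal: the model
  # cannot beat chance (selection-frequency counts, by contrast, stay high on
  # any fixed dataset because 10-fold training sets overlap heavily)
  expect_gt(cv$mean_auc, 0.3)
  expect_lt(cv$mean_auc, 0.7)
})
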