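test_that("profile_distance is the square-difference statistic", {
  p <- c(Man5 = 0.5, G0F = 0.5)
  q <- c(Man5 = 0.6, G0F = 0.4)
  expect_identical(profile_distance(p, p), 0)
  expect_equal(profile_distance(p, q), 0.02)
  # species are aligned on the union of names
  r <- c(Man5 = 0.5, G1F = 0.5)
  expect_equal(profile_distance(p, r), 0.5)
  expect_error(profile_distance(p, c(Man5 = 0.7, G0F = 0.7)), "sum to 1")
})

test_that("mann_whitney matches known exact values and wilcox.test", {
  mw <- mann_whitney(1:3, 4:6)
  expect_identical(mw$U, 0)
  expect_equal(mw$p.value, 0.1)   # 2 x 1/choose(6,3)
  expect_equal(mann_whitney(rep(1, 5), rep(1, 5))$p.value, 1)

  # tie-free small samples agree with wilcox.test's exact distribution
  withr::with_seed(77, {
    for (i in 1:20) {
      nx <- sample(2:8, 1); ny <- sample(2:8, 1)
      x <- rnorm(nx); y <- rnorm(ny)
      mw <- mann_whitney(x, y)
      wt <- wilcox.test(x, y, exact = TRUE)
      expect_equal(mw$U, unname(wt$statistic))
      expect_equal(mw$p.value, wt$p.value, tolerance = 1e-12)
    }
  })

  # large samples use the tie-corrected normal approximation
  withr::with_seed(78, {
    x <- round(rnorm(30), 1); y <- round(rnorm(25), 1)
    mw <- mann_whitney(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p.value, wt$p.value, tolerance = 1e-9)
  })
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("gelman_rubin behaves at its analytic limits", {
  withr::with_seed(5, x <- rnorm(200))
  # duplicated chains: B = 0 so R = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(x, x)), sqrt(199 / 200))
  # iid same-target chains stay near 1
  withr::with_seed(6, ch <- replicate(4, rnorm(500), simplify = FALSE))
  expect_lt(gelman_rubin(ch), 1.1)
  # well-separated chains blow up
  withr::with_seed(7, ch2 <- list(rnorm(500), rnorm(500) + 10))
  expect_gt(gelman_rubin(ch2), 1.2)
  expect_error(gelman_rubin(list(rep(1, 50), rep(1, 50))), "variance")
  expect_error(gelman_rubin(list(rnorm(50))), "2 chains")
})

test_that("a degenerate proposal freezes the chain at its start", {
  eng <- ssa_engine()
  obs <- simulate_profile(default_enzyme_params(), 2000, seed = 1,
                          engine = eng)$profile
  cfg <- abc_config(chain_length = 60, n_chains = 1, n_glycans = 2000,
                    tie_cisternae = TRUE, proposal_sd = 1e-12,
                    epsilon = 10, adapt = FALSE, thinning = 1)
  ch <- abc_mcmc_chain(obs, cfg, chain_seed = 3, engine = eng)
  expect_equal(ch$acceptance_rate, 1)
  spread <- apply(log(ch$samples), 2, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)
})

test_that("recorded samples satisfy the tolerance and re-simulate exactly", {
  eng <- ssa_engine()
  obs <- simulate_profile(default_enzyme_params(), 3000, seed = 2,
                          engine = eng)$profile
  cfg <- abc_config(chain_length = 300, n_chains = 2, n_glycans = 3000,
                    tie_cisternae = TRUE, seed = 9, epsilon = 0.2)
  chains <- run_parallel_chains(obs, cfg, eng)
  eps <- attr(chains, "epsilon")
  for (ch in chains) expect_true(all(ch$distances <= eps))
  # a recorded distance is reproducible from its stored simulation seed
  ch <- chains[[1]]
  for (i in c(1, nrow(ch$samples))) {
    d <- glygolgi:::simulate_distance(ch$samples[i, ], obs, cfg, eng,
                                      ch$sim_seeds[i])
    expect_identical(d, ch$distances[i])
  }
})

test_that("parallel chains are deterministic given the master seed", {
  eng <- ssa_engine()
  obs <- simulate_profile(default_enzyme_params(), 2000, seed = 4,
                          engine = eng)$profile
  cfg <- abc_config(chain_length = 100, n_chains = 2, n_glycans = 2000,
                    tie_cisternae = TRUE, seed = 21, epsilon = 0.2)
  a <- run_parallel_chains(obs, cfg, eng)
  b <- run_parallel_chains(obs, cfg, eng)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_identical(lapply(a, `[[`, "distances"), lapply(b, `[[`, "distances"))
})

test_that("compare_posteriors detects a planted shift with the right sign", {
  eng <- ssa_engine(core_biantennary_rules())
  tied <- recovery_base_params()
  tgt <- make_abc_target(params_base = tied, perturbation = c(GalT = 4),
                         n_glycans = 5000, seed = 5, engine = eng)
  base <- simulate_profile(tied, 5000, seed = 6, engine = eng)$profile
  cfg <- abc_config(chain_length = 1200, n_chains = 2, n_glycans = 5000,
                    tie_cisternae = TRUE, seed = 31)
  chA <- suppressWarnings(run_parallel_chains(tgt$observed, cfg, eng))
  cfgB <- cfg; cfgB$seed <- 32
  chB <- suppressWarnings(run_parallel_chains(base, cfgB, eng))
  cp <- compare_posteriors(chA, chB, "GalT")
  expect_gt(cp$median_log2_ratio, 0.5)
  expect_lt(cp$p, 0.05)
})
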