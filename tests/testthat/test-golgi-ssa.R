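test_that("degenerate parameter sets give the expected limits", {
  zero <- enzyme_params(matrix(0, 9, 4))
  res <- simulate_profile(zero, 500, seed = 1)
  expect_identical(res$profile, c(Man9 = 1))
  expect_identical(sum(res$firing_counts), 0L)

  # saturating Man1 in the first cisterna trims every glycan to Man5
  act <- matrix(0, 9, 4, dimnames = list(glygolgi:::GLYCAN_ENZYMES, NULL))
  act["Man1", 1] <- 1e6
  res <- simulate_profile(enzyme_params(act), 500, seed = 2)
  expect_identical(res$profile, c(Man5 = 1))
})

test_that("profiles are deterministic given a seed and conserve glycans", {
  p <- default_enzyme_params()
  a <- simulate_profile(p, 2000, seed = 7)
  b <- simulate_profile(p, 2000, seed = 7)
  expect_identical(a$profile, b$profile)
  expect_identical(a$firing_counts, b$firing_counts)
  expect_lt(abs(sum(a$profile) - 1), 1e-9)
  # terminal states account for exactly n glycans
  expect_identical(sum(a$profile) * a$n_glycans, 2000)
})

test_that("gillespie_step has exponential waiting times and lock semantics", {
  act <- matrix(0, 9, 4, dimnames = list(glygolgi:::GLYCAN_ENZYMES, NULL))
  act["Mgat1", 1] <- 2
  p <- enzyme_params(act)
  withr::with_seed(11, {
    wts <- replicate(4000, gillespie_step(glycan_state(5), p, 1)$waiting_time)
  })
  # Exponential(2): mean 0.5, se = 0.5/sqrt(n)
  expect_lt(abs(mean(wts) - 0.5), 3 * 0.5 / sqrt(4000))

  # absorbing state
  st <- gillespie_step(glycan_state(9), p, 1)
  expect_identical(st$waiting_time, Inf)
  expect_true(is.na(st$fired))

  # a locked state can only resolve, at lock_resolution_rate
  locked <- glycan_state(3, 1, 0, 0, 0, locked = TRUE)
  withr::with_seed(12, st <- gillespie_step(locked, p, 1))
  expect_identical(st$fired, "lock_resolution")
  expect_identical(unclass(st$next_state)[["fuc"]], 1L)
})

test_that("single-reaction conversion matches the closed-form CTMC", {
  # one cisterna, Mgat1 at rate k from Man5: P(converted) = 1 - exp(-kT)
  k <- 0.8
  act <- matrix(k, 1, 1, dimnames = list("Mgat1", NULL))
  full <- matrix(0, 9, 1, dimnames = list(glygolgi:::GLYCAN_ENZYMES, NULL))
  full["Mgat1", 1] <- k
  p <- enzyme_params(full, residence_time = 1)
  eng <- ssa_engine(Filter(function(r) r$enzyme == "Mgat1", default_rules()),
                    glycan_state(5))
  res <- simulate_profile(p, 10000, seed = 5, engine = eng)
  pr <- 1 - exp(-k)
  frac <- 1 - res$profile["Man5"]
  expect_lt(abs(frac - pr), 3 * sqrt(pr * (1 - pr) / 10000))
})

test_that("the empirical terminal distribution matches the matrix exponential", {
  # linear Man1 trimming chain, one cisterna
  act <- matrix(0, 9, 1, dimnames = list(glygolgi:::GLYCAN_ENZYMES, NULL))
  act["Man1", 1] <- 1.5
  p <- enzyme_params(act, residence_time = 1)
  eng <- ssa_engine(man1_only_rules())
  sim <- simulate_profile(p, 10000, seed = 9, engine = eng)
  exact <- ctmc_terminal_distribution(eng, p)
  expect_lt(total_variation(sim$profile, exact), 0.02)
})

test_that("R reference path and compiled path sample the same law", {
  act <- matrix(0, 9, 2, dimnames = list(glygolgi:::GLYCAN_ENZYMES, NULL))
  act[c("Man1", "Mgat1"), 1] <- c(3, 1)
  act[c("Man2", "Fut8"), 2] <- c(2, 1)
  p <- enzyme_params(act)
  withr::with_seed(21, {
    ref <- table(replicate(600, canonical_name(
      simulate_glycan(glycan_state(9), p)$final_state)))
  })
  ref <- setNames(as.numeric(ref) / 600, names(ref))
  cpp <- simulate_profile(p, 20000, seed = 22)$profile
  expect_lt(total_variation(ref, cpp), 0.07)
})

test_that("raising GalT activity does not lower galactosylated output", {
  base <- default_enzyme_params()
  up <- base; up$activity["GalT", ] <- up$activity["GalT", ] * 2
  gal_frac <- function(params, seed) {
    pr <- simulate_profile(params, 4000, seed = seed)$profile
    sum(pr[names(pr) %in% c("G1F", "G2F", "G1", "G2")])
  }
  for (s in 1:3)
    expect_gte(gal_frac(up, 100 + s), gal_frac(base, 100 + s) - 0.02)
})

test_that("the fucosylation lock artefact vanishes as resolution gets fast", {
  p_fast <- default_enzyme_params()
  p_fast$lock_resolution_rate <- 1e6
  eng_lock <- ssa_engine(default_rules(fut8_lock = TRUE))
  eng_free <- ssa_engine(default_rules(fut8_lock = FALSE))
  with_lock <- simulate_profile(p_fast, 20000, seed = 31, engine = eng_lock)
  no_lock <- simulate_profile(p_fast, 20000, seed = 32, engine = eng_free)
  expect_lt(total_variation(with_lock$profile, no_lock$profile), 0.02)
})

test_that("flux localization normalizes firing counts per cisterna", {
  act <- matrix(0, 9, 4, dimnames = list(glygolgi:::GLYCAN_ENZYMES, NULL))
  act["Man1", 1] <- 5
  res <- simulate_profile(enzyme_params(act), 1000, seed = 41)
  expect_identical(as.numeric(flux_localization(res, "Man1")), c(1, 0, 0, 0))
  expect_warning(fl <- flux_localization(res, "SiaT"), "never fired")
  expect_identical(as.numeric(fl), rep(0, 4))
  full <- simulate_profile(default_enzyme_params(), 2000, seed = 42)
  expect_lt(abs(sum(flux_localization(full, "Mgat1")) - 1), 1e-12)
})
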