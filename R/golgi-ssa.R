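# Stochastic simulation of glycan processing across Golgi cisternae.
#
# Each of n independent glycans enters cisterna 1 as Man9 and spends a fixed
# residence time per cisterna; within a cisterna, reaction propensities are
# the per-enzyme, per-cisterna activities, and events are sampled exactly
# (Gillespie).  Time is dimensionless: activities are identifiable only as
# products with residence time, which is therefore fixed to 1 during fitting.

#' Construct a per-enzyme, per-cisterna parameter set
#'
#' @param activity 9 x K non-negative matrix of enzyme activities
#'   (rows named by enzyme, columns = cisternae in transit order).
#' @param lock_resolution_rate positive rate at which a Fut8 lock resolves
#'   into core fucose.
#' @param residence_time positive residence time per cisterna (scalar or
#'   length-K vector), in the same dimensionless units as 1/activity.
#' @return an `enzyme_params` object.
#' @export
enzyme_params <- function(activity, lock_resolution_rate = 5,
                          residence_time = 1) {
  activity <- as.matrix(activity)
  if (nrow(activity) != length(GLYCAN_ENZYMES))
    stop("activity must have one row per enzyme (", length(GLYCAN_ENZYMES),
         ")", call. = FALSE)
  if (is.null(rownames(activity))) rownames(activity) <- GLYCAN_ENZYMES
  if (!identical(rownames(activity), GLYCAN_ENZYMES))
    activity <- activity[GLYCAN_ENZYMES, , drop = FALSE]
  if (any(activity < 0) || any(!is.finite(activity)))
    stop("activities must be finite and >= 0", call. = FALSE)
  K <- ncol(activity)
  residence_time <- rep_len(as.numeric(residence_time), K)
  if (any(residence_time <= 0)) stop("residence_time must be > 0", call. = FALSE)
  if (lock_resolution_rate <= 0)
    stop("lock_resolution_rate must be > 0", call. = FALSE)
  structure(list(activity = activity,
                 lock_resolution_rate = as.numeric(lock_resolution_rate),
                 residence_time = residence_time),
            class = "enzyme_params")
}

#' Default parameter set (4 cisternae)
#'
#' A baseline activity layout following the classical cis/medial/trans/TGN
#' decomposition: mannosidase trimming early, antenna initiation and core
#' fucosylation medial, galactosylation late, light sialylation in the TGN.
#' Chosen once to yield a realistic mixed antibody profile (G0F-dominant with
#' appreciable Man5, G0, G1F and G2F) and used as the base condition for the
#' synthetic fitting targets.
#'
#' @param K number of cisternae (activities beyond the template's 4 columns
#'   are zero-padded or truncated).
#' @return an `enzyme_params` object.
#' @export
default_enzyme_params <- function(K = 4) {
  tmpl <- rbind(
    Man1  = c(6,   2,   0,    0),
    Mgat1 = c(0,   2.5, 1.5,  0),
    Man2  = c(0,   3,   2,    0),
    Fut8  = c(0,   1.5, 1.5,  0),
    Mgat2 = c(0,   1,   3,    1),
    Mgat4 = c(0,   0,   0.05, 0.05),
    Mgat5 = c(0,   0,   0.05, 0.05),
    GalT  = c(0,   0,   0.3,  0.45),
    SiaT  = c(0,   0,   0,    0.05))
  act <- matrix(0, nrow = nrow(tmpl), ncol = K,
                dimnames = list(rownames(tmpl), paste0("cisterna", seq_len(K))))
  take <- seq_len(min(K, ncol(tmpl)))
  act[, take] <- tmpl[, take]
  enzyme_params(act, lock_resolution_rate = 5, residence_time = 1)
}

#' Precompute the simulation engine for a rule set
#'
#' Enumerates the reachable state space once and packages the indexed
#' transition table for the compiled event loop; reuse it when simulating many
#' parameter sets over the same topology (as the ABC fitter does).
#'
#' @param rules rule list (default [default_rules()]).
#' @param start entry state (default Man9).
#' @return an `ssa_engine` object.
#' @export
ssa_engine <- function(rules = default_rules(), start = glycan_state(9L)) {
  tab <- build_transition_table(rules, start)
  tr <- tab$transitions[order(tab$transitions$from), , drop = FALSE]
  n_states <- length(tab$states)
  adj_len <- tabulate(tr$from, nbins = n_states)
  adj_start <- c(0L, cumsum(adj_len))[seq_len(n_states)]
  structure(list(table = tab, n_states = n_states,
                 trans_to = as.integer(tr$to - 1L),
                 trans_rule = as.integer(tr$rule - 1L),
                 adj_start = as.integer(adj_start),
                 adj_len = as.integer(adj_len),
                 resolve_to = as.integer(tab$resolve_to - 1L),
                 rule_names = tab$rule_names,
                 start_index = tab$start_index),
            class = "ssa_engine")
}

rates_matrix <- function(engine, params) {
  K <- length(params$residence_time)
  n_enz <- length(engine$rule_names) - 1L
  rn <- engine$rule_names[seq_len(n_enz)]
  rates <- rbind(params$activity[rn, , drop = FALSE],
                 lock_resolution = rep(params$lock_resolution_rate, K))
  storage.mode(rates) <- "double"
  rates
}

engine_simulate <- function(engine, params, n_glycans) {
  res <- ssa_simulate_cpp(as.integer(n_glycans),
                          as.integer(engine$start_index - 1L),
                          engine$n_states,
                          engine$trans_to, engine$trans_rule,
                          engine$adj_start, engine$adj_len,
                          rates_matrix(engine, params),
                          params$residence_time,
                          engine$resolve_to)
  counts <- res$terminal_counts
  nm <- engine$table$names
  keep <- counts > 0L
  agg <- tapply(counts[keep], nm[keep], sum)
  profile <- as.numeric(agg) / n_glycans
  names(profile) <- names(agg)
  fc <- res$firing_counts
  dimnames(fc) <- list(engine$rule_names,
                       paste0("cisterna", seq_along(params$residence_time)))
  structure(list(profile = profile, firing_counts = fc,
                 n_glycans = as.integer(n_glycans)),
            class = "simulation_result")
}

#' Simulate a glycan profile
#'
#' Runs `n_glycans` independent glycans from the start state through all
#' cisternae and aggregates terminal states (after force-resolving any
#' dangling fucosylation lock) into a named fractional profile summing to 1.
#'
#' @param params an `enzyme_params` object.
#' @param n_glycans number of glycans (study default 10000).
#' @param seed integer seed; the profile is bit-identical across runs with
#'   the same seed.
#' @param rules,start simulation topology (defaults: canonical rules, Man9).
#' @param engine optional prebuilt [ssa_engine()] (overrides `rules`/`start`).
#' @return a `simulation_result`: `profile` (named fractions), `firing_counts`
#'   (rule x cisterna), `n_glycans`.
#' @export
simulate_profile <- function(params, n_glycans = 10000, seed = NULL,
                             rules = default_rules(),
                             start = glycan_state(9L), engine = NULL) {
  stopifnot(n_glycans >= 1)
  if (is.null(engine)) engine <- ssa_engine(rules, start)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  engine_simulate(engine, params, n_glycans)
}

#' One Gillespie step (reference implementation)
#'
#' Propensity of each applicable rule equals its activity in the current
#' cisterna; a locked state exposes only the lock-resolution pseudo-reaction
#' at `lock_resolution_rate`.  The waiting time is Exponential(total
#' propensity) and the firing rule is chosen proportionally.  With no
#' applicable reaction the state is absorbing (`waiting_time = Inf`).
#'
#' This R-level implementation exists as the readable reference for the
#' compiled event loop and is cross-checked against it in the test suite.
#'
#' @param state a valid `glycan_state`.
#' @param params an `enzyme_params`.
#' @param cisterna_index cisterna number, 1..K.
#' @param rules rule list.
#' @return list(next_state, waiting_time, fired) where `fired` is the enzyme
#'   name, `"lock_resolution"`, or `NA` if nothing can fire.
#' @export
gillespie_step <- function(state, params, cisterna_index,
                           rules = default_rules()) {
  K <- length(params$residence_time)
  if (cisterna_index < 1 || cisterna_index > K)
    stop("cisterna_index outside 1..K", call. = FALSE)
  if (is_locked(state)) {
    cand <- list(list(name = "lock_resolution",
                      rate = params$lock_resolution_rate,
                      deltas = LOCK_RESOLUTION_DELTAS))
  } else {
    app <- applicable_rules(state, rules)
    cand <- lapply(app, function(r)
      list(name = r$enzyme,
           rate = params$activity[r$enzyme, cisterna_index],
           deltas = r$deltas))
  }
  rates <- vapply(cand, `[[`, numeric(1), "rate")
  a0 <- sum(rates)
  if (length(cand) == 0L || a0 <= 0)
    return(list(next_state = state, waiting_time = Inf, fired = NA_character_))
  wt <- rexp(1, rate = a0)
  pick <- cand[[sample.int(length(cand), 1L, prob = rates)]]
  list(next_state = apply_deltas(state, pick$deltas),
       waiting_time = wt, fired = pick$name)
}

#' Simulate one glycan through all cisternae (reference implementation)
#'
#' Runs [gillespie_step()] within each cisterna until the accumulated waiting
#' time exceeds that cisterna's residence time, then advances; an in-progress
#' lock carries into the next cisterna, and any lock still unresolved after
#' the last cisterna is force-resolved (fucose added).
#'
#' @inheritParams gillespie_step
#' @param start entry state.
#' @return list(final_state, firing_counts) with `firing_counts` a
#'   (rules + lock resolution) x K matrix.
#' @export
simulate_glycan <- function(start, params, rules = default_rules()) {
  K <- length(params$residence_time)
  rule_names <- c(vapply(rules, `[[`, character(1), "enzyme"),
                  "lock_resolution")
  fc <- matrix(0L, nrow = length(rule_names), ncol = K,
               dimnames = list(rule_names, paste0("cisterna", seq_len(K))))
  s <- start
  for (k in seq_len(K)) {
    t <- 0
    repeat {
      st <- gillespie_step(s, params, k, rules)
      if (!is.finite(st$waiting_time)) break
      t <- t + st$waiting_time
      if (t > params$residence_time[k]) break
      s <- st$next_state
      fc[st$fired, k] <- fc[st$fired, k] + 1L
    }
  }
  if (is_locked(s)) {
    fc["lock_resolution", K] <- fc["lock_resolution", K] + 1L
    s <- apply_deltas(s, LOCK_RESOLUTION_DELTAS)
  }
  list(final_state = s, firing_counts = fc)
}

#' Per-cisterna localization of an enzyme's flux
#'
#' Normalizes the enzyme's firing counts across cisternae to fractions summing
#' to 1, i.e. where in the Golgi the enzyme's reactions actually occurred —
#' the readout used to compare the spatial distribution of activity (e.g.
#' Mgat1) between fitted conditions.
#'
#' @param result a `simulation_result`.
#' @param enzyme_name one of the nine enzymes (or `"lock_resolution"`).
#' @return numeric vector over cisternae summing to 1; all zeros (with a
#'   warning) if the enzyme never fired.
#' @export
flux_localization <- function(result, enzyme_name) {
  row <- result$firing_counts[enzyme_name, ]
  tot <- sum(row)
  if (tot == 0) {
    warning("enzyme ", enzyme_name, " never fired; empty flux", call. = FALSE)
    return(row * 0)
  }
  row / tot
}

#' Validate a glycan profile
#'
#' @param profile named numeric vector of fractions.
#' @param tol tolerance on the unit sum.
#' @return the profile, invisibly.
#' @export
validate_profile <- function(profile, tol = 1e-9) {
  if (any(profile < 0)) stop("profile has negative fractions", call. = FALSE)
  if (abs(sum(profile) - 1) > tol)
    stop("profile fractions do not sum to 1 (off by ",
         format(sum(profile) - 1), ")", call. = FALSE)
  invisible(profile)
}

# Align two profiles on the union of their species (absent species = 0).
align_profiles <- function(a, b) {
  nm <- union(names(a), names(b))
  av <- setNames(numeric(length(nm)), nm); av[names(a)] <- a
  bv <- setNames(numeric(length(nm)), nm); bv[names(b)] <- b
  list(a = av, b = bv)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Derive a named substream seed from a master seed
#'
#' All randomness flows from one master seed through named substreams so each
#' pipeline stage is independently reproducible.
#'
#' @param master integer master seed.
#' @param stream character substream name.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(master) * 48271 + h) %% 2147483629) + 1L
}
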